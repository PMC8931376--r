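# Profile-likelihood (parameter continuation) and Monte Carlo confidence
# intervals for weighted least-squares fits.

# minimal least-squares fit object sharing the flux_fit interface; used for
# small test problems and internally by the CI routines
new_ls_fit <- function(predict_num, par0, values, sds, lower, upper,
                       n_starts = 1, seed = 1) {
  make_objective <- function(v) {
    function(par) {
      p <- tryCatch(predict_num(par), error = function(e) NULL)
      if (is.null(p) || anyNA(p)) return(1e10)
      sum(((p - v) / sds)^2)
    }
  }
  objective <- make_objective(values)
  best <- stats::nlminb(par0, objective, lower = lower, upper = upper)
  structure(list(
    par = stats::setNames(best$par, names(par0)),
    free = names(par0),
    ssr = best$objective,
    lower = lower, upper = upper,
    objective = objective,
    predict_num = predict_num,
    make_objective = make_objective,
    meas_values = values, meas_sds = sds,
    n_obs = length(values), dof = length(values) - length(par0),
    multistart = list(seed = seed, n_starts = n_starts, best = 1L,
                      converged = best$convergence == 0)
  ), class = "flux_fit")
}

# re-optimize the remaining parameters with parameter `idx` fixed at `value`
profile_point <- function(fit, idx, value, start, objective = fit$objective) {
  if (length(fit$par) == 1L) {
    return(list(ssr = objective(value), par = value))
  }
  obj_fixed <- function(rest) {
    par <- numeric(length(fit$par))
    par[idx] <- value
    par[-idx] <- rest
    objective(par)
  }
  res <- stats::nlminb(start[-idx], obj_fixed,
                       lower = fit$lower[-idx], upper = fit$upper[-idx])
  par <- numeric(length(fit$par))
  par[idx] <- value
  par[-idx] <- res$par
  list(ssr = res$objective, par = par)
}

#' Profile-likelihood confidence interval by parameter continuation
#'
#' Walks one parameter away from its estimate in both directions,
#' re-optimizing all remaining parameters at each step, until the weighted
#' SSR exceeds `SSR_min + qchisq(level, 1)`; the crossing is located by
#' linear interpolation. A bound hit before the crossing yields a one-sided
#' interval with a flag.
#'
#' @param fit A `flux_fit`.
#' @param parameter Name of the parameter (as in `fit$par`).
#' @param level Confidence level (default 0.95).
#' @param step Initial step as a fraction of the estimate's magnitude
#'   (default 0.02); steps grow geometrically.
#' @param max_steps Maximum continuation steps per direction.
#' @return A `profile_ci` list: `estimate`, `lower`, `upper`,
#'   `lower_at_bound`, `upper_at_bound`, `level`, and the SSR `trace`.
#' @export
profile_ci <- function(fit, parameter, level = 0.95, step = 0.02,
                       max_steps = 60) {
  stopifnot(inherits(fit, "flux_fit"))
  idx <- match(parameter, fit$free)
  if (is.na(idx)) stop("unknown parameter '", parameter, "'", call. = FALSE)
  est <- unname(fit$par[idx])
  thresh <- fit$ssr + stats::qchisq(level, df = 1)
  h0 <- max(abs(est) * step, step * max(1, fit$upper[idx] - fit$lower[idx]) / 50,
            1e-6)

  walk <- function(dir) {
    v <- est
    h <- h0
    start <- unname(fit$par)
    trace_v <- est
    trace_ssr <- fit$ssr
    hit_bound <- FALSE
    for (k in seq_len(max_steps)) {
      v_next <- v + dir * h
      if (v_next <= fit$lower[idx]) { v_next <- fit$lower[idx]; hit_bound <- TRUE }
      if (v_next >= fit$upper[idx]) { v_next <- fit$upper[idx]; hit_bound <- TRUE }
      pp <- profile_point(fit, idx, v_next, start)
      trace_v <- c(trace_v, v_next)
      trace_ssr <- c(trace_ssr, pp$ssr)
      start <- pp$par
      if (pp$ssr >= thresh) {
        # bracketed: refine the crossing by regula falsi
        lo_v <- trace_v[length(trace_v) - 1L]
        lo_s <- trace_ssr[length(trace_ssr) - 1L]
        hi_v <- v_next
        hi_s <- pp$ssr
        for (it in 1:6) {
          mid_v <- lo_v + (thresh - lo_s) / (hi_s - lo_s) * (hi_v - lo_v)
          pm <- profile_point(fit, idx, mid_v, start)
          trace_v <- c(trace_v, mid_v)
          trace_ssr <- c(trace_ssr, pm$ssr)
          if (abs(pm$ssr - thresh) < 1e-4 * (thresh - fit$ssr)) {
            return(list(bound = mid_v, at_bound = FALSE,
                        trace_v = trace_v, trace_ssr = trace_ssr))
          }
          if (pm$ssr < thresh) {
            lo_v <- mid_v; lo_s <- pm$ssr
          } else {
            hi_v <- mid_v; hi_s <- pm$ssr
          }
        }
        return(list(bound = lo_v + (thresh - lo_s) / (hi_s - lo_s) *
                      (hi_v - lo_v),
                    at_bound = FALSE,
                    trace_v = trace_v, trace_ssr = trace_ssr))
      }
      if (hit_bound) {
        return(list(bound = v_next, at_bound = TRUE,
                    trace_v = trace_v, trace_ssr = trace_ssr))
      }
      v <- v_next
      h <- h * 1.6
    }
    list(bound = v, at_bound = TRUE, trace_v = trace_v, trace_ssr = trace_ssr)
  }

  up <- walk(+1)
  dn <- walk(-1)
  structure(list(
    parameter = parameter, estimate = est,
    lower = dn$bound, upper = up$bound,
    lower_at_bound = dn$at_bound, upper_at_bound = up$at_bound,
    level = level,
    trace = tibble::tibble(
      value = c(rev(dn$trace_v), up$trace_v[-1]),
      ssr = c(rev(dn$trace_ssr), up$trace_ssr[-1])
    )
  ), class = "profile_ci")
}

#' @export
print.profile_ci <- function(x, ...) {
  cat(sprintf("%s: %.4g  [%0.1f%% CI %.4g, %.4g]%s%s\n",
              x$parameter, x$estimate, 100 * x$level, x$lower, x$upper,
              if (x$lower_at_bound) " (lower at bound)" else "",
              if (x$upper_at_bound) " (upper at bound)" else ""))
  invisible(x)
}

#' Monte Carlo (parametric bootstrap) confidence intervals
#'
#' Resimulates the measurements as Gaussian draws around the best-fit
#' predictions at their stated SDs, refits each draw (starting from the
#' best-fit parameters), and returns percentile intervals of the refitted
#' estimates.
#'
#' @param fit A `flux_fit`.
#' @param n_draws Number of synthetic datasets (default 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param noise_scale Multiplier on the stated SDs when drawing noise
#'   (1 = nominal; 0 reproduces the point estimate exactly).
#' @return A `mc_ci` list with a tibble `intervals` (`parameter`,
#'   `estimate`, `lower`, `upper`) and the draw matrix `draws`.
#' @export
monte_carlo_ci <- function(fit, n_draws = 100, seed = 1, level = 0.95,
                           noise_scale = 1) {
  stopifnot(inherits(fit, "flux_fit"))
  if (length(fit$par) == 0L) stop("fit has no free parameters", call. = FALSE)
  base_pred <- fit$predict_num(unname(fit$par))
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(fit$par),
                  dimnames = list(NULL, fit$free))
  fails <- 0L
  for (i in seq_len(n_draws)) {
    values <- base_pred +
      noise_scale * stats::rnorm(length(base_pred), 0, fit$meas_sds)
    obj <- fit$make_objective(values)
    res <- tryCatch(
      stats::nlminb(unname(fit$par), obj, lower = fit$lower,
                    upper = fit$upper),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$objective) || res$objective >= 1e10) {
      fails <- fails + 1L
    } else {
      draws[i, ] <- res$par
    }
  }
  if (fails > 0.1 * n_draws) {
    stop("more than 10% of Monte Carlo refits failed (", fails, "/", n_draws,
         ")", call. = FALSE)
  }
  a <- (1 - level) / 2
  intervals <- tibble::tibble(
    parameter = fit$free,
    estimate = unname(fit$par),
    lower = apply(draws, 2, stats::quantile, probs = a, na.rm = TRUE),
    upper = apply(draws, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  )
  structure(list(intervals = intervals, draws = draws, level = level,
                 n_draws = n_draws, failures = fails, seed = seed),
            class = "mc_ci")
}

#' @export
print.mc_ci <- function(x, ...) {
  cat("<mc_ci> ", x$n_draws, " draws, ", x$failures, " failures, level ",
      x$level, "\n", sep = "")
  print(x$intervals)
  invisible(x)
}
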