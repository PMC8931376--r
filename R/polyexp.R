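# Polyexponential decay fitting for percent-12C time courses.

exp_model_matrix <- function(par, K, has_constant, t_h) {
  A <- par[seq_len(K)]
  k <- par[K + seq_len(K)]
  C <- if (has_constant) par[2 * K + 1L] else 0
  drop(exp(outer(t_h, -k)) %*% A) + C
}

exp_par_names <- function(K, has_constant) {
  c(paste0("A", seq_len(K)), paste0("k", seq_len(K)),
    if (has_constant) "C")
}

canonical_order <- function(par, K, has_constant) {
  A <- par[seq_len(K)]
  k <- par[K + seq_len(K)]
  o <- order(-k, -A)
  out <- c(A[o], k[o], if (has_constant) par[2 * K + 1L])
  stats::setNames(out, exp_par_names(K, has_constant))
}

#' Fit a K-term exponential decay model
#'
#' Fits `u(t) = sum_i A_i exp(-k_i t) + C` to a percent-12C decay series by
#' bound-constrained Levenberg-Marquardt least squares, restarted from
#' `n_starts` initializations: the first start comes from curve stripping
#' when it succeeds, the rest draw rates log-uniformly on 0.01-100 per hour
#' and amplitudes on the data scale. Time is taken in minutes and rates are
#' reported per hour. Amplitudes and the constant are constrained
#' non-negative; parameters are returned in canonical descending-rate order.
#'
#' @param series Data frame with columns `time_min` and `pct_12c`.
#' @param K Number of exponential terms (1-4).
#' @param has_constant Include a constant offset (inactive-pool analogue).
#' @param n_starts Number of multistarts (default 100).
#' @param seed Integer seed for the random starts.
#' @return An `exp_fit`: parameter estimates, `ssr`, `residuals`,
#'   `fitted`, counts, convergence and multistart record.
#' @export
fit_exp_model <- function(series, K, has_constant = FALSE, n_starts = 100,
                          seed = 1) {
  if (!is.numeric(K) || length(K) != 1L || !K %in% 1:4) {
    stop("K must be 1, 2, 3 or 4", call. = FALSE)
  }
  t_min <- series$time_min
  u <- series$pct_12c
  stopifnot(is.numeric(t_min), is.numeric(u), length(t_min) == length(u))
  n <- length(u)
  p <- 2L * K + as.integer(has_constant)
  if (n < p + 1L) {
    stop("need at least ", p + 1L, " observations for this model",
         call. = FALSE)
  }
  t_h <- t_min / 60
  scale_u <- max(u) - min(u)
  if (scale_u <= 0) scale_u <- max(abs(u), 1)

  lower <- c(rep(0, K), rep(1e-4, K), if (has_constant) 0)
  upper <- c(rep(2 * max(abs(u), 1), K), rep(1e4, K),
             if (has_constant) max(abs(u), 1))
  resid_fn <- function(par) u - exp_model_matrix(par, K, has_constant, t_h)

  starts <- list()
  strip <- tryCatch(
    suppressWarnings(curve_strip(series, phases = K)),
    error = function(e) NULL
  )
  if (!is.null(strip) && nrow(strip) == K &&
      all(is.finite(strip$A)) && all(is.finite(strip$k)) && all(strip$k > 0)) {
    starts[[1]] <- pmin(pmax(
      c(strip$A, strip$k, if (has_constant) min(u)),
      lower), upper)
  }
  set.seed(seed)
  while (length(starts) < n_starts) {
    w <- stats::runif(K)
    A0 <- scale_u * w / sum(w)
    k0 <- 10^stats::runif(K, -2, 2)
    starts[[length(starts) + 1L]] <-
      c(A0, k0, if (has_constant) stats::runif(1, 0, max(min(u), 1)))
  }

  best <- NULL
  best_ssr <- Inf
  best_i <- NA_integer_
  n_conv <- 0L
  for (i in seq_along(starts)) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[i]], lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ssr <- sum(res$fvec^2)
    if (is.finite(ssr)) {
      n_conv <- n_conv + 1L
      if (ssr < best_ssr) {
        best_ssr <- ssr
        best <- res
        best_i <- i
      }
    }
  }
  if (is.null(best)) {
    stop("no multistart converged for K = ", K, call. = FALSE)
  }
  par <- canonical_order(best$par, K, has_constant)
  fitted <- exp_model_matrix(unname(par), K, has_constant, t_h)
  structure(list(
    K = K, has_constant = has_constant,
    par = par,
    ssr = best_ssr,
    residuals = u - fitted,
    fitted = fitted,
    series = tibble::tibble(time_min = t_min, pct_12c = u),
    n = n, p = p,
    converged = best$info %in% 1:4,
    multistart = list(seed = seed, n_starts = length(starts),
                      n_converged = n_conv, best = best_i)
  ), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> ", x$K, " exponential term(s)",
      if (x$has_constant) " + constant", ", SSR = ", signif(x$ssr, 6),
      "\n", sep = "")
  print(signif(x$par, 5))
  invisible(x)
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  t_min <- if (is.null(newdata)) object$series$time_min else newdata$time_min
  exp_model_matrix(unname(object$par), object$K, object$has_constant,
                   t_min / 60)
}

#' @rdname cbclabel-tidiers
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname cbclabel-tidiers
#' @export
glance.exp_fit <- function(x, ...) {
  ic <- information_criteria(x)
  tibble::tibble(K = x$K, has_constant = x$has_constant, ssr = x$ssr,
                 n = x$n, p = x$p, aic = ic$aic, bic = ic$bic,
                 converged = x$converged)
}

#' Curve stripping: sequential semilog peeling of exponential phases
#'
#' Pharmacokinetics-style initialization: a straight line is fitted to the
#' logarithm of the slowest tail of the series, the implied component is
#' subtracted, and the procedure repeats toward faster phases. Returns
#' amplitude/rate guesses ordered fastest first (descending rate).
#'
#' @param series Data frame with `time_min`, `pct_12c`.
#' @param phases Number of phases to strip (1-4).
#' @return Tibble with columns `A` (percent) and `k` (per hour).
#' @export
curve_strip <- function(series, phases) {
  stopifnot(phases %in% 1:4)
  t_h <- series$time_min / 60
  r <- series$pct_12c
  out <- list()
  for (ph in seq_len(phases)) {
    pos <- which(r > 0 & t_h > 0)
    if (length(pos) < 2L) {
      warning("curve stripping ran out of positive residual points; ",
              "falling back to random initialization")
      return(NULL)
    }
    m <- max(3L, ceiling(length(pos) / 4))
    use <- utils::tail(pos, m)
    co <- stats::coef(stats::lm(log(r[use]) ~ t_h[use]))
    k <- max(-co[2], 1e-4)
    A <- exp(co[1])
    out[[ph]] <- c(A = unname(A), k = unname(k))
    r <- r - A * exp(-k * t_h)
    t_keep <- t_h < min(t_h[use])
    r[!t_keep] <- 0
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, dplyr::desc(.data$k))
}

#' Residual-resampling bootstrap band for an exponential fit
#'
#' Resamples the fit residuals with replacement onto the fitted curve
#' (the time grid is fixed by design), refits each resample from the
#' best-fit parameters, and returns percentile intervals for the parameters
#' and for the fitted curve on a fine time grid.
#'
#' @param fit An `exp_fit`.
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param band_times_min Time grid for the curve band (default: 100 points
#'   spanning the data).
#' @return A `bootstrap_band`: `param_ci` tibble, `band` tibble
#'   (`time_min`, `fit`, `lower`, `upper`), failures count.
#' @export
bootstrap_band <- function(fit, n_resamples = 1000, level = 0.95, seed = 1,
                           band_times_min = NULL) {
  stopifnot(inherits(fit, "exp_fit"))
  t_min <- fit$series$time_min
  t_h <- t_min / 60
  if (is.null(band_times_min)) {
    band_times_min <- seq(min(t_min), max(t_min), length.out = 100)
  }
  K <- fit$K
  hc <- fit$has_constant
  lower <- c(rep(0, K), rep(1e-4, K), if (hc) 0)
  upper <- c(rep(2 * max(abs(fit$series$pct_12c), 1), K), rep(1e4, K),
             if (hc) max(abs(fit$series$pct_12c), 1))
  set.seed(seed)
  par_mat <- matrix(NA_real_, n_resamples, length(fit$par),
                    dimnames = list(NULL, names(fit$par)))
  band_mat <- matrix(NA_real_, n_resamples, length(band_times_min))
  fails <- 0L
  for (b in seq_len(n_resamples)) {
    u_star <- fit$fitted + sample(fit$residuals, length(fit$residuals),
                                  replace = TRUE)
    resid_fn <- function(par) u_star - exp_model_matrix(par, K, hc, t_h)
    res <- tryCatch(
      minpack.lm::nls.lm(par = unname(fit$par), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL
    )
    if (is.null(res) || !all(is.finite(res$par))) {
      fails <- fails + 1L
      next
    }
    pb <- canonical_order(res$par, K, hc)
    par_mat[b, ] <- pb
    band_mat[b, ] <- exp_model_matrix(unname(pb), K, hc, band_times_min / 60)
  }
  if (fails > 0.1 * n_resamples) {
    stop("more than 10% of bootstrap refits failed (", fails, "/",
         n_resamples, ")", call. = FALSE)
  }
  a <- (1 - level) / 2
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p, na.rm = TRUE)
  structure(list(
    param_ci = tibble::tibble(
      term = names(fit$par), estimate = unname(fit$par),
      lower = q(par_mat, a), upper = q(par_mat, 1 - a)
    ),
    band = tibble::tibble(
      time_min = band_times_min,
      fit = exp_model_matrix(unname(fit$par), K, hc, band_times_min / 60),
      lower = q(band_mat, a), upper = q(band_mat, 1 - a)
    ),
    draws = par_mat, level = level, n_resamples = n_resamples,
    failures = fails, seed = seed
  ), class = "bootstrap_band")
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat("<bootstrap_band> ", x$n_resamples, " resamples (", x$failures,
      " failures), level ", x$level, "\n", sep = "")
  print(x$param_ci)
  invisible(x)
}
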