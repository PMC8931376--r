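# Weighted least-squares flux fitting, variant comparison, confidence
# intervals.

#' Weighted sum of squared residuals
#'
#' Compares predicted measured-species MIDs (and optionally scalar flux
#' measurements) with a dataset, summing `((sim - meas) / sd)^2` over every
#' isotopologue channel, time point, and scalar.
#'
#' @param pred Long MID tibble of predictions (`metabolite`, `time_min`,
#'   `mass`, `fraction`).
#' @param d A `cbc_dataset` (or list with `mids` and optionally `scalars`).
#' @param pred_scalars Optional named vector of predicted scalar values
#'   matching `d$scalars$name`.
#' @param per_species Return a per-species breakdown instead of the total.
#' @return Total weighted SSR (scalar), or a tibble when
#'   `per_species = TRUE`.
#' @export
weighted_ssr <- function(pred, d, pred_scalars = NULL, per_species = FALSE) {
  meas <- d$mids
  if (any(meas$sd <= 0)) stop("measurement SDs must be positive", call. = FALSE)
  j <- dplyr::inner_join(
    meas, pred,
    by = c("metabolite", "time_min", "mass"), suffix = c("", ".pred")
  )
  if (nrow(j) < nrow(meas)) {
    stop("prediction missing for ", nrow(meas) - nrow(j),
         " measured channel(s)", call. = FALSE)
  }
  j <- j |>
    dplyr::mutate(wres2 = ((.data$fraction.pred - .data$fraction) / .data$sd)^2)
  if (per_species) {
    return(
      j |>
        dplyr::group_by(.data$metabolite) |>
        dplyr::summarise(ssr = sum(.data$wres2), n = dplyr::n(),
                         .groups = "drop") |>
        dplyr::arrange(dplyr::desc(.data$ssr))
    )
  }
  total <- sum(j$wres2)
  if (!is.null(pred_scalars) && !is.null(d$scalars) && nrow(d$scalars) > 0) {
    sc <- d$scalars
    missing <- setdiff(sc$name, names(pred_scalars))
    if (length(missing) > 0L) {
      stop("predicted scalar(s) missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    total <- total + sum(((pred_scalars[sc$name] - sc$value) / sc$sd)^2)
  }
  total
}

# parameter spec handling: names are "flux:<rxn>", "exch:<rxn>",
# "pool:<met>", "inactive:<met>"
param_kind <- function(p) sub(":.*$", "", p)
param_id <- function(p) sub("^[a-z]+:", "", p)

default_bounds <- function(free) {
  kind <- param_kind(free)
  lower <- ifelse(kind == "pool", 1e-3, 0)
  upper <- dplyr::case_when(
    kind == "flux" ~ 500,
    kind == "exch" ~ 500,
    kind == "pool" ~ 100,
    kind == "inactive" ~ 0.95
  )
  list(lower = stats::setNames(lower, free),
       upper = stats::setNames(upper, free))
}

apply_params <- function(base, free, par) {
  out <- base
  for (i in seq_along(free)) {
    kind <- param_kind(free[i])
    id <- param_id(free[i])
    val <- par[i]
    if (kind == "flux") out$spec[id] <- val
    else if (kind == "exch") out$exch[id] <- val
    else if (kind == "pool") out$pools[id] <- val
    else if (kind == "inactive") out$f_inactive[id] <- val
    else stop("unknown parameter kind in '", free[i], "'", call. = FALSE)
  }
  out
}

predict_scalars <- function(f) {
  v <- f$net
  g <- function(id) if (id %in% names(v)) v[[id]] else 0
  c(net_assimilation = g("co2_in") - g("co2_efflux"),
    sucrose_export = g("suc_export"),
    triose_export = g("triose_efflux"),
    vo_vc = if (g("rubisco_c") > 0) g("rubisco_o") / g("rubisco_c") else NA_real_)
}

#' Fit a network variant to a labeling dataset
#'
#' Multistart bound-constrained weighted least squares over a chosen set of
#' free parameters. Metabolic steady state is enforced by construction: net
#' fluxes are re-solved in the null space of the stoichiometric matrix at
#' every iterate (specified fluxes plus the free flux parameters), so every
#' candidate flux vector is exactly balanced. Scalar measurements (net
#' assimilation, export rates, the vo/vc ratio) enter as soft constraints,
#' i.e. extra weighted residuals.
#'
#' @param net A `cbc_network` (a variant's reaction set).
#' @param d A `cbc_dataset` to fit.
#' @param free Character vector of free parameters: `"flux:<rxn>"`,
#'   `"exch:<rxn>"`, `"pool:<met>"`, `"inactive:<met>"`.
#' @param base List with the fixed problem definition: `spec` (named flux
#'   values for [flux_solve()]), `exch`, `pools`, optionally `f_inactive`,
#'   `input_enrichment`, `init`.
#' @param n_starts Number of random multistarts (default 20).
#' @param seed Integer seed for start generation.
#' @param lower,upper Optional named bounds overriding the defaults.
#' @param use_scalars Include scalar measurements in the SSR.
#' @param rtol,atol Forward-simulation tolerances used during fitting.
#' @return A `flux_fit` object: best parameters (`par`), weighted `ssr`,
#'   per-species breakdown, fitted `flux_state`, predictions, degrees of
#'   freedom, the multistart record, and a refit closure used by the
#'   confidence-interval methods.
#' @export
fit_variant <- function(net, d, free, base, n_starts = 20, seed = 1,
                        lower = NULL, upper = NULL, use_scalars = TRUE,
                        rtol = 1e-7, atol = 1e-9) {
  stopifnot(inherits(net, "cbc_network"), inherits(d, "cbc_dataset"))
  free <- unique(free)
  bounds <- if (length(free)) default_bounds(free) else
    list(lower = numeric(0), upper = numeric(0))
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper

  base$pools <- base$pools[names(base$pools) %in% net$metabolites$id]
  base$exch <- base$exch[names(base$exch) %in% names(net$reactions)]
  mixing <- d$mixing
  mixing <- purrr::map(mixing, function(pl) pl[pl %in% net$metabolites$id])
  mixing <- mixing[vapply(mixing, length, integer(1)) > 0L]
  fit_species <- intersect(unique(d$mids$metabolite), names(mixing))
  meas <- list(
    mids = dplyr::filter(d$mids, .data$metabolite %in% fit_species),
    scalars = if (use_scalars) d$scalars else NULL
  )
  n_res <- nrow(meas$mids) + if (use_scalars) nrow(d$scalars) else 0L
  if (n_res - length(free) <= 0) {
    stop("no residual degrees of freedom for ", length(free), " parameters",
         call. = FALSE)
  }

  sys <- emu_decompose(net, unique(unlist(mixing)))
  times <- sort(unique(meas$mids$time_min))

  simulate_par <- function(par) {
    b <- apply_params(base, free, par)
    f <- flux_solve(net, b$spec, exch = b$exch)
    sim <- simulate_labeling(
      sys, f, b$pools, times,
      input_enrichment = b$input_enrichment %||% 0.99,
      init = b$init %||% "unlabeled",
      f_inactive = b$f_inactive,
      rtol = rtol, atol = atol
    )
    list(pred = mix_species_mids(sim, mixing, b$pools),
         scalars = predict_scalars(f), flux = f)
  }
  # numeric view of measurements and predictions (MID channels, then scalars)
  key <- function(tb) paste(tb$metabolite, tb$time_min, tb$mass, sep = "|")
  meas_key <- key(meas$mids)
  meas_values <- meas$mids$fraction
  meas_sds <- meas$mids$sd
  if (use_scalars) {
    meas_values <- c(meas_values, d$scalars$value)
    meas_sds <- c(meas_sds, d$scalars$sd)
  }
  predict_num <- function(par) {
    out <- simulate_par(par)
    p <- out$pred$fraction[match(meas_key, key(out$pred))]
    if (use_scalars) p <- c(p, out$scalars[d$scalars$name])
    unname(p)
  }
  make_objective <- function(values) {
    function(par) {
      p <- tryCatch(predict_num(par), error = function(e) NULL)
      if (is.null(p) || anyNA(p)) return(1e10)
      sum(((p - values) / meas_sds)^2)
    }
  }
  objective <- make_objective(meas_values)

  if (length(free) == 0L) {
    at_opt <- simulate_par(numeric(0))
    ssr0 <- weighted_ssr(at_opt$pred, meas,
                         pred_scalars = if (use_scalars) at_opt$scalars else NULL)
    return(structure(list(
      par = numeric(0), ssr = ssr0,
      ssr_by_species = weighted_ssr(at_opt$pred, meas, per_species = TRUE),
      flux = at_opt$flux, predictions = at_opt$pred,
      pred_scalars = at_opt$scalars,
      free = character(0), lower = numeric(0), upper = numeric(0),
      base = base, network = net, meas = meas, use_scalars = use_scalars,
      n_obs = n_res, dof = n_res, objective = objective,
      simulate_par = simulate_par,
      predict_num = predict_num, make_objective = make_objective,
      meas_values = meas_values, meas_sds = meas_sds,
      multistart = list(seed = seed, n_starts = 0L, best = NA_integer_,
                        ssr = ssr0, converged = TRUE)
    ), class = "flux_fit"))
  }

  start0 <- vapply(seq_along(free), function(i) {
    kind <- param_kind(free[i]); id <- param_id(free[i])
    v <- switch(kind,
      flux = unname(base$spec[id]),
      exch = unname(base$exch[id]),
      pool = unname(base$pools[id]),
      inactive = unname((base$f_inactive %||% numeric(0))[id])
    )
    if (length(v) != 1L || is.na(v)) v <- NA_real_
    v
  }, numeric(1))
  set.seed(seed)
  lo <- bounds$lower; hi <- bounds$upper
  starts <- matrix(NA_real_, nrow = n_starts, ncol = length(free))
  starts[1, ] <- ifelse(is.na(start0), NA, pmin(pmax(start0, lo), hi))
  for (r in seq_len(n_starts)) {
    rand <- exp(stats::runif(length(free),
                             log(pmax(lo, 1e-3)), log(pmax(hi, 2e-3))))
    kind <- param_kind(free)
    unif <- stats::runif(length(free), lo, hi)
    row <- ifelse(kind %in% c("flux", "exch"), pmin(rand, hi), unif)
    if (r > 1L || anyNA(starts[1, ])) starts[r, ] <- row
  }

  runs <- vector("list", n_starts)
  for (r in seq_len(n_starts)) {
    runs[[r]] <- tryCatch(
      stats::nlminb(starts[r, ], objective, lower = lo, upper = hi,
                    control = list(iter.max = 300, eval.max = 600)),
      error = function(e) list(objective = Inf, convergence = 1L)
    )
  }
  ssrs <- vapply(runs, function(x) x$objective, numeric(1))
  if (!any(is.finite(ssrs) & ssrs < 1e10)) {
    stop("no multistart converged to a finite SSR", call. = FALSE)
  }
  best_i <- which.min(ssrs)
  best <- runs[[best_i]]
  par <- stats::setNames(best$par, free)
  at_opt <- simulate_par(best$par)

  structure(list(
    par = par, ssr = best$objective,
    ssr_by_species = weighted_ssr(at_opt$pred, meas, per_species = TRUE),
    flux = at_opt$flux,
    predictions = at_opt$pred,
    pred_scalars = at_opt$scalars,
    free = free, lower = lo, upper = hi,
    base = base, network = net, meas = meas, use_scalars = use_scalars,
    n_obs = n_res, dof = n_res - length(free),
    objective = objective,
    simulate_par = simulate_par,
    predict_num = predict_num,
    make_objective = make_objective,
    meas_values = meas_values, meas_sds = meas_sds,
    multistart = list(seed = seed, n_starts = n_starts, best = best_i,
                      ssr = ssrs,
                      converged = vapply(runs, function(x)
                        isTRUE(x$convergence == 0), logical(1)))
  ), class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit> SSR = ", signif(x$ssr, 6), " over ", x$n_obs,
      " residuals (dof ", x$dof, ")\n", sep = "")
  for (i in seq_along(x$par)) {
    cat(sprintf("  %-18s %.4g\n", x$free[i], x$par[i]))
  }
  invisible(x)
}

#' @rdname cbclabel-tidiers
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @export
tidy.flux_fit <- function(x, ...) {
  tibble::tibble(term = x$free, estimate = unname(x$par),
                 lower = unname(x$lower), upper = unname(x$upper))
}

#' @rdname cbclabel-tidiers
#' @param x A `flux_fit`.
#' @param ... Unused.
#' @export
glance.flux_fit <- function(x, ...) {
  tibble::tibble(ssr = x$ssr, n_obs = x$n_obs, dof = x$dof,
                 n_starts = x$multistart$n_starts,
                 converged = any(x$multistart$converged))
}

#' Compare unlabeled-carbon-entry model variants
#'
#' Fits each hypothesis variant to the same dataset, freeing that variant's
#' entry flux (plus the sucrose-recycling fluxes for V5), and tabulates the
#' weighted SSR, its change versus the base model, and the fitted entry
#' flux. Only measured species representable in every compared variant enter
#' the SSR, so the values are directly comparable.
#'
#' @param d A `cbc_dataset`.
#' @param variants Character vector of variant ids (default V0..V5).
#' @param base Fixed problem definition shared by all variants (see
#'   [fit_variant()]); entry fluxes and recycling fluxes are removed from
#'   `base$spec` automatically where they are freed.
#' @param net_full Full network (default [cbc_network()]).
#' @param n_starts,seed Multistart settings per variant fit.
#' @param rtol,atol Forward-simulation tolerances.
#' @return A `variant_comparison` tibble: `variant`, `ssr`, `delta_ssr`
#'   (vs V0), `entry_flux`, `n_free`, plus a `fits` attribute with the
#'   individual `flux_fit` objects.
#' @export
compare_variants <- function(d, variants = paste0("V", 0:5), base,
                             net_full = cbc_network(), n_starts = 5, seed = 1,
                             rtol = 1e-7, atol = 1e-9) {
  entry_of <- c(V0 = NA, V1 = "e1_glc", V2 = "e2_glc", V3 = "e3_co2",
                V4 = "e4_tp", V5 = "e1_glc")
  nets <- lapply(variants, function(id) make_variant(net_full, id))
  names(nets) <- variants
  # species representable in every variant
  common <- names(d$mixing)
  for (nt in nets) {
    ok <- vapply(d$mixing, function(pl) any(pl %in% nt$metabolites$id),
                 logical(1))
    common <- intersect(common, names(d$mixing)[ok])
  }
  d_common <- d
  d_common$mids <- dplyr::filter(d$mids, .data$metabolite %in% common)
  d_common$mixing <- d$mixing[common]

  fits <- list()
  rows <- list()
  for (id in variants) {
    nt <- nets[[id]]
    entry <- entry_of[[id]]
    free <- character(0)
    b <- base
    if (!is.na(entry)) {
      free <- paste0("flux:", entry)
      b$spec <- b$spec[setdiff(names(b$spec), entry)]
    }
    if (id == "V5") {
      free <- c(free, "flux:suc_tono", "flux:inv_c")
      b$spec <- b$spec[setdiff(names(b$spec), c("suc_tono", "inv_c"))]
    } else {
      b$spec <- b$spec[setdiff(names(b$spec), sugar_cycle_ids)]
    }
    b$spec <- b$spec[names(b$spec) %in% names(nt$reactions)]
    fit <- tryCatch(
      fit_variant(nt, d_common, free, b, n_starts = n_starts, seed = seed,
                  upper = if (length(free))
                    stats::setNames(rep(50, length(free)), free) else NULL,
                  rtol = rtol, atol = atol),
      error = function(e) e
    )
    fits[[id]] <- fit
    if (inherits(fit, "error")) {
      rows[[id]] <- tibble::tibble(variant = id, ssr = NA_real_,
                                   entry_flux = NA_real_, n_free = NA_integer_,
                                   failed = TRUE)
    } else {
      ef <- if (!is.na(entry)) unname(fit$par[paste0("flux:", entry)]) else 0
      rows[[id]] <- tibble::tibble(variant = id, ssr = fit$ssr,
                                   entry_flux = ef %||% 0,
                                   n_free = length(fit$free), failed = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  base_ssr <- out$ssr[out$variant == "V0"]
  if (length(base_ssr) == 1L) out$delta_ssr <- out$ssr - base_ssr
  out <- dplyr::arrange(out, .data$ssr)
  attr(out, "fits") <- fits
  class(out) <- c("variant_comparison", class(out))
  out
}

#' Per-species SSR breakdown of a variant comparison
#' @param x A `variant_comparison`.
#' @return Tibble `variant`, `metabolite`, `ssr`.
#' @export
ssr_breakdown <- function(x) {
  fits <- attr(x, "fits")
  purrr::imap_dfr(fits, function(f, id) {
    if (inherits(f, "error")) return(NULL)
    dplyr::mutate(f$ssr_by_species, variant = id, .before = 1)
  })
}
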