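# Nested model selection for polyexponential decay fits: extra sum of
# squares, Holm correction, information criteria, cross-validation.

#' Extra-sum-of-squares F test between nested least-squares fits
#'
#' `F = ((SSR_r - SSR_f) / (p_f - p_r)) / (SSR_f / (n - p_f))`, with the
#' p-value from the F distribution on `(p_f - p_r, n - p_f)` degrees of
#' freedom. A negative numerator (the larger model fitting worse, possible
#' up to optimizer tolerance) is clamped to `F = 0`, `p = 1`.
#'
#' @param reduced,full `exp_fit` objects on the same data; `full` must have
#'   more parameters.
#' @return Tibble with `F`, `df1`, `df2`, `p`.
#' @export
extra_ss_test <- function(reduced, full) {
  if (full$p <= reduced$p) {
    stop("the full model must have more parameters than the reduced model",
         call. = FALSE)
  }
  if (full$n != reduced$n) {
    stop("fits are not on the same data (different n)", call. = FALSE)
  }
  n <- full$n
  if (n <= full$p) stop("no residual degrees of freedom", call. = FALSE)
  df1 <- full$p - reduced$p
  df2 <- n - full$p
  num <- (reduced$ssr - full$ssr) / df1
  den <- full$ssr / df2
  Fv <- if (num <= 0 || den <= 0) 0 else num / den
  tibble::tibble(
    F = Fv, df1 = df1, df2 = df2,
    p = if (Fv == 0) 1 else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  )
}

#' Holm step-down adjustment of p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order).
#' @export
holm_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}

#' Gaussian-likelihood information criteria for a least-squares fit
#'
#' `AIC = n log(SSR/n) + 2q` and `BIC = n log(SSR/n) + q log n`, with
#' `q = p + 1` counting the residual variance as a parameter.
#'
#' @param fit An `exp_fit` (any object with `ssr`, `n`, `p`).
#' @return Tibble with `aic`, `bic`, `q`.
#' @export
information_criteria <- function(fit) {
  n <- fit$n
  q <- fit$p + 1L
  if (n <= fit$p + 1L) {
    stop("too few observations for information criteria", call. = FALSE)
  }
  if (fit$ssr <= 0) {
    warning("SSR is zero; information criteria are -Inf")
    return(tibble::tibble(aic = -Inf, bic = -Inf, q = q))
  }
  tibble::tibble(
    aic = n * log(fit$ssr / n) + 2 * q,
    bic = n * log(fit$ssr / n) + q * log(n),
    q = q
  )
}

#' Leave-one-out cross-validation score of an exponential model
#'
#' Deterministic leave-one-out: each observation is held out in turn, the
#' model is refitted on the rest, and the mean held-out squared prediction
#' error is returned. Folds whose refit fails are skipped with a warning.
#'
#' @param series Data frame with `time_min`, `pct_12c`.
#' @param K,has_constant Model specification.
#' @param n_starts Multistarts per fold (default 10; each fold reuses the
#'   same seed, so the score is reproducible).
#' @param seed Integer seed.
#' @return A list with `score` (mean squared held-out error), `n_folds`,
#'   `skipped`.
#' @export
cross_validate <- function(series, K, has_constant = FALSE, n_starts = 10,
                           seed = 1) {
  n <- nrow(series)
  errs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- series[-i, , drop = FALSE]
    fit <- tryCatch(
      fit_exp_model(train, K, has_constant, n_starts = n_starts, seed = seed),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    pred <- predict(fit, newdata = series[i, , drop = FALSE])
    errs[i] <- (series$pct_12c[i] - pred)^2
  }
  skipped <- sum(is.na(errs))
  if (skipped > 0) {
    warning(skipped, " of ", n, " cross-validation folds failed and were skipped")
  }
  if (skipped == n) stop("all cross-validation folds failed", call. = FALSE)
  list(score = mean(errs, na.rm = TRUE), n_folds = n, skipped = skipped)
}

default_roster <- tibble::tibble(
  model = 1:7,
  name = c("1exp", "1exp+C", "2exp", "2exp+C", "3exp", "3exp+C", "4exp"),
  K = c(1, 1, 2, 2, 3, 3, 4),
  has_constant = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
)

#' Select the number of kinetic components in a decay series
#'
#' Fits the nested roster of polyexponential models (by default 1exp,
#' 1exp+C, 2exp, 2exp+C, 3exp, 3exp+C, 4exp), evaluates four selection
#' criteria - extra-sum-of-squares F tests between consecutive models with
#' Holm correction, AIC, BIC, and leave-one-out cross-validation - and
#' reports the per-criterion verdicts plus a consensus model. The consensus
#' walks up the roster and accepts a model when its Holm-adjusted extra-SS
#' p-value versus the previous model is below `alpha` and at least two of
#' AIC, BIC and CV also improve.
#'
#' @param series Data frame with `time_min`, `pct_12c`.
#' @param roster Model roster tibble (`name`, `K`, `has_constant`).
#' @param seed Integer seed shared by all fits.
#' @param n_starts Multistarts per model fit (default 100).
#' @param cv_starts Multistarts per cross-validation fold (default 10).
#' @param alpha Significance level for the extra-SS ladder (default 0.05).
#' @return A `selection_report` with a per-model `table`, per-criterion
#'   winners, and the consensus model.
#' @export
select_model <- function(series, roster = default_roster, seed = 1,
                         n_starts = 100, cv_starts = 10, alpha = 0.05) {
  m <- nrow(roster)
  fits <- vector("list", m)
  failed <- logical(m)
  for (i in seq_len(m)) {
    fits[[i]] <- tryCatch(
      fit_exp_model(series, roster$K[i], roster$has_constant[i],
                    n_starts = n_starts, seed = seed),
      error = function(e) NULL
    )
    failed[i] <- is.null(fits[[i]])
  }
  if (all(failed)) stop("every model fit failed", call. = FALSE)

  ic <- purrr::map(fits, function(f) {
    if (is.null(f)) tibble::tibble(aic = NA_real_, bic = NA_real_, q = NA)
    else information_criteria(f)
  })
  cv <- purrr::map_dbl(seq_len(m), function(i) {
    if (failed[i]) return(NA_real_)
    tryCatch(
      suppressWarnings(cross_validate(series, roster$K[i],
                                      roster$has_constant[i],
                                      n_starts = cv_starts, seed = seed)$score),
      error = function(e) NA_real_
    )
  })
  p_raw <- rep(NA_real_, m)
  for (i in 2:m) {
    if (!failed[i] && !failed[i - 1L]) {
      p_raw[i] <- extra_ss_test(fits[[i - 1L]], fits[[i]])$p
    }
  }
  p_holm <- rep(NA_real_, m)
  idx <- which(!is.na(p_raw))
  p_holm[idx] <- holm_adjust(p_raw[idx])

  tab <- roster |>
    dplyr::mutate(
      p_params = vapply(fits,
                        function(f) if (is.null(f)) NA_real_ else as.numeric(f$p),
                        numeric(1)),
      ssr = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$ssr,
                   numeric(1)),
      aic = vapply(ic, function(x) x$aic[1], numeric(1)),
      bic = vapply(ic, function(x) x$bic[1], numeric(1)),
      cv = cv,
      p_extra_ss = p_raw,
      p_holm = p_holm
    )

  # a model is "green" when it improves on its predecessor; the selected
  # model is the highest green rung of the ladder
  consensus <- 1L
  extra_ss_pick <- 1L
  for (i in 2:m) {
    if (failed[i] || is.na(p_holm[i])) next
    sig <- p_holm[i] < alpha
    votes <- sum(c(tab$aic[i] < tab$aic[i - 1L],
                   tab$bic[i] < tab$bic[i - 1L],
                   cv[i] < cv[i - 1L]), na.rm = TRUE)
    if (sig) extra_ss_pick <- i
    if (sig && votes >= 2) consensus <- i
  }
  winners <- list(
    extra_ss = roster$name[extra_ss_pick],
    aic = roster$name[which.min(tab$aic)],
    bic = roster$name[which.min(tab$bic)],
    cv = roster$name[which.min(tab$cv)]
  )
  structure(list(
    table = tab,
    fits = fits,
    winners = winners,
    consensus = list(
      model = roster$name[consensus],
      K = roster$K[consensus],
      has_constant = roster$has_constant[consensus]
    ),
    alpha = alpha, seed = seed
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> consensus: ", x$consensus$model, " (",
      x$consensus$K, " exponential term(s)",
      if (x$consensus$has_constant) " + constant", ")\n", sep = "")
  print(dplyr::select(x$table, "name", "p_params", "ssr", "aic", "bic",
                      "cv", "p_holm"))
  cat("criterion winners: ",
      paste(names(x$winners), unlist(x$winners), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname cbclabel-tidiers
#' @export
tidy.selection_report <- function(x, ...) x$table

#' @rdname cbclabel-tidiers
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(consensus = x$consensus$model, K = x$consensus$K,
                 has_constant = x$consensus$has_constant, alpha = x$alpha)
}
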