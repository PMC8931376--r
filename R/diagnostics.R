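# Isotopologue diagnostics: the M0-over-M1 anomaly that signals entry of
# intact unlabeled carbon skeletons.

#' Binomial mass isotopologue distribution
#'
#' The MID expected when every carbon of an n-carbon metabolite is labeled
#' independently with probability `p`: `m_i = choose(n, i) p^i (1-p)^(n-i)`.
#' Under such single-population labeling, `M1/M0 = n p / (1 - p)`; once `p`
#' exceeds `1/(n+1)`, M1 must exceed M0, so a persistent excess of M0 over
#' M1 cannot arise from uniform labeling.
#'
#' @param n Carbon count.
#' @param p Per-carbon 13C probability in `[0, 1]`.
#' @return Numeric vector `m0..mn`.
#' @examples
#' binomial_mid(6, 0.96)  # M1/M0 = 144
#' @export
binomial_mid <- function(n, p) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  stats::dbinom(0:n, n, p)
}

#' Observed versus binomial-predicted M1/M0 ratio
#'
#' Compares the observed `m1/m0` of a MID with the ratio predicted by
#' single-population binomial labeling at a per-carbon enrichment `p_hat`,
#' `n p_hat / (1 - p_hat)`. By default `p_hat` is estimated from the labeled
#' subpopulation (the mean enrichment excluding M0), treating M0 as a
#' potentially distinct unlabeled population; `p_hat_from = "total"` uses
#' the plain mean enrichment instead.
#'
#' @param mid Numeric MID vector `m0..mn`.
#' @param p_hat Optional externally estimated per-carbon enrichment.
#' @param p_hat_from `"labeled"` (default) or `"total"` estimator when
#'   `p_hat` is not given.
#' @param excess_factor Flag threshold: excess when
#'   `observed < predicted / excess_factor` (default 10).
#' @return Tibble with `observed`, `predicted`, `p_hat`, `excess`.
#'   `observed` is `NA` (undefined) when `m0 = 0`.
#' @export
m1_m0_stats <- function(mid, p_hat = NULL, p_hat_from = c("labeled", "total"),
                        excess_factor = 10) {
  p_hat_from <- match.arg(p_hat_from)
  n <- length(mid) - 1L
  if (is.null(p_hat)) {
    p_hat <- mean_enrichment(mid, exclude_m0 = (p_hat_from == "labeled"))
  }
  observed <- if (mid[1] > 0) mid[2] / mid[1] else NA_real_
  predicted <- if (!is.na(p_hat) && p_hat < 1) n * p_hat / (1 - p_hat) else Inf
  tibble::tibble(
    observed = observed,
    predicted = predicted,
    p_hat = p_hat,
    excess = !is.na(observed) & observed < predicted / excess_factor
  )
}

#' Share of a MID's unlabeled carbon carried by the M0 isotopologue
#'
#' If metabolically inactive pools explained residual 12C, the fully
#' unlabeled isotopologue would account for all of it; a small share
#' indicates 12C spread across partially labeled molecules. Computed as
#' `(m0 * n) / sum_i m_i * (n - i)`.
#'
#' @param mid Numeric MID vector `m0..mn`.
#' @return Fraction in `[0, 1]`.
#' @export
m0_share_of_unlabeled <- function(mid) {
  n <- length(mid) - 1L
  i <- seq_along(mid) - 1L
  tot <- sum(mid * (n - i))
  if (tot <= 0) stop("MID carries no 12C", call. = FALSE)
  mid[1] * n / tot
}

#' Isotopologue diagnostic table at one time point
#'
#' One row per metabolite: M0/M1/M2 fractions, the observed and
#' binomial-predicted M1/M0 ratios, the M0 share of total 12C, and the pool
#' size, sorted by the strength of the M0 excess.
#'
#' @param mids Long MID tibble (`metabolite`, `n_carbons`, `time_min`,
#'   `mass`, `fraction`).
#' @param time Requested time (minutes).
#' @param pool_sizes Optional named pool sizes to attach.
#' @param strict Error when the exact time is absent (default); otherwise
#'   the nearest time is used with a warning.
#' @param excess_factor Passed to [m1_m0_stats()].
#' @return A tibble of diagnostic rows.
#' @export
diag_table <- function(mids, time, pool_sizes = NULL, strict = TRUE,
                       excess_factor = 10) {
  if (nrow(mids) == 0L) {
    return(tibble::tibble(
      metabolite = character(0), time_min = numeric(0), m0 = numeric(0),
      m1 = numeric(0), m2 = numeric(0), m1_m0_observed = numeric(0),
      m1_m0_predicted = numeric(0), m0_share_12c = numeric(0),
      pool_size = numeric(0), excess = logical(0)
    ))
  }
  times <- sort(unique(mids$time_min))
  if (!time %in% times) {
    if (strict) {
      stop("time ", time, " min not present in the dataset", call. = FALSE)
    }
    nearest <- times[which.min(abs(times - time))]
    warning("time ", time, " min not present; using nearest time ", nearest)
    time <- nearest
  }
  rows <- mids |>
    dplyr::filter(.data$time_min == time) |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_map(function(g, key) {
      mid <- g$fraction[order(g$mass)]
      st <- m1_m0_stats(mid, excess_factor = excess_factor)
      tibble::tibble(
        metabolite = key$metabolite,
        time_min = time,
        m0 = mid[1], m1 = mid[2],
        m2 = if (length(mid) >= 3) mid[3] else NA_real_,
        m1_m0_observed = st$observed,
        m1_m0_predicted = st$predicted,
        m0_share_12c = tryCatch(m0_share_of_unlabeled(mid),
                                error = function(e) NA_real_),
        pool_size = if (!is.null(pool_sizes) &&
                        key$metabolite %in% names(pool_sizes)) {
          pool_sizes[[key$metabolite]]
        } else {
          NA_real_
        },
        excess = st$excess
      )
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(rows,
                 dplyr::desc(.data$m1_m0_predicted /
                               pmax(.data$m1_m0_observed, 1e-12)))
}
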