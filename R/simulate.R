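#' Fraction of carbon-12 in a mass isotopologue distribution
#'
#' For an n-carbon metabolite with isotopologue fractions `m0..mn`, the
#' percentage of its carbon that is 12C is `100 * sum(m_i * (n - i) / n)`.
#'
#' @param mid Numeric vector of isotopologue fractions `m0..mn`.
#' @return Percentage of 12C (scalar, 0-100).
#' @examples
#' twelve_c_fraction(c(0.25, 0.25, 0.25, 0.25))  # 50 for a 3-carbon species
#' @export
twelve_c_fraction <- function(mid) {
  stopifnot(is.numeric(mid), length(mid) >= 2L)
  n <- length(mid) - 1L
  100 * sum(mid * (n - seq_along(mid) + 1L) / n)
}

#' Per-carbon mean enrichment of a MID
#'
#' @param mid Numeric vector `m0..mn`.
#' @param exclude_m0 Restrict the mean to the labeled subpopulation (drop M0).
#' @return Mean 13C fraction per carbon.
#' @export
mean_enrichment <- function(mid, exclude_m0 = FALSE) {
  n <- length(mid) - 1L
  i <- seq_along(mid) - 1L
  if (exclude_m0) {
    w <- mid
    w[1] <- 0
    if (sum(w) <= 0) return(NA_real_)
    sum(i * w) / (n * sum(w))
  } else {
    sum(i * mid) / n
  }
}

#' Closed-form labeling kinetics of a first-order linear chain
#'
#' For a chain of M well-mixed pools fed by fully labeled substrate, with
#' first-order turnover rates `k[1..M]` (per hour), the 12C fraction of pool
#' j is a j-term polyexponential. This evaluates the exact solution by the
#' partial-fraction recurrence and returns both the coefficients and the
#' evaluated curves.
#'
#' @param rates Positive, pairwise distinct turnover rates `k_j = v / c_j`
#'   (h-1), ordered along the chain.
#' @param times_min Times in minutes at which to evaluate.
#' @return A list with `coefficients` (M x M lower-triangular matrix; row j
#'   holds the weights of `exp(-k_i t)` for pool j) and `values`, a tibble
#'   with `time_min`, `pool`, `pct_12c`.
#' @export
linear_chain_closed_form <- function(rates, times_min) {
  stopifnot(is.numeric(rates), all(rates > 0))
  M <- length(rates)
  if (M >= 2L) {
    gaps <- abs(outer(rates, rates, "-"))
    diag(gaps) <- Inf
    if (min(gaps) < 1e-9 * max(rates)) {
      stop("repeated turnover rates: the distinct-rate closed form does not ",
           "apply (perturb the rates)", call. = FALSE)
    }
  }
  A <- matrix(0, M, M)
  A[1, 1] <- 1
  if (M >= 2L) {
    for (j in 2:M) {
      prev <- A[j - 1L, seq_len(j - 1L)]
      ki <- rates[seq_len(j - 1L)]
      carried <- rates[j] * prev / (rates[j] - ki)
      A[j, seq_len(j - 1L)] <- carried
      A[j, j] <- 1 - sum(carried)
    }
  }
  t_h <- times_min / 60
  vals <- purrr::map_dfr(seq_len(M), function(j) {
    u <- drop(exp(outer(t_h, -rates[seq_len(j)])) %*% A[j, seq_len(j)])
    tibble::tibble(time_min = times_min, pool = j, pct_12c = 100 * u)
  })
  list(coefficients = A, values = vals)
}

binom_mid_vec <- function(n, p) stats::dbinom(0:n, n, p)

# ---------------------------------------------------------------------------
# EMU ODE compilation and integration
# ---------------------------------------------------------------------------

compile_emu_ode <- function(sys, f, pools, source_enrichment, init_q) {
  emus <- sys$emus
  sim <- emus[emus$role == "balanced", ]
  fixed <- emus[emus$role != "balanced", ]

  need_pool <- unique(sim$met)
  missing <- setdiff(need_pool, names(pools))
  if (length(missing) > 0L) {
    stop("pool size missing for metabolite(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(pools[need_pool] <= 0)) {
    stop("pool sizes must be positive for all simulated metabolites",
         call. = FALSE)
  }

  off <- integer(nrow(sim))
  len <- sim$size + 1L
  off[1] <- 0L
  if (nrow(sim) > 1L) off <- cumsum(c(0L, len[-length(len)]))
  sim_idx <- stats::setNames(seq_len(nrow(sim)), sim$key)

  fixed_vals <- numeric(0)
  fixed_off <- integer(nrow(fixed))
  if (nrow(fixed) > 0L) {
    for (i in seq_len(nrow(fixed))) {
      met <- fixed$met[i]
      q <- if (met %in% names(source_enrichment)) {
        source_enrichment[[met]]
      } else {
        init_q
      }
      mid <- binom_mid_vec(fixed$size[i], q)
      fixed_off[i] <- length(fixed_vals)
      fixed_vals <- c(fixed_vals, mid)
    }
  }
  fixed_idx <- stats::setNames(seq_len(nrow(fixed)), fixed$key)

  fb <- forward_backward(f)
  ch_target <- integer(0); ch_flux <- numeric(0)
  ch_src_start <- integer(0); ch_src_count <- integer(0)
  src_kind <- integer(0); src_off <- integer(0); src_len <- integer(0)
  size_of <- stats::setNames(emus$size, emus$key)

  for (ch in sys$channels) {
    fl <- if (ch$dir == "fwd") fb$fwd[[ch$rxn]] else fb$bwd[[ch$rxn]]
    if (fl <= 0) next
    tgt <- ch$target
    if (!tgt %in% names(sim_idx)) next
    ch_target <- c(ch_target, sim_idx[[tgt]] - 1L)
    ch_flux <- c(ch_flux, fl)
    ch_src_start <- c(ch_src_start, length(src_kind))
    ch_src_count <- c(ch_src_count, length(ch$sources))
    for (sk in ch$sources) {
      if (sk %in% names(sim_idx)) {
        i <- sim_idx[[sk]]
        src_kind <- c(src_kind, 0L)
        src_off <- c(src_off, off[i])
        src_len <- c(src_len, len[i])
      } else {
        i <- fixed_idx[[sk]]
        src_kind <- c(src_kind, 1L)
        src_off <- c(src_off, fixed_off[i])
        src_len <- c(src_len, fixed$size[i] + 1L)
      }
    }
  }

  phi <- numeric(nrow(sim))
  for (k in seq_along(ch_target)) {
    phi[ch_target[k] + 1L] <- phi[ch_target[k] + 1L] + ch_flux[k]
  }
  # pools with zero throughput (all channel fluxes zero) simply keep their
  # initial MID: dx/dt = 0 is well defined with phi = 0

  list(
    sim = sim, off = off, len = len,
    pool = unname(pools[sim$met]),
    phi = phi,
    ch_target = ch_target, ch_flux = ch_flux,
    ch_src_start = ch_src_start, ch_src_count = ch_src_count,
    src_kind = src_kind, src_off = src_off, src_len = src_len,
    fixed_vals = fixed_vals,
    n_state = sum(len)
  )
}

#' Simulate transient mass isotopologue distributions
#'
#' Integrates the EMU labeling cascade `dX/dt = (inflow - outflow * X) / c`
#' for a network at metabolic steady state, following a step change of the
#' CO2 feed to the stated 13C enrichment. Time is supplied in minutes
#' (matching data files); fluxes are per hour and pool sizes in umol g-1 FW.
#'
#' @param sys An `emu_system` from [emu_decompose()].
#' @param f A `flux_state`; must satisfy steady state.
#' @param pools Named numeric vector of pool sizes for all simulated
#'   metabolites (umol g-1 FW).
#' @param times_min Numeric vector of output times in minutes, first may be 0.
#' @param input_enrichment 13C fraction of the CO2 feed (default 0.99).
#' @param init `"unlabeled"` (pure 12C start) or `"natural"` (1.1% 13C per
#'   carbon, binomial).
#' @param source_enrichment Optional named per-carbon 13C fractions for
#'   source species; defaults give the CO2 feed (`CO2in`) the input
#'   enrichment and every other source the initial-condition enrichment.
#' @param f_inactive Optional named fractions in `[0, 1)`; the observed MID
#'   of those metabolites is `(1 - f) * simulated + f * initial`.
#' @param rtol,atol Tolerances of the stiff sparse-Jacobian solver (lsodes);
#'   pool turnover times span several orders of magnitude, so a stiff
#'   implicit method is required.
#' @return A tibble (`metabolite`, `n_carbons`, `time_min`, `mass`,
#'   `fraction`) for every observed metabolite of `sys`, in long format.
#' @export
simulate_labeling <- function(sys, f, pools, times_min,
                              input_enrichment = 0.99,
                              init = c("unlabeled", "natural"),
                              source_enrichment = NULL,
                              f_inactive = NULL,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sys, "emu_system"), inherits(f, "flux_state"))
  init <- match.arg(init)
  init_q <- if (init == "natural") 0.011 else 0
  bal <- check_steady_state(sys$network, f)
  if (!all(bal$balanced)) {
    stop("flux state is not at steady state (", sum(!bal$balanced),
         " imbalanced pools)", call. = FALSE)
  }
  if (is.null(source_enrichment)) source_enrichment <- numeric(0)
  if (!"CO2in" %in% names(source_enrichment) &&
      "CO2in" %in% sys$emus$met) {
    source_enrichment <- c(source_enrichment, CO2in = input_enrichment)
  }

  ode <- compile_emu_ode(sys, f, pools, source_enrichment, init_q)

  x0 <- numeric(ode$n_state)
  for (i in seq_len(nrow(ode$sim))) {
    x0[ode$off[i] + seq_len(ode$len[i])] <- binom_mid_vec(ode$sim$size[i], init_q)
  }

  t_h <- sort(unique(c(0, times_min / 60)))
  deriv <- function(t, x, parms) {
    list(emu_deriv_cpp(x, ode$off, ode$len, ode$pool, ode$phi,
                       ode$ch_target, ode$ch_flux,
                       ode$ch_src_start, ode$ch_src_count,
                       ode$src_kind, ode$src_off, ode$src_len,
                       ode$fixed_vals))
  }
  sol <- deSolve::lsodes(x0, t_h, deriv, parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, -1]))) {
    stop("EMU ODE integration failed or produced non-finite state",
         call. = FALSE)
  }
  if (min(sol[, -1]) < -1e-6) {
    stop("simulated MID fraction below -1e-6: integration inaccurate",
         call. = FALSE)
  }

  ncar <- stats::setNames(sys$network$metabolites$n_carbons,
                          sys$network$metabolites$id)
  out <- list()
  for (m in sys$observed) {
    n <- ncar[[m]]
    key <- paste0(m, "|", paste(seq_len(n), collapse = ","))
    i <- match(key, ode$sim$key)
    cols <- 1L + ode$off[i] + seq_len(ode$len[i])
    rows <- match(round(times_min / 60, 12), round(t_h, 12))
    mids <- sol[rows, cols, drop = FALSE]
    mids[mids < 0] <- 0
    mids <- mids / rowSums(mids)
    fi <- if (!is.null(f_inactive) && m %in% names(f_inactive)) {
      f_inactive[[m]]
    } else {
      0
    }
    if (fi > 0) {
      init_mid <- binom_mid_vec(n, init_q)
      mids <- (1 - fi) * mids + fi * matrix(init_mid, nrow(mids), n + 1L,
                                            byrow = TRUE)
    }
    out[[m]] <- tibble::tibble(
      metabolite = m,
      n_carbons = n,
      time_min = rep(times_min, each = n + 1L),
      mass = rep(0:n, times = length(times_min)),
      fraction = as.vector(t(mids))
    )
  }
  dplyr::bind_rows(out)
}

#' Percent-12C time series of simulated or measured MIDs
#'
#' @param mids Long MID tibble (`metabolite`, `n_carbons`, `time_min`,
#'   `mass`, `fraction`).
#' @return A tibble `metabolite`, `time_min`, `pct_12c`.
#' @export
twelve_c_series <- function(mids) {
  mids |>
    dplyr::group_by(.data$metabolite, .data$time_min) |>
    dplyr::summarise(
      pct_12c = twelve_c_fraction(.data$fraction[order(.data$mass)]),
      .groups = "drop"
    )
}

#' Aggregate percent-12C across metabolites
#'
#' Combines the 12C percentage of several metabolites into one series, by
#' default weighting each metabolite by its total carbon (pool size times
#' carbon number), which is how a pooled measurement would average them. An
#' unweighted mean is available with `weighted = FALSE`.
#'
#' @param mids Long MID tibble as returned by [simulate_labeling()].
#' @param metabolites Metabolites to aggregate (must all be present at all
#'   times).
#' @param pool_sizes Named pool sizes, required when `weighted = TRUE`.
#' @param weighted Pool-carbon-weighted mean (default) or plain mean.
#' @return A tibble `time_min`, `pct_12c`.
#' @export
aggregate_12c <- function(mids, metabolites, pool_sizes = NULL,
                          weighted = TRUE) {
  missing <- setdiff(metabolites, unique(mids$metabolite))
  if (length(missing) > 0L) {
    stop("metabolite(s) absent from the dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ser <- twelve_c_series(dplyr::filter(mids, .data$metabolite %in% metabolites))
  n_per <- dplyr::count(ser, .data$metabolite)
  if (length(unique(n_per$n)) != 1L) {
    stop("metabolites do not share a common time grid", call. = FALSE)
  }
  if (weighted) {
    if (is.null(pool_sizes)) {
      stop("pool_sizes required for the weighted aggregate", call. = FALSE)
    }
    ncar <- mids |>
      dplyr::distinct(.data$metabolite, .data$n_carbons)
    w <- stats::setNames(
      unname(pool_sizes[ncar$metabolite]) * ncar$n_carbons,
      ncar$metabolite
    )
    if (any(is.na(w[metabolites]))) {
      stop("pool size missing for an aggregated metabolite", call. = FALSE)
    }
    ser |>
      dplyr::mutate(w = w[.data$metabolite]) |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(pct_12c = sum(.data$w * .data$pct_12c) / sum(.data$w),
                       .groups = "drop")
  } else {
    ser |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(pct_12c = mean(.data$pct_12c), .groups = "drop")
  }
}
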