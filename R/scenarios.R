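# Ground-truth scenario definitions and synthetic dataset generation.

default_times_min <- c(0, 0.5, 1, 2, 2.5, 3, 5, 7, 10, 15, 30, 60, 90, 120)

#' Seven Calvin-Benson cycle intermediates used for the aggregate series
#' @export
cbc_core_species <- c("DHAP", "E4P", "FBP", "GAP", "PGA", "RUBP", "S7P")

# default pool sizes (umol g-1 FW), sized so that the three kinetic tiers of
# the labeling data are well separated: seconds-to-minutes turnover for the
# CBC pools (whole-cycle carbon turnover ~2 min), minutes to tens of minutes
# for cytosolic sugars, and one-to-two-hour turnover for vacuolar sugars so
# that free glucose/fructose label to only ~13/19% by 60 min
default_pools <- c(
  RUBP.p = 0.12, PGA.p = 0.4, GAP.p = 0.02, DHAP.p = 0.15, FBP.p = 0.08,
  F6P.p = 0.15, G6P.p = 0.2, E4P.p = 0.02, XU5P.p = 0.03, R5P.p = 0.03,
  RU5P.p = 0.03, SBP.p = 0.08, S7P.p = 0.15, ADPG.p = 0.02, CO2.p = 0.005,
  `2PG.p` = 0.06, GLY.m = 0.8, SER.m = 1.2, GA.c = 0.04,
  DHAP.c = 0.1, GAP.c = 0.02, FBP.c = 0.04, F6P.c = 0.25, G6P.c = 0.8,
  UDPG.c = 0.25, RU5P.c = 0.01, XU5P.c = 0.01,
  SUC.c = 3, GLC.c = 1.3, FRC.c = 0.8,
  SUC.v = 4, GLC.v = 2.5, FRC.v = 2
)

# large exchange fluxes keep the near-equilibrium reactions (isomerases,
# transketolases, aldolases, the translocators) well mixed, so the cycle
# behaves as one kinetic pool
default_exch <- c(
  tpi_p = 200, rpe_p = 100, rpi = 100, pgi_p = 100, pgi_c = 50, tpi_c = 50,
  fba_p = 50, sba = 50, tk1 = 50, tk2 = 50, tpt = 50, fba_c = 20
)

# measured species -> simulated compartmental pools (mass spectrometry does
# not resolve compartments)
species_pool_map <- list(
  RUBP = "RUBP.p", PGA = "PGA.p", GAP = c("GAP.p", "GAP.c"),
  DHAP = c("DHAP.p", "DHAP.c"), FBP = c("FBP.p", "FBP.c"), E4P = "E4P.p",
  S7P = "S7P.p", R5P = "R5P.p", RU5P = c("RU5P.p", "RU5P.c"),
  XU5P = c("XU5P.p", "XU5P.c"), F6P = c("F6P.p", "F6P.c"),
  G6P = c("G6P.p", "G6P.c"), ADPG = "ADPG.p", UDPG = "UDPG.c",
  `2PG` = "2PG.p", GLY = "GLY.m", SER = "SER.m",
  SUC = c("SUC.c", "SUC.v"), GLC = c("GLC.c", "GLC.v"),
  FRC = c("FRC.c", "FRC.v")
)

# flux specifications per scenario (umol g-1 FW h-1); the remaining fluxes
# follow from steady state
scenario_defs <- list(
  base_no_reentry = list(
    variant = "V0",
    spec = c(rubisco_c = 172, rubisco_o = 50, shunt = 7, adpgs = 6,
             suc_export = 7.5, co2_efflux = 0)
  ),
  glucose_reentry = list(
    variant = "V1",
    spec = c(rubisco_c = 172, rubisco_o = 50, shunt = 7, e1_glc = 1.9,
             adpgs = 6, suc_export = 7.5, co2_efflux = 0)
  ),
  starch_turnover = list(
    variant = "V2",
    spec = c(rubisco_c = 172, rubisco_o = 50, shunt = 7, e2_glc = 0.5,
             adpgs = 6, suc_export = 7.5, co2_efflux = 0)
  ),
  inactive_pools = list(
    variant = "V0",
    spec = c(rubisco_c = 172, rubisco_o = 50, shunt = 7, adpgs = 6,
             suc_export = 7.5, co2_efflux = 0),
    f_inactive = c(GLY.m = 0.3, SER.m = 0.3)
  ),
  final_v5 = list(
    variant = "V5",
    spec = c(rubisco_c = 172, rubisco_o = 50, shunt = 7, e1_glc = 1.9,
             adpgs = 6, suc_export = 7.5, inv_c = 1, suc_tono = 5,
             co2_efflux = 0)
  )
)

#' Ground-truth labeling scenario
#'
#' Builds a fully specified synthetic labeling experiment: a network variant,
#' a steady-state flux truth, pool sizes, the 14-point sampling grid
#' (0-120 min), input enrichment and the measurement-noise model. The
#' `final_v5` defaults carry the headline flux map: carboxylation 172,
#' photorespiratory CO2 release 25, shunt CO2 release 7, unlabeled glucose
#' entry 1.9 umol g-1 FW h-1, with slowly turning vacuolar sugar pools.
#'
#' @param name One of `"base_no_reentry"`, `"glucose_reentry"`,
#'   `"starch_turnover"`, `"inactive_pools"`, `"final_v5"`.
#' @param overrides Named list overriding scenario fields: `spec` (named flux
#'   values, merged), `pools` (merged), `exch` (merged), `times_min`,
#'   `noise_sd`, `input_enrichment`, `f_inactive`, `seed`.
#' @return A `cbc_scenario` object.
#' @export
scenario <- function(name, overrides = list()) {
  if (!name %in% names(scenario_defs)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(scenario_defs), collapse = ", "), call. = FALSE)
  }
  def <- scenario_defs[[name]]
  merge_vec <- function(base, over) {
    if (is.null(over)) return(base)
    base[names(over)] <- over
    base
  }
  spec <- merge_vec(def$spec, overrides$spec)
  pools <- merge_vec(default_pools, overrides$pools)
  exch <- merge_vec(default_exch, overrides$exch)
  f_inactive <- merge_vec(def$f_inactive %||% numeric(0), overrides$f_inactive)

  net <- make_variant(cbc_network(), def$variant)
  present <- names(net$reactions)
  exch <- exch[names(exch) %in% present]
  pools <- pools[names(pools) %in% net$metabolites$id]
  truth <- flux_solve(net, spec, exch = exch)
  bal <- check_steady_state(net, truth)
  if (!all(bal$balanced)) {
    stop("scenario overrides violate steady state", call. = FALSE)
  }

  mix <- species_pool_map |>
    purrr::imap(function(p, sp) p[p %in% net$metabolites$id]) |>
    purrr::compact()
  mix <- mix[vapply(mix, length, integer(1)) > 0L]

  s <- structure(list(
    name = name,
    variant = def$variant,
    network = net,
    spec_fluxes = spec,
    exch = exch,
    truth = truth,
    pools = pools,
    mixing = mix,
    times_min = overrides$times_min %||% default_times_min,
    noise_sd = overrides$noise_sd %||% 0.01,
    input_enrichment = overrides$input_enrichment %||% 0.99,
    init = overrides$init %||% "unlabeled",
    f_inactive = if (length(f_inactive)) f_inactive else NULL,
    seed = overrides$seed %||% 1L
  ), class = "cbc_scenario")
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cbc_scenario <- function(x, ...) {
  cat("<cbc_scenario> ", x$name, " (variant ", x$variant, ")\n", sep = "")
  cat("  fluxes specified:",
      paste(names(x$spec_fluxes), signif(x$spec_fluxes, 4), sep = "=",
            collapse = ", "), "\n")
  cat("  ", length(x$times_min), " time points, noise SD ", x$noise_sd,
      ", feed 13C ", x$input_enrichment, "\n", sep = "")
  invisible(x)
}

# mix compartmental pool MIDs into measured-species MIDs,
# pool-size-proportionally
mix_species_mids <- function(sim, mixing, pools) {
  out <- purrr::imap(mixing, function(pl, sp) {
    w <- pools[pl]
    w <- w / sum(w)
    sub <- sim |>
      dplyr::filter(.data$metabolite %in% pl) |>
      dplyr::mutate(w = w[.data$metabolite]) |>
      dplyr::group_by(.data$time_min, .data$mass) |>
      dplyr::summarise(fraction = sum(.data$w * .data$fraction),
                       n_carbons = .data$n_carbons[1], .groups = "drop")
    tibble::tibble(
      metabolite = sp, n_carbons = sub$n_carbons, time_min = sub$time_min,
      mass = sub$mass, fraction = sub$fraction
    )
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$metabolite, .data$time_min, .data$mass)
}

# species-level pool sizes (sum over mixed compartments)
species_pools <- function(mixing, pools) {
  vapply(mixing, function(pl) sum(pools[pl]), numeric(1))
}

simulate_scenario <- function(s, rtol = 1e-8, atol = 1e-10) {
  sys <- emu_decompose(s$network, unique(unlist(s$mixing)))
  sim <- simulate_labeling(
    sys, s$truth, s$pools, s$times_min,
    input_enrichment = s$input_enrichment, init = s$init,
    f_inactive = s$f_inactive, rtol = rtol, atol = atol
  )
  mix_species_mids(sim, s$mixing, s$pools)
}

#' Add measurement noise to a MID table
#'
#' Independent additive Gaussian noise per isotopologue channel, truncated at
#' zero, with each MID renormalized to sum to one afterwards.
#'
#' @param mids Long MID tibble.
#' @param sd Absolute noise SD in fraction units.
#' @param seed Integer seed.
#' @return The tibble with perturbed `fraction` and an `sd` column.
#' @export
add_mid_noise <- function(mids, sd, seed) {
  set.seed(seed)
  out <- mids
  if (sd > 0) {
    out$fraction <- pmax(out$fraction + stats::rnorm(nrow(out), 0, sd), 0)
    out <- out |>
      dplyr::group_by(.data$metabolite, .data$time_min) |>
      dplyr::mutate(fraction = .data$fraction / sum(.data$fraction)) |>
      dplyr::ungroup()
  }
  out$sd <- max(sd, 1e-4)
  out
}

#' Generate a synthetic labeling dataset with known ground truth
#'
#' Simulates the scenario's mass isotopologue distributions at its sampling
#' times, mixes compartmental pools into measured species, adds truncated
#' Gaussian channel noise, and derives scalar flux measurements
#' (net CO2 assimilation, sucrose and triose export, vo/vc ratio) from the
#' flux truth.
#'
#' @param s A `cbc_scenario`.
#' @param seed Integer seed for the noise draw (default: the scenario's).
#' @param noise_sd Channel noise SD (default: the scenario's; 0 gives the
#'   noise-free dataset with a floor SD retained for weighting).
#' @return A `cbc_dataset`: list with `mids` (noisy, with `sd`),
#'   `mids_noisefree`, `scalars` (tibble `name`, `value`, `sd`), `mixing`,
#'   `pools`, `truth`, `scenario`, `seed`.
#' @export
generate_dataset <- function(s, seed = s$seed, noise_sd = s$noise_sd) {
  stopifnot(inherits(s, "cbc_scenario"))
  clean <- simulate_scenario(s)
  noisy <- add_mid_noise(clean, noise_sd, seed)
  v <- s$truth$net
  get0f <- function(id) if (id %in% names(v)) v[[id]] else 0
  scalars <- tibble::tibble(
    name = c("net_assimilation", "sucrose_export", "triose_export", "vo_vc"),
    value = c(get0f("co2_in") - get0f("co2_efflux"), get0f("suc_export"),
              get0f("triose_efflux"), get0f("rubisco_o") / get0f("rubisco_c")),
    sd = c(4, 0.5, 0.5, 0.02)
  )
  structure(list(
    mids = noisy, mids_noisefree = clean, scalars = scalars,
    mixing = s$mixing, pools = s$pools, truth = s$truth,
    scenario = s, seed = seed
  ), class = "cbc_dataset")
}

#' @export
print.cbc_dataset <- function(x, ...) {
  cat("<cbc_dataset> scenario ", x$scenario$name, ": ",
      length(unique(x$mids$metabolite)), " species x ",
      length(unique(x$mids$time_min)), " times, noise seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Aggregate percent-12C series of the core CBC intermediates
#'
#' @param d A `cbc_dataset`.
#' @param species Species to aggregate (default the seven core CBC
#'   intermediates).
#' @param noisefree Use the noise-free table instead of the noisy one.
#' @param weighted Pool-carbon weighting (default) or plain mean.
#' @return Tibble `time_min`, `pct_12c`.
#' @export
cbc_aggregate_series <- function(d, species = cbc_core_species,
                                 noisefree = FALSE, weighted = TRUE) {
  stopifnot(inherits(d, "cbc_dataset"))
  mids <- if (noisefree) d$mids_noisefree else d$mids
  aggregate_12c(mids, species,
                pool_sizes = species_pools(d$mixing, d$pools),
                weighted = weighted)
}
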