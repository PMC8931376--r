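# File formats: wide MID CSV tables and run configuration.

#' Write a MID time-course table to CSV
#'
#' Wide format: columns `metabolite`, `n_carbons`, `time_min`, `M0..Mk`,
#' `sd_M0..sd_Mk`, with empty cells beyond a metabolite's carbon count.
#' Values are written at full double precision so a write/read round trip
#' is exact.
#'
#' @param mids Long MID tibble (optionally with an `sd` column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mid_csv <- function(mids, path) {
  kmax <- max(mids$n_carbons)
  has_sd <- "sd" %in% names(mids)
  wide <- mids |>
    dplyr::mutate(ch = paste0("M", .data$mass)) |>
    tidyr::pivot_wider(
      id_cols = c("metabolite", "n_carbons", "time_min"),
      names_from = "ch", values_from = "fraction"
    )
  for (k in 0:kmax) {
    nm <- paste0("M", k)
    if (!nm %in% names(wide)) wide[[nm]] <- NA_real_
  }
  wide <- wide[, c("metabolite", "n_carbons", "time_min", paste0("M", 0:kmax))]
  if (has_sd) {
    sds <- mids |>
      dplyr::mutate(ch = paste0("sd_M", .data$mass)) |>
      tidyr::pivot_wider(
        id_cols = c("metabolite", "n_carbons", "time_min"),
        names_from = "ch", values_from = "sd"
      )
    for (k in 0:kmax) {
      nm <- paste0("sd_M", k)
      if (!nm %in% names(sds)) sds[[nm]] <- NA_real_
    }
    wide <- dplyr::left_join(
      wide, sds[, c("metabolite", "time_min", paste0("sd_M", 0:kmax))],
      by = c("metabolite", "time_min")
    )
  }
  num_cols <- setdiff(names(wide), c("metabolite"))
  out <- wide
  for (nm in num_cols) {
    out[[nm]] <- ifelse(is.na(wide[[nm]]), "",
                        sprintf("%.17g", wide[[nm]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a MID time-course table from CSV
#'
#' Reads the wide format written by [write_mid_csv()] and validates it:
#' negative fractions and duplicated (metabolite, time) rows are rejected;
#' MIDs whose sum deviates from 1 by more than `renorm_tol` are rejected,
#' smaller deviations are renormalized with a warning.
#'
#' @param path CSV file path.
#' @param renorm_tol Maximum off-simplex deviation that is silently
#'   renormalized (default `1e-3`).
#' @return Long MID tibble (`metabolite`, `n_carbons`, `time_min`, `mass`,
#'   `fraction`, and `sd` when present).
#' @export
read_mid_csv <- function(path, renorm_tol = 1e-3) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = NA, stringsAsFactors = FALSE)
  need <- c("metabolite", "n_carbons", "time_min", "M0")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("malformed MID CSV header: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw[, c("metabolite", "time_min")])) {
    stop("duplicated (metabolite, time) row(s) in MID table", call. = FALSE)
  }
  m_cols <- grep("^M[0-9]+$", names(raw), value = TRUE)
  sd_cols <- grep("^sd_M[0-9]+$", names(raw), value = TRUE)
  has_sd <- length(sd_cols) > 0L
  rows <- list()
  for (i in seq_len(nrow(raw))) {
    n <- raw$n_carbons[i]
    use <- paste0("M", 0:n)
    frac <- suppressWarnings(as.numeric(raw[i, use]))
    if (anyNA(frac)) {
      stop("row ", i, ": missing isotopologue channel(s) up to M", n,
           call. = FALSE)
    }
    if (any(frac < 0)) {
      stop("row ", i, ": negative isotopologue fraction", call. = FALSE)
    }
    s <- sum(frac)
    if (abs(s - 1) > renorm_tol) {
      stop("row ", i, " (", raw$metabolite[i], ", t=", raw$time_min[i],
           "): MID sums to ", signif(s, 6), ", outside tolerance",
           call. = FALSE)
    }
    if (s != 1) {
      if (abs(s - 1) > 1e-12) {
        warning("row ", i, ": MID renormalized (sum ", signif(s, 8), ")")
      }
      frac <- frac / s
    }
    row <- tibble::tibble(
      metabolite = raw$metabolite[i], n_carbons = n,
      time_min = raw$time_min[i], mass = 0:n, fraction = frac
    )
    if (has_sd) {
      sdv <- suppressWarnings(as.numeric(raw[i, paste0("sd_M", 0:n)]))
      row$sd <- sdv
    }
    rows[[i]] <- row
  }
  dplyr::bind_rows(rows)
}

run_config_defaults <- list(
  seed = NULL,
  polyexp_starts = 100,
  flux_starts = 20,
  resamples = 1000,
  mc_draws = 100,
  rtol = 1e-8,
  atol = 1e-10,
  input_enrichment = 0.99,
  vo_vc = 0.31,
  vo_vc_sd = 0.02,
  noise_sd = 0.01,
  variants = paste0("V", 0:5)
)

#' Read a run configuration (YAML)
#'
#' Fills defaults (100 polyexponential multistarts, 20 flux multistarts,
#' 1000 bootstrap resamples, vo/vc constraint 0.31 with SD 0.02) and rejects
#' unknown keys. A missing seed is drawn at random, recorded in the result,
#' and reported via a message.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(run_config_defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- run_config_defaults
  cfg[names(user)] <- user
  num_keys <- setdiff(names(cfg), c("variants", "seed"))
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L) {
      stop("configuration key '", k, "' must be a single number",
           call. = FALSE)
    }
  }
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(1e6, 1)
    message("no seed configured; drew seed ", cfg$seed)
  }
  structure(cfg, class = "run_config")
}
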