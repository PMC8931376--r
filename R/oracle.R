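#' Brute-force isotopomer simulation (reference implementation)
#'
#' Integrates the full positional-isotopomer state (2^n states per n-carbon
#' pool) of a labeled network. This enumerative simulator is exponential in
#' carbon number and intended for small networks only; it serves as a
#' reference against which the EMU cascade of [simulate_labeling()] can be
#' validated, since both must yield identical mass isotopologue
#' distributions.
#'
#' @inheritParams simulate_labeling
#' @param net A `cbc_network` (all balanced metabolites are simulated).
#' @param max_carbons Guard against accidental use on large networks.
#' @return Long MID tibble with the same shape as [simulate_labeling()].
#' @export
simulate_isotopomers <- function(net, f, pools, times_min,
                                 input_enrichment = 0.99,
                                 init = c("unlabeled", "natural"),
                                 source_enrichment = NULL,
                                 max_carbons = 6L,
                                 rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(net, "cbc_network"), inherits(f, "flux_state"))
  init <- match.arg(init)
  init_q <- if (init == "natural") 0.011 else 0
  mets <- net$metabolites
  bal <- mets[mets$role == "balanced", ]
  if (any(bal$n_carbons > max_carbons)) {
    stop("brute-force isotopomer simulation limited to <= ", max_carbons,
         " carbons", call. = FALSE)
  }
  if (is.null(source_enrichment)) source_enrichment <- numeric(0)
  if (!"CO2in" %in% names(source_enrichment) && "CO2in" %in% mets$id) {
    source_enrichment <- c(source_enrichment, CO2in = input_enrichment)
  }

  iso_dist <- function(n, q) {
    # independent per-carbon labeling; bit i of the pattern = carbon i is 13C
    patterns <- 0:(2^n - 1L)
    vapply(patterns, function(p) {
      bits <- bitwAnd(bitwShiftR(p, 0:(n - 1L)), 1L)
      prod(ifelse(bits == 1L, q, 1 - q))
    }, numeric(1))
  }

  ids <- bal$id
  ncar <- stats::setNames(mets$n_carbons, mets$id)
  off <- stats::setNames(cumsum(c(0L, 2^bal$n_carbons[-nrow(bal)])), ids)
  lens <- stats::setNames(2L^bal$n_carbons, ids)
  n_state <- sum(lens)

  fixed_dist <- list()
  for (m in mets$id[mets$role == "source"]) {
    q <- if (m %in% names(source_enrichment)) source_enrichment[[m]] else init_q
    fixed_dist[[m]] <- iso_dist(ncar[[m]], q)
  }

  fb <- forward_backward(f)
  channels <- list()
  for (r in net$reactions) {
    dirs <- list(list(dir = "fwd", from = r$subs, to = r$prods,
                      flux = fb$fwd[[r$id]]))
    if (r$reversible) {
      dirs <- c(dirs, list(list(dir = "bwd", from = r$prods, to = r$subs,
                                flux = fb$bwd[[r$id]])))
    }
    for (d in dirs) {
      if (d$flux <= 0) next
      for (out in d$to) {
        if (!out$met %in% ids) next
        # which substrate instances feed which product atom
        srcs <- list()
        atom_src <- matrix(0L, nrow = length(out$atoms), ncol = 2)
        for (si in seq_along(d$from)) {
          inst <- d$from[[si]]
          hit <- match(out$atoms, inst$atoms)
          use <- which(!is.na(hit))
          if (length(use) > 0L) {
            srcs[[length(srcs) + 1L]] <- inst$met
            atom_src[use, 1] <- length(srcs)
            atom_src[use, 2] <- hit[use]
          }
        }
        channels[[length(channels) + 1L]] <- list(
          target = out$met, flux = d$flux, srcs = unlist(srcs),
          atom_src = atom_src
        )
      }
    }
  }

  phi <- stats::setNames(numeric(length(ids)), ids)
  for (ch in channels) phi[ch$target] <- phi[ch$target] + ch$flux

  bit <- function(p, i) bitwAnd(bitwShiftR(p, i - 1L), 1L)

  # precompute the product-pattern index for every combination of source
  # patterns, per channel
  for (k in seq_along(channels)) {
    ch <- channels[[k]]
    ns <- vapply(ch$srcs, function(m) ncar[[m]], integer(1))
    combos <- expand.grid(lapply(ns, function(n) 0:(2^n - 1L)),
                          KEEP.OUT.ATTRS = FALSE)
    prod_pat <- integer(nrow(combos))
    for (a in seq_len(nrow(ch$atom_src))) {
      s <- ch$atom_src[a, 1]
      pos <- ch$atom_src[a, 2]
      prod_pat <- prod_pat + bit(combos[[s]], pos) * 2L^(a - 1L)
    }
    channels[[k]]$combos <- as.matrix(combos)
    channels[[k]]$prod_pat <- prod_pat
  }

  deriv <- function(t, x, parms) {
    dx <- numeric(n_state)
    get_dist <- function(m) {
      if (m %in% ids) x[off[[m]] + seq_len(lens[[m]])] else fixed_dist[[m]]
    }
    for (ch in channels) {
      dists <- lapply(ch$srcs, get_dist)
      w <- rep(1, nrow(ch$combos))
      for (s in seq_along(dists)) {
        w <- w * dists[[s]][ch$combos[, s] + 1L]
      }
      inflow <- numeric(2^nrow(ch$atom_src))
      agg <- tapply(w, ch$prod_pat, sum)
      inflow[as.integer(names(agg)) + 1L] <- agg
      i <- off[[ch$target]] + seq_len(lens[[ch$target]])
      dx[i] <- dx[i] + ch$flux * inflow
    }
    for (m in ids) {
      i <- off[[m]] + seq_len(lens[[m]])
      dx[i] <- (dx[i] - phi[[m]] * x[i]) / pools[[m]]
    }
    list(dx)
  }

  x0 <- numeric(n_state)
  for (m in ids) {
    x0[off[[m]] + seq_len(lens[[m]])] <- iso_dist(ncar[[m]], init_q)
  }
  t_h <- sort(unique(c(0, times_min / 60)))
  sol <- deSolve::lsoda(x0, t_h, deriv, parms = NULL, rtol = rtol, atol = atol)

  out <- list()
  for (m in ids) {
    n <- ncar[[m]]
    pat_mass <- vapply(0:(2^n - 1L), function(p) {
      sum(bitwAnd(bitwShiftR(p, 0:(n - 1L)), 1L))
    }, integer(1))
    rows <- match(round(times_min / 60, 12), round(t_h, 12))
    dist <- sol[rows, 1L + off[[m]] + seq_len(lens[[m]]), drop = FALSE]
    mid <- t(apply(dist, 1, function(d) {
      vapply(0:n, function(mass) sum(d[pat_mass == mass]), numeric(1))
    }))
    out[[m]] <- tibble::tibble(
      metabolite = m, n_carbons = n,
      time_min = rep(times_min, each = n + 1L),
      mass = rep(0:n, times = length(times_min)),
      fraction = as.vector(t(mid))
    )
  }
  dplyr::bind_rows(out)
}
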