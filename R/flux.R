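#' Construct a flux state for a network
#'
#' A flux state carries a net flux for every reaction and a non-negative
#' exchange flux for every reversible reaction (all in umol g-1 FW h-1).
#' Forward and backward fluxes are derived as
#' `v_f = max(v_net, 0) + v_exch` and `v_b = v_exch + max(-v_net, 0)`.
#' Irreversible reactions must have `v_net >= 0` and no exchange.
#'
#' @param net A `cbc_network`.
#' @param net_flux Named numeric vector of net fluxes; every reaction of
#'   `net` must be covered.
#' @param exch Named numeric vector of exchange fluxes for (a subset of)
#'   reversible reactions; missing entries default to 0.
#' @return A `flux_state` object with elements `net` and `exch` (both named
#'   over all reactions).
#' @export
flux_state <- function(net, net_flux, exch = NULL) {
  stopifnot(inherits(net, "cbc_network"))
  ids <- names(net$reactions)
  missing <- setdiff(ids, names(net_flux))
  if (length(missing) > 0L) {
    stop("net flux missing for reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- net_flux[ids]
  ex <- stats::setNames(numeric(length(ids)), ids)
  if (!is.null(exch) && length(exch) > 0L) {
    unknown <- setdiff(names(exch), ids)
    if (length(unknown) > 0L) {
      stop("exchange flux for unknown reaction(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ex[names(exch)] <- exch
  }
  rev <- vapply(net$reactions, `[[`, logical(1), "reversible")
  if (any(ex < 0)) stop("exchange fluxes must be >= 0", call. = FALSE)
  if (any(ex[!rev] > 0)) {
    stop("exchange flux set on irreversible reaction(s): ",
         paste(ids[!rev & ex > 0], collapse = ", "), call. = FALSE)
  }
  if (any(v[!rev] < -1e-9)) {
    stop("negative net flux on irreversible reaction(s): ",
         paste(ids[!rev & v < -1e-9], collapse = ", "), call. = FALSE)
  }
  structure(list(net = v, exch = ex), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> ", length(x$net), " reactions; ",
      sum(x$exch > 0), " with nonzero exchange\n", sep = "")
  print(utils::head(tibble::tibble(
    reaction = names(x$net), v_net = unname(x$net), v_exch = unname(x$exch)
  ), 10))
  invisible(x)
}

forward_backward <- function(f) {
  list(
    fwd = pmax(f$net, 0) + f$exch,
    bwd = f$exch + pmax(-f$net, 0)
  )
}

#' Stoichiometric matrix of a network
#'
#' @param net A `cbc_network`.
#' @param balanced_only Keep only rows for balanced metabolites (default).
#' @return A dense numeric matrix, metabolites x reactions, with molecule
#'   counts as coefficients (products positive, substrates negative).
#' @export
stoich_matrix <- function(net, balanced_only = TRUE) {
  mets <- net$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = length(net$reactions),
              dimnames = list(mets, names(net$reactions)))
  for (r in net$reactions) {
    for (inst in r$subs) S[inst$met, r$id] <- S[inst$met, r$id] - 1
    for (inst in r$prods) S[inst$met, r$id] <- S[inst$met, r$id] + 1
  }
  if (balanced_only) {
    S <- S[net$metabolites$role == "balanced", , drop = FALSE]
  }
  S
}

#' Check metabolic steady state of a flux state
#'
#' Computes the net production of every balanced metabolite under the given
#' net fluxes and flags imbalances. Exchange fluxes cancel by construction
#' and do not enter the balance.
#'
#' @param net A `cbc_network`.
#' @param f A `flux_state` (or named numeric vector of net fluxes).
#' @param tol Relative tolerance for flagging (default `1e-6`), scaled by the
#'   largest absolute flux.
#' @return A tibble with `metabolite`, `net_production`, and `balanced`.
#' @export
check_steady_state <- function(net, f, tol = 1e-6) {
  v <- if (inherits(f, "flux_state")) f$net else f
  S <- stoich_matrix(net)
  missing <- setdiff(colnames(S), names(v))
  if (length(missing) > 0L) {
    stop("flux not defined for reaction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  b <- drop(S %*% v[colnames(S)])
  scale <- max(abs(v), 1)
  tibble::tibble(
    metabolite = rownames(S),
    net_production = unname(b),
    balanced = abs(b) <= tol * scale
  )
}

#' Solve for a steady-state flux vector
#'
#' Finds net fluxes satisfying the steady-state balance `S v = 0` for all
#' balanced metabolites while matching a set of specified flux values. The
#' balance is enforced exactly by working in the null space of `S`; the
#' specified values are matched by least squares, and an error is raised if
#' they cannot all be met (inconsistent specification).
#'
#' @param net A `cbc_network`.
#' @param specified Named numeric vector of flux values to impose.
#' @param exch Optional named exchange fluxes passed through to the result.
#' @param tol Consistency tolerance for the specified values.
#' @return A `flux_state`.
#' @export
flux_solve <- function(net, specified, exch = NULL, tol = 1e-6) {
  S <- stoich_matrix(net)
  ids <- colnames(S)
  unknown <- setdiff(names(specified), ids)
  if (length(unknown) > 0L) {
    stop("specified flux for unknown reaction(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  N <- MASS::Null(t(S))
  if (length(N) == 0L) stop("network admits only the zero flux", call. = FALSE)
  E <- matrix(0, nrow = length(specified), ncol = length(ids))
  E[cbind(seq_along(specified), match(names(specified), ids))] <- 1
  A <- E %*% N
  # ridge toward the minimum-norm solution fixes any left-over free directions
  fit <- qr.solve(rbind(A, diag(1e-8, ncol(N))),
                  c(specified, numeric(ncol(N))))
  v <- drop(N %*% fit)
  names(v) <- ids
  resid <- max(abs(v[names(specified)] - specified))
  if (resid > tol * max(1, max(abs(specified)))) {
    stop("specified fluxes are inconsistent with steady state (max deviation ",
         signif(resid, 3), ")", call. = FALSE)
  }
  v[abs(v) < 1e-12] <- 0
  flux_state(net, v, exch = exch)
}

#' Carbon and ATP accounting of the flux map
#'
#' Summarises the carbon economy of a photosynthetic flux map: carbons
#' returned to the cycle by photorespiration (3 per glycerate) and by the
#' G6P shunt (5 per pentose phosphate), the total extra carbons processed per
#' carboxylation, CO2 releases as percentages of net assimilation, and the
#' ATP cost per net CO2 fixed, `3 + 3 * shunt_glucose / net_assimilation`
#' (three ATP per glucose cycled through the shunt).
#'
#' All fluxes in umol g-1 FW h-1. Percentages are reported at full precision;
#' the printed report rounds them to whole percent.
#'
#' @param carboxylation Rubisco carboxylation flux (CO2 fixed gross).
#' @param glycerate_return Glycerate re-entry flux (molecules of glycerate).
#' @param pentose_return Pentose-phosphate import flux into the plastid.
#' @param photoresp_co2 CO2 release by glycine decarboxylation.
#' @param shunt_co2 CO2 release by the G6P shunt.
#' @param shunt_glucose Glucose (hexose-phosphate) flux entering the shunt.
#' @return A `carbon_accounting` tibble (one row) with columns
#'   `net_assimilation`, `carbons_photorespiration`, `carbons_shunt`,
#'   `extra_carbons`, `photoresp_pct_net`, `shunt_pct_net`, `atp_per_net_co2`.
#' @examples
#' carbon_accounting(172, 25, 7, 25, 7, 7)
#' @export
carbon_accounting <- function(carboxylation, glycerate_return, pentose_return,
                              photoresp_co2, shunt_co2, shunt_glucose) {
  vals <- c(carboxylation, glycerate_return, pentose_return,
            photoresp_co2, shunt_co2, shunt_glucose)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals >= 0))
  net <- carboxylation - photoresp_co2 - shunt_co2
  if (net <= 0) stop("net assimilation must be positive", call. = FALSE)
  res <- tibble::tibble(
    net_assimilation = net,
    carbons_photorespiration = 3 * glycerate_return,
    carbons_shunt = 5 * pentose_return,
    extra_carbons = 3 * glycerate_return + 5 * pentose_return,
    photoresp_pct_net = 100 * photoresp_co2 / net,
    shunt_pct_net = 100 * shunt_co2 / net,
    atp_per_net_co2 = 3 + 3 * shunt_glucose / net
  )
  class(res) <- c("carbon_accounting", class(res))
  res
}

#' @export
print.carbon_accounting <- function(x, ...) {
  cat("Carbon accounting (umol g-1 FW h-1)\n")
  cat(sprintf("  net CO2 assimilation:        %.1f\n", x$net_assimilation))
  cat(sprintf("  carbons from photorespiration: %.0f\n", x$carbons_photorespiration))
  cat(sprintf("  carbons from G6P shunt:        %.0f\n", x$carbons_shunt))
  cat(sprintf("  extra carbons per cycle:       %.0f\n", x$extra_carbons))
  cat(sprintf("  photorespiratory CO2 release:  %.0f%% of net\n",
              round(x$photoresp_pct_net)))
  cat(sprintf("  shunt CO2 release:             %.0f%% of net\n",
              round(x$shunt_pct_net)))
  cat(sprintf("  ATP per net CO2:               %.2f\n", x$atp_per_net_co2))
  invisible(x)
}

#' Carbon accounting from a fitted flux state
#'
#' Extracts the canonical fluxes from a flux state on the shipped network
#' (reactions `rubisco_c`, `ga_pga`, `xpt`, `gdc`, `shunt`) and calls
#' [carbon_accounting()].
#'
#' @param net A `cbc_network` (used for validation only).
#' @param f A `flux_state`.
#' @return See [carbon_accounting()].
#' @export
carbon_accounting_fluxes <- function(net, f) {
  stopifnot(inherits(f, "flux_state"))
  need <- c("rubisco_c", "ga_pga", "xpt", "gdc", "shunt")
  missing <- setdiff(need, names(f$net))
  if (length(missing) > 0L) {
    stop("flux state lacks reaction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  carbon_accounting(
    carboxylation = f$net[["rubisco_c"]],
    glycerate_return = f$net[["ga_pga"]],
    pentose_return = f$net[["xpt"]],
    photoresp_co2 = f$net[["gdc"]],
    shunt_co2 = f$net[["shunt"]],
    shunt_glucose = f$net[["shunt"]]
  )
}

#' Fraction of photorespired carbon returned to the cycle
#'
#' Traces carbon atoms from 2-phosphoglycolate through the photorespiratory
#' reactions of the network until they reach 3-phosphoglycerate (returned),
#' CO2, or an external sink (lost), and returns the returned fraction.
#' Atoms are propagated through the atom maps; at each intermediate the
#' unique consuming reaction is applied (an error is raised if the route
#' branches, unless `weights` provides per-reaction flux weights).
#'
#' @param net A `cbc_network` containing a path from a 2-carbon
#'   phosphoglycolate pool (default id `"2PG.p"`) to PGA.
#' @param start Starting metabolite id (default `"2PG.p"`).
#' @param target Re-entry metabolite id (default `"PGA.p"`).
#' @param weights Optional named fluxes used to split branching consumption.
#' @return The returned fraction of carbon (e.g. 0.75 for the canonical path).
#' @export
photorespiration_return_fraction <- function(net, start = "2PG.p",
                                             target = "PGA.p", weights = NULL) {
  stopifnot(inherits(net, "cbc_network"))
  if (!start %in% net$metabolites$id) {
    stop("photorespiratory start pool '", start, "' absent from network",
         call. = FALSE)
  }
  if (!target %in% net$metabolites$id) {
    stop("re-entry pool '", target, "' absent from network", call. = FALSE)
  }
  roles <- stats::setNames(net$metabolites$role, net$metabolites$id)
  is_terminal <- function(m) {
    m == target || roles[[m]] != "balanced" || grepl("^CO2", m)
  }
  # carbon mass per metabolite, starting with the start pool's own carbons
  n0 <- net$metabolites$n_carbons[net$metabolites$id == start]
  # two molecules of a 2-carbon pool make the canonical 4-carbon budget, but
  # the returned *fraction* is independent of the absolute amount
  mass <- stats::setNames(numeric(nrow(net$metabolites)), net$metabolites$id)
  mass[start] <- n0
  total0 <- mass[start]
  returned <- 0
  lost <- 0
  consumers <- function(m) {
    Filter(function(r) any(vapply(r$subs, `[[`, character(1), "met") == m),
           net$reactions)
  }
  visited_guard <- 0L
  while (any(mass > 1e-12)) {
    visited_guard <- visited_guard + 1L
    if (visited_guard > 10000L) {
      stop("atom trace did not terminate (cyclic photorespiratory route?)",
           call. = FALSE)
    }
    m <- names(which(mass > 1e-12))[1]
    amount <- mass[[m]]
    mass[[m]] <- 0
    cons <- consumers(m)
    if (length(cons) == 0L) {
      stop("metabolite '", m, "' on the photorespiratory route has no consumer",
           call. = FALSE)
    }
    if (length(cons) > 1L) {
      if (is.null(weights)) {
        stop("branching consumption of '", m,
             "'; supply `weights` to split the atom trace", call. = FALSE)
      }
      w <- vapply(cons, function(r) weights[[r$id]], numeric(1))
      if (any(is.na(w)) || sum(w) <= 0) {
        stop("weights must cover all consumers of '", m, "'", call. = FALSE)
      }
      w <- w / sum(w)
    } else {
      w <- 1
    }
    for (k in seq_along(cons)) {
      r <- cons[[k]]
      part <- amount * w[k]
      sub_atoms <- unlist(lapply(r$subs[vapply(r$subs, `[[`, character(1), "met") == m],
                                 `[[`, "atoms"))
      n_sub <- length(sub_atoms)
      for (inst in r$prods) {
        frac <- sum(inst$atoms %in% sub_atoms) / n_sub
        if (frac == 0) next
        dest <- inst$met
        if (dest == target) {
          returned <- returned + part * frac
        } else if (is_terminal(dest)) {
          lost <- lost + part * frac
        } else {
          mass[[dest]] <- mass[[dest]] + part * frac
        }
      }
    }
  }
  unname(returned / total0)
}
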