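#' Elementary metabolite unit (EMU) decomposition
#'
#' Decomposes a network into the minimal set of EMUs (metabolite, subset of
#' carbon atoms) required to simulate the full-length mass isotopologue
#' distributions of the observed metabolites. Starting from the observed
#' full-length EMUs, each EMU is traced backwards through every producing
#' reaction (and through the backward direction of reversible reactions);
#' atoms drawn from two or more substrate molecules yield convolution edges.
#'
#' @param net A `cbc_network`.
#' @param observed Character vector of metabolite ids whose full MIDs are
#'   needed.
#' @return An `emu_system`: list with `emus` (tibble: `key`, `met`, `size`),
#'   `channels` (list of production channels: target key, reaction, direction,
#'   source EMU keys or fixed source metabolites), and the originating
#'   network.
#' @export
emu_decompose <- function(net, observed) {
  stopifnot(inherits(net, "cbc_network"))
  mets <- net$metabolites
  missing <- setdiff(observed, mets$id)
  if (length(missing) > 0L) {
    stop("observed metabolite(s) not in network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  role <- stats::setNames(mets$role, mets$id)
  ncar <- stats::setNames(mets$n_carbons, mets$id)
  if (any(role[observed] != "balanced")) {
    stop("observed metabolites must be balanced pools", call. = FALSE)
  }

  emu_key <- function(met, atoms) paste0(met, "|", paste(sort(atoms), collapse = ","))

  # precompute, per metabolite, the list of (reaction, direction, producing
  # instance index) channels that make it
  prod_channels <- list()
  add_pc <- function(met, entry) {
    prod_channels[[met]] <<- c(prod_channels[[met]], list(entry))
  }
  for (r in net$reactions) {
    for (i in seq_along(r$prods)) {
      add_pc(r$prods[[i]]$met,
             list(rxn = r$id, dir = "fwd", out = r$prods[[i]], from = r$subs))
    }
    if (r$reversible) {
      for (i in seq_along(r$subs)) {
        add_pc(r$subs[[i]]$met,
               list(rxn = r$id, dir = "bwd", out = r$subs[[i]], from = r$prods))
      }
    }
  }

  seen <- character(0)
  queue <- lapply(observed, function(m) list(met = m, atoms = seq_len(ncar[[m]])))
  channels <- list()
  emus <- list()

  while (length(queue) > 0L) {
    e <- queue[[1]]
    queue <- queue[-1]
    key <- emu_key(e$met, e$atoms)
    if (key %in% seen) next
    seen <- c(seen, key)
    emus[[key]] <- list(met = e$met, atoms = sort(e$atoms))
    if (role[[e$met]] != "balanced") next  # fixed boundary EMU: no producers

    pcs <- prod_channels[[e$met]]
    if (is.null(pcs) || length(pcs) == 0L) {
      stop("no producing reaction for balanced metabolite '", e$met, "'",
           call. = FALSE)
    }
    for (pc in pcs) {
      if (is.null(pc$out$atoms)) {
        stop("missing atom map for metabolite '", e$met, "' in reaction '",
             pc$rxn, "'", call. = FALSE)
      }
      letters_needed <- pc$out$atoms[e$atoms]
      src <- list()
      for (inst in pc$from) {
        pos <- which(inst$atoms %in% letters_needed)
        if (length(pos) > 0L) {
          src <- c(src, list(list(met = inst$met, atoms = pos)))
        }
      }
      if (sum(vapply(src, function(s) length(s$atoms), integer(1))) !=
          length(letters_needed)) {
        stop("atom map of reaction '", pc$rxn, "' does not cover EMU ", key,
             call. = FALSE)
      }
      src_keys <- vapply(src, function(s) emu_key(s$met, s$atoms), character(1))
      channels[[length(channels) + 1L]] <- list(
        target = key, rxn = pc$rxn, dir = pc$dir, sources = src_keys
      )
      for (s in src) queue <- c(queue, list(s))
    }
  }

  emu_tbl <- tibble::tibble(
    key = names(emus),
    met = vapply(emus, `[[`, character(1), "met"),
    size = vapply(emus, function(e) length(e$atoms), integer(1))
  ) |>
    dplyr::mutate(role = unname(role[.data$met])) |>
    dplyr::arrange(.data$size, .data$key)

  structure(
    list(emus = emu_tbl, channels = channels, network = net,
         observed = observed),
    class = "emu_system"
  )
}

#' @export
print.emu_system <- function(x, ...) {
  cat("<emu_system> ", nrow(x$emus), " EMUs (",
      sum(x$emus$role == "balanced"), " simulated), ",
      length(x$channels), " production channels\n", sep = "")
  print(dplyr::count(x$emus, .data$size))
  invisible(x)
}
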