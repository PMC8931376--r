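#' Parse an atom-mapped reaction network
#'
#' Reads a plain-text network definition with one reaction per line,
#' `id: S1 [+ S2] -> P1 [+ P2] , map ; reversible|irreversible`, where `map`
#' gives one lower-case letter per carbon atom of every substrate and product
#' (e.g. `abcde + f -> fba + cde`). Letters must appear exactly once on each
#' side, so every reaction conserves carbon; the separator between the two
#' sides of the map may be `->` or `:`. Lines starting with `#` are comments.
#'
#' Species carry a compartment suffix `.p` (plastid), `.c` (cytosol),
#' `.m` (mitochondrion) or `.v` (vacuole); untagged species are external.
#' A species that is never produced is classified as a source, one that is
#' never consumed as a sink, and all others are balanced pools that must obey
#' a metabolic steady state.
#'
#' @param text Character scalar (whole document) or character vector of lines.
#' @return A `cbc_network` object: a list with a `metabolites` tibble
#'   (`id`, `n_carbons`, `compartment`, `role`), a `reactions` list of parsed
#'   reactions, and a `reaction_tbl` summary tibble.
#' @examples
#' net <- parse_network(c(
#'   "v1: A -> B , ab -> ab ; irreversible",
#'   "v2: B -> C , ab -> ba ; irreversible"
#' ))
#' net$metabolites
#' @export
parse_network <- function(text) {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (length(keep) == 0L) {
    stop("empty network document: no reactions found", call. = FALSE)
  }

  reactions <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    reactions[[j]] <- parse_reaction_line(lines[i], line = i)
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicated reaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(reactions) <- ids
  build_network(reactions)
}

parse_reaction_line <- function(text, line = NULL) {
  where <- if (!is.null(line)) paste0(" at line ", line) else ""
  txt <- trimws(text)
  m <- regexpr(":", txt, fixed = TRUE)
  if (m < 0) stop("syntax error", where, ": missing ':' after reaction id", call. = FALSE)
  id <- trimws(substr(txt, 1L, m - 1L))
  rest <- substr(txt, m + 1L, nchar(txt))
  if (id == "" || grepl("\\s", id)) {
    stop("syntax error", where, ": bad reaction id", call. = FALSE)
  }

  parts <- strsplit(rest, ";", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("syntax error", where, ": expected ';' before reversibility flag", call. = FALSE)
  }
  rev_flag <- trimws(parts[2])
  if (!rev_flag %in% c("reversible", "irreversible")) {
    stop("syntax error", where, ": reversibility must be 'reversible' or 'irreversible'",
         call. = FALSE)
  }

  eq_map <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  if (length(eq_map) != 2L) {
    stop("syntax error", where, ": expected ',' between equation and atom map", call. = FALSE)
  }

  split_side <- function(s) trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  split_arrow <- function(s, what) {
    sides <- strsplit(s, "->", fixed = TRUE)[[1]]
    if (length(sides) != 2L && what == "map") {
      sides <- strsplit(s, ":", fixed = TRUE)[[1]]
    }
    if (length(sides) != 2L) {
      stop("syntax error", where, ": ", what, " needs exactly one side separator",
           call. = FALSE)
    }
    lapply(sides, split_side)
  }

  eq <- split_arrow(eq_map[1], "equation")
  map <- split_arrow(eq_map[2], "map")
  if (length(eq[[1]]) != length(map[[1]]) || length(eq[[2]]) != length(map[[2]])) {
    stop("atom map mismatch in reaction '", id, "'", where,
         ": species and map group counts differ", call. = FALSE)
  }
  bad <- !grepl("^[a-z]+$", unlist(map))
  if (any(bad)) {
    stop("syntax error", where, ": atom maps must be lower-case letter strings",
         call. = FALSE)
  }

  sub_letters <- strsplit(unlist(map[[1]]), "", fixed = TRUE)
  prod_letters <- strsplit(unlist(map[[2]]), "", fixed = TRUE)
  ls <- unlist(sub_letters)
  lp <- unlist(prod_letters)
  if (anyDuplicated(ls) || anyDuplicated(lp)) {
    stop("atom map error in reaction '", id, "'", where,
         ": a letter appears more than once on one side", call. = FALSE)
  }
  if (length(ls) != length(lp) || !setequal(ls, lp)) {
    stop("atom count mismatch in reaction '", id, "'", where, ": ",
         length(ls), " substrate carbon(s) vs ", length(lp), " product carbon(s)",
         call. = FALSE)
  }

  mk <- function(species, groups) {
    purrr::map2(species, groups, function(s, g) {
      list(met = s, atoms = strsplit(g, "", fixed = TRUE)[[1]])
    })
  }
  list(
    id = id,
    reversible = (rev_flag == "reversible"),
    subs = mk(eq[[1]], map[[1]]),
    prods = mk(eq[[2]], map[[2]])
  )
}

build_network <- function(reactions) {
  all_insts <- purrr::map_dfr(reactions, function(r) {
    tibble::tibble(
      rxn = r$id,
      met = c(
        vapply(r$subs, `[[`, character(1), "met"),
        vapply(r$prods, `[[`, character(1), "met")
      ),
      side = rep(c("sub", "prod"),
                 c(length(r$subs), length(r$prods))),
      n = c(
        vapply(r$subs, function(x) length(x$atoms), integer(1)),
        vapply(r$prods, function(x) length(x$atoms), integer(1))
      )
    )
  })

  nc <- all_insts |>
    dplyr::distinct(.data$met, .data$n)
  dup <- nc$met[duplicated(nc$met)]
  if (length(dup) > 0L) {
    stop("inconsistent carbon count for metabolite(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  produced <- unique(all_insts$met[all_insts$side == "prod"])
  consumed <- unique(all_insts$met[all_insts$side == "sub"])
  mets <- tibble::tibble(id = nc$met, n_carbons = nc$n) |>
    dplyr::mutate(
      compartment = dplyr::if_else(
        grepl("\\.([cpmv])$", .data$id),
        sub("^.*\\.", "", .data$id), NA_character_
      ),
      role = dplyr::case_when(
        .data$id %in% produced & .data$id %in% consumed ~ "balanced",
        .data$id %in% consumed ~ "source",
        TRUE ~ "sink"
      )
    ) |>
    dplyr::arrange(.data$id)

  reaction_tbl <- tibble::tibble(
    id = vapply(reactions, `[[`, character(1), "id"),
    reversible = vapply(reactions, `[[`, logical(1), "reversible"),
    equation = vapply(reactions, format_equation, character(1))
  )

  net <- structure(
    list(metabolites = mets, reactions = reactions, reaction_tbl = reaction_tbl),
    class = "cbc_network"
  )
  check_reachability(net)
  net
}

format_equation <- function(r) {
  side <- function(insts) paste(vapply(insts, `[[`, character(1), "met"), collapse = " + ")
  paste(side(r$subs), "->", side(r$prods))
}

check_reachability <- function(net) {
  sources <- net$metabolites$id[net$metabolites$role == "source"]
  balanced <- net$metabolites$id[net$metabolites$role == "balanced"]
  if (length(balanced) == 0L) return(invisible(net))
  if (length(sources) == 0L) {
    stop("network has no source species feeding its balanced pools", call. = FALSE)
  }
  reach <- sources
  repeat {
    grew <- FALSE
    for (r in net$reactions) {
      subs <- vapply(r$subs, `[[`, character(1), "met")
      prods <- vapply(r$prods, `[[`, character(1), "met")
      if (any(subs %in% reach)) {
        new <- setdiff(prods, reach)
        if (length(new)) { reach <- c(reach, new); grew <- TRUE }
      }
      if (r$reversible && any(prods %in% reach)) {
        new <- setdiff(subs, reach)
        if (length(new)) { reach <- c(reach, new); grew <- TRUE }
      }
    }
    if (!grew) break
  }
  missing <- setdiff(balanced, reach)
  if (length(missing) > 0L) {
    stop("balanced metabolite(s) unreachable from any source: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(net)
}

#' @export
print.cbc_network <- function(x, ...) {
  nb <- sum(x$metabolites$role == "balanced")
  nrev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  cat("<cbc_network> ", length(x$reactions), " reactions, ",
      nb, " balanced metabolites (", nrev, " reversible)\n", sep = "")
  comp <- sort(unique(stats::na.omit(x$metabolites$compartment)))
  cat("compartments:", paste(comp, collapse = ", "), "\n")
  invisible(x)
}

#' Canonical leaf carbon-metabolism network
#'
#' Loads the atom-mapped network shipped with the package: Calvin-Benson cycle
#' and starch synthesis in the plastid, lumped photorespiration, cytosolic
#' sucrose synthesis, the cytosolic G6P shunt with pentose-phosphate return to
#' the plastid, sucrose recycling with vacuolar sugar pools, and the
#' unlabeled-carbon entry reactions used by the model variants.
#'
#' @return A `cbc_network` containing all reactions (all variant groups).
#' @seealso [make_variant()] to select a hypothesis variant's reaction set.
#' @export
cbc_network <- function() {
  path <- system.file("extdata", "cbc_network.txt", package = "cbclabel",
                      mustWork = TRUE)
  parse_network(readLines(path, warn = FALSE))
}

# reaction-id groups used by the variant constructor
variant_entry_ids <- c("e1_glc", "e2_glc", "e3_co2", "e4_tp", "starch_to")
sugar_cycle_ids <- c("inv_c", "hxk", "frk", "suc_tono", "inv_v",
                     "glc_tono", "frc_tono")

#' Build a hypothesis variant of the network
#'
#' Starting from a network containing all candidate reactions, returns the
#' reaction set of one unlabeled-carbon-entry hypothesis:
#' * `V0` - base model: no unlabeled entry, no sucrose recycling;
#' * `V1` - unlabeled glucose enters the cytosolic hexose-phosphate pool;
#' * `V2` - unlabeled glucose enters the plastidic hexose-phosphate pool
#'   (starch-turnover surrogate);
#' * `V3` - unlabeled CO2 is injected into the internal CO2 pool;
#' * `V4` - unlabeled triose phosphate enters the plastid pool;
#' * `V5` - final model: glucose entry plus sucrose recycling
#'   (invertase, hexokinase, fructokinase) and tonoplast transport with
#'   vacuolar sucrose/glucose/fructose pools.
#'
#' Metabolites no longer referenced by any retained reaction are dropped.
#'
#' @param net A `cbc_network` containing the full reaction roster.
#' @param id Variant id, one of `"V0"`..`"V5"`.
#' @return A `cbc_network` with the variant's reactions.
#' @export
make_variant <- function(net, id) {
  stopifnot(inherits(net, "cbc_network"))
  if (!is.character(id) || length(id) != 1L || !id %in% paste0("V", 0:5)) {
    stop("unknown variant id: ", paste(id, collapse = ", "),
         " (expected one of V0..V5)", call. = FALSE)
  }
  keep_entry <- switch(id,
    V0 = character(0),
    V1 = "e1_glc",
    V2 = "e2_glc",
    V3 = "e3_co2",
    V4 = "e4_tp",
    V5 = "e1_glc"
  )
  drop <- setdiff(variant_entry_ids, keep_entry)
  if (id != "V5") drop <- c(drop, sugar_cycle_ids)
  missing_entry <- setdiff(keep_entry, names(net$reactions))
  if (length(missing_entry) > 0L) {
    stop("network lacks entry reaction(s) required by ", id, ": ",
         paste(missing_entry, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(names(net$reactions), drop)
  build_network(net$reactions[keep])
}
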