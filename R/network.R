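#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise
#'   ungroup left_join distinct pull n
#' @importFrom purrr map map_chr map_int map_lgl map_dbl imap keep
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# A reaction network <M, R>: an ordered species vector and a list of
# reactions, each with reactant/product multisets (named integer counts)
# and a positive mass-action rate constant.

new_reaction_network <- function(species, reactions) {
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

validate_network <- function(net) {
  if (anyDuplicated(net$species))
    abort("duplicate species names in network")
  ids <- map_chr(net$reactions, "id")
  if (anyDuplicated(ids))
    abort(paste0("duplicate reaction id: ", ids[duplicated(ids)][1]))
  for (r in net$reactions) {
    unknown <- setdiff(c(names(r$reactants), names(r$products)), net$species)
    if (length(unknown))
      abort(paste0("reaction ", r$id, " references undeclared species: ",
                   paste(unknown, collapse = ", ")))
    if (!is.finite(r$rate) || r$rate <= 0)
      abort(paste0("reaction ", r$id, " has non-positive rate"))
    if (length(r$reactants) == 0 && length(r$products) == 0)
      abort(paste0("reaction ", r$id, " has empty left- and right-hand side"))
  }
  net
}

#' Build a reaction network from reactant/product multisets
#'
#' Constructs a `reaction_network` object, the central data structure of the
#' package: an ordered set of molecular species together with a list of
#' mass-action reactions.  Species names may contain `:`, `/` and `-` (as in
#' `"APC/C:Cdc20"`), but not whitespace, `+`, `;` or `>`.
#'
#' @param reactions A list of reactions.  Each element is a list with fields
#'   `reactants` and `products` (named integer vectors: species name to
#'   stoichiometric coefficient; empty vectors denote inflow/outflow), an
#'   optional `rate` (positive numeric, default 1) and an optional `id`.
#' @param species Optional character vector fixing the species order.  By
#'   default species appear in order of first appearance across reactions.
#' @return A `reaction_network` object.
#' @examples
#' net <- reaction_network(list(
#'   list(reactants = c(KinU = 1), products = c(KinA = 1), rate = 0.01)
#' ))
#' species(net)
#' @export
reaction_network <- function(reactions, species = NULL) {
  reactions <- imap(reactions, function(r, i) {
    list(
      id = r$id %||% paste0("r", i),
      reactants = as_multiset(r$reactants),
      products = as_multiset(r$products),
      rate = r$rate %||% 1
    )
  })
  seen <- unique(unlist(map(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  species <- if (is.null(species)) seen else {
    extra <- setdiff(seen, species)
    if (length(extra))
      abort(paste0("species not declared: ", paste(extra, collapse = ", ")))
    species
  }
  validate_network(new_reaction_network(species %||% character(), reactions))
}

as_multiset <- function(x) {
  if (is.null(x) || length(x) == 0) return(setNames(integer(), character()))
  if (is.null(names(x)) || any(names(x) == ""))
    abort("reactant/product vectors must be named by species")
  x <- x[x > 0]
  storage.mode(x) <- "integer"
  # merge repeated names
  tapply(x, names(x), sum)[unique(names(x))]
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions)
    cat(sprintf("  %-6s %s\n", paste0(r$id, ":"), format_reaction(r)))
  invisible(x)
}

side_to_text <- function(side) {
  if (length(side) == 0) return("")
  paste(ifelse(side > 1, paste(side, names(side)), names(side)),
        collapse = " + ")
}

format_reaction <- function(r) {
  sprintf("%s -> %s ; %s", side_to_text(r$reactants), side_to_text(r$products),
          format(r$rate, digits = 12))
}

#' Species of a reaction network
#'
#' @param net A `reaction_network`.
#' @return Character vector of species names, in network order.
#' @export
species <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  net$species
}

#' Parse a reaction-list document
#'
#' Reads the plain-text `.rn` reaction-list format: one reaction per line,
#' `LHS -> RHS ; rate [; id]`, with species tokens separated by `+`.
#' Stoichiometric coefficients may be written as a prefix integer (`2 A`) or
#' by repetition (`A + A`).  An empty left-hand side denotes an inflow, an
#' empty right-hand side a decay.  `#` starts a comment.  A line
#' `@species a b c` (optional) pre-declares species order.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines, or a file path (when `file = TRUE`).
#' @param file If `TRUE`, `text` is a path to read.
#' @return A `reaction_network`.
#' @examples
#' parse_network("KinU -> KinA ; 0.01")
#' @export
parse_network <- function(text, file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  declared <- character()
  reactions <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "@species")) {
      declared <- c(declared, strsplit(trimws(sub("^@species", "", ln)),
                                       "[[:space:]]+")[[1]])
      next
    }
    if (!grepl("->", ln, fixed = TRUE))
      abort(sprintf("line %d: missing '->' in '%s'", i, ln))
    parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      abort(sprintf("line %d: malformed reaction '%s'", i, ln))
    rhs_rate <- strsplit(parts[2], ";", fixed = TRUE)[[1]]
    if (length(rhs_rate) < 2)
      abort(sprintf("line %d: missing rate in '%s'", i, ln))
    rate <- suppressWarnings(as.numeric(trimws(rhs_rate[2])))
    if (is.na(rate))
      abort(sprintf("line %d: unreadable rate '%s'", i, trimws(rhs_rate[2])))
    if (rate <= 0)
      abort(sprintf("line %d: non-positive rate", i))
    id <- if (length(rhs_rate) >= 3) trimws(rhs_rate[3]) else NULL
    reactions[[length(reactions) + 1L]] <- list(
      reactants = parse_side(parts[1], i),
      products = parse_side(rhs_rate[1], i),
      rate = rate, id = id
    )
  }
  # default ids after parse so numbering matches line order
  reactions <- imap(reactions, function(r, j) {
    r$id <- r$id %||% paste0("r", j); r
  })
  seen <- unique(unlist(map(reactions, function(r)
    c(names(r$reactants), names(r$products)))))
  reaction_network(reactions, species = unique(c(declared, seen)))
}

parse_side <- function(text, lineno) {
  text <- trimws(text)
  if (text == "" || text == "0") return(NULL)
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  out <- integer()
  for (term in terms) {
    if (term == "")
      abort(sprintf("line %d: empty species term", lineno))
    toks <- strsplit(term, "[[:space:]]+")[[1]]
    if (length(toks) == 2 && grepl("^[0-9]+$", toks[1])) {
      coef <- as.integer(toks[1]); name <- toks[2]
    } else if (length(toks) == 1) {
      coef <- 1L; name <- toks
    } else {
      abort(sprintf("line %d: malformed term '%s'", lineno, term))
    }
    if (grepl("[;>[:space:]]", name))
      abort(sprintf("line %d: invalid species name '%s'", lineno, name))
    out[name] <- (if (name %in% names(out)) out[[name]] else 0L) + coef
  }
  out
}

#' Serialise a reaction network to the `.rn` text format
#'
#' The output re-parses to an identical network (same species order,
#' reactions, ids and rates): `parse_network(write_network(net))` is the
#' identity.
#'
#' @param net A `reaction_network`.
#' @param path Optional file path; when given the document is also written
#'   to disk.
#' @return The document as a single string, invisibly when `path` is given.
#' @export
write_network <- function(net, path = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  header <- if (length(net$species))
    paste("@species", paste(net$species, collapse = " ")) else character()
  body <- map_chr(net$reactions, function(r)
    paste(format_reaction(r), r$id, sep = " ; "))
  doc <- paste(c(header, body), collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Stoichiometric matrix of a network
#'
#' Returns the |M| x |R| integer matrix N with `N[i, r]` the net production
#' of species `i` by reaction `r` (products minus reactants).
#'
#' @param net A `reaction_network`.
#' @return Integer matrix with species as row names and reaction ids as
#'   column names.
#' @examples
#' net <- parse_network(c("KinU + O-Mad2 -> KinU + C-Mad2 ; 1"))
#' stoichiometric_matrix(net)
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  N <- matrix(0L, length(net$species), length(net$reactions),
              dimnames = list(net$species, map_chr(net$reactions, "id")))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    N[names(r$reactants), j] <- N[names(r$reactants), j] - r$reactants
    N[names(r$products), j] <- N[names(r$products), j] + r$products
  }
  N
}

#' Remove reactions from a network
#'
#' Used to derive short-timescale ("pro-metaphase") model variants in which
#' slow reactions such as kinetochore attachment are dropped while the
#' species set is kept intact.
#'
#' @param net A `reaction_network`.
#' @param removed_reaction_ids Character vector of reaction ids to drop.
#' @return A `reaction_network` with the same species and the remaining
#'   reactions.
#' @export
restrict <- function(net, removed_reaction_ids) {
  stopifnot(inherits(net, "reaction_network"))
  ids <- map_chr(net$reactions, "id")
  unknown <- setdiff(removed_reaction_ids, ids)
  if (length(unknown))
    abort(paste0("unknown reaction id: ", paste(unknown, collapse = ", ")))
  new_reaction_network(net$species,
                       net$reactions[!ids %in% removed_reaction_ids])
}

#' Tidy a reaction network into one row per reaction
#'
#' @param x A `reaction_network`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `reactants`, `products` (display
#'   strings) and `rate`.
#' @exportS3Method generics::tidy
tidy.reaction_network <- function(x, ...) {
  tibble(
    id = map_chr(x$reactions, "id"),
    reactants = map_chr(x$reactions, function(r) side_to_text(r$reactants)),
    products = map_chr(x$reactions, function(r) side_to_text(r$products)),
    rate = map_dbl(x$reactions, "rate")
  )
}

#' @exportS3Method generics::glance
glance.reaction_network <- function(x, ...) {
  tibble(n_species = length(x$species), n_reactions = length(x$reactions))
}

# ---- internal bitmask helpers shared by the static and stochastic layers ----

# Species subsets are represented as integer bitmasks over the network's
# species order (|M| <= 30).  Reactions are pre-encoded once per network.

net_masks <- function(net) {
  idx <- setNames(seq_along(net$species) - 1L, net$species)
  lhs <- map_int(net$reactions, function(r)
    Reduce(bitwOr, bitwShiftL(1L, idx[names(r$reactants)]), 0L))
  rhs <- map_int(net$reactions, function(r)
    Reduce(bitwOr, bitwShiftL(1L, idx[names(r$products)]), 0L))
  list(idx = idx, lhs = lhs, rhs = rhs,
       full = if (length(idx)) bitwShiftL(1L, length(idx)) - 1L else 0L)
}

set_to_mask <- function(net, members) {
  if (length(members) == 0) return(0L)
  unknown <- setdiff(members, net$species)
  if (length(unknown))
    abort(paste0("unknown species: ", paste(unknown, collapse = ", ")))
  idx <- match(members, net$species) - 1L
  Reduce(bitwOr, bitwShiftL(1L, idx), 0L)
}

mask_to_set <- function(net, mask) {
  net$species[bitwAnd(bitwShiftR(mask, seq_along(net$species) - 1L), 1L) == 1L]
}
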