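# Static chemical organization theory: closure, self-maintenance,
# organization generation/enumeration, Hasse lattice, and filtering by
# "interesting organization" predicates.

#' Reactions that can fire within a species set
#'
#' A reaction fires in `A` when all of its reactants are members of `A`.
#' Inflow reactions (empty left-hand side) always fire.
#'
#' @param net A `reaction_network`.
#' @param A Character vector of species (a subset of `species(net)`).
#' @return Character vector of reaction ids.
#' @export
fireable <- function(net, A) {
  m <- net_masks(net)
  a <- set_to_mask(net, A)
  ids <- map_chr(net$reactions, "id")
  ids[bitwAnd(m$lhs, bitwNot(a)) == 0L]
}

#' Species directly produced by a species set
#'
#' The union of the product sets of all reactions fireable in `A`.
#'
#' @inheritParams fireable
#' @return Character vector of species.
#' @export
directly_produced <- function(net, A) {
  m <- net_masks(net)
  mask_to_set(net, dp_mask(m, set_to_mask(net, A)))
}

dp_mask <- function(m, a) {
  fire <- bitwAnd(m$lhs, bitwNot(a)) == 0L
  Reduce(bitwOr, m$rhs[fire], 0L)
}

closure_mask <- function(m, b) {
  repeat {
    nb <- bitwOr(b, dp_mask(m, b))
    if (nb == b) return(b)
    b <- nb
  }
}

#' Is a species set closed?
#'
#' `A` is closed when every reaction fireable in `A` produces only species
#' of `A`.
#'
#' @inheritParams fireable
#' @return Logical scalar.
#' @export
is_closed <- function(net, A) {
  m <- net_masks(net)
  a <- set_to_mask(net, A)
  bitwAnd(dp_mask(m, a), bitwNot(a)) == 0L
}

#' Closure of a species set
#'
#' The smallest closed superset of `B`, computed by iterating direct
#' production to its fixed point.  Closure is extensive, monotone and
#' idempotent.
#'
#' @param net A `reaction_network`.
#' @param B Character vector of species.
#' @return Character vector of species, in network order.
#' @export
closure <- function(net, B) {
  m <- net_masks(net)
  mask_to_set(net, closure_mask(m, set_to_mask(net, B)))
}

# ---- self-maintenance: linear-programming flux feasibility ----------------

# A is self-maintaining iff a flux vector v exists with v_r > 0 exactly on
# the reactions fireable in A and N v >= 0 on the relevant species rows.
# Strict positivity is encoded as v_r >= 1 (the system is homogeneous, so
# feasibility is scale invariant).  Substituting w = v - 1 >= 0 gives the
# standard-form feasibility problem  N_A w >= -N_A 1,  w >= 0,  solved with
# a Big-M simplex.  For a closed set all species rows can be enforced
# (species outside A have no fireable consumer); for non-closed sets rows
# are restricted to the members of A.

sm_tolerance <- 1e-9

lp_feasible <- function(Nsub) {
  nv <- ncol(Nsub)
  rowsum1 <- as.vector(Nsub %*% rep(1, nv))
  # constraints: -Nsub w <= rowsum1
  res <- tryCatch(
    pracma::linprog(cc = rep(0, nv), A = -Nsub, b = rowsum1,
                    maxiter = 200 + 20 * nv),
    error = function(e) list(errno = -99))
  if (!is.null(res$errno) && res$errno == 1) {
    v <- res$x + 1
    slack <- as.vector(Nsub %*% v)
    if (all(slack >= -sm_tolerance)) return(list(ok = TRUE, v = v))
  }
  list(ok = FALSE, v = NULL)
}

self_maintaining_witness <- function(net, a, N = NULL, m = NULL) {
  m <- m %||% net_masks(net)
  N <- N %||% stoichiometric_matrix(net)
  fire <- which(bitwAnd(m$lhs, bitwNot(a)) == 0L)
  v <- setNames(rep(0, length(net$reactions)), colnames(N))
  if (length(fire) == 0) return(list(ok = TRUE, v = v))
  closed <- bitwAnd(dp_mask(m, a), bitwNot(a)) == 0L
  rows <- if (closed) seq_along(net$species) else
    which(bitwAnd(bitwShiftR(a, seq_along(net$species) - 1L), 1L) == 1L)
  ans <- lp_feasible(N[rows, fire, drop = FALSE])
  if (!ans$ok) return(list(ok = FALSE, v = NULL))
  v[fire] <- ans$v
  list(ok = TRUE, v = v)
}

#' Is a species set self-maintaining?
#'
#' Decides, by linear programming, whether a strictly positive flux over the
#' reactions fireable in `A` exists under which no species of `A` has
#' negative net production.  The empty flux vector certifies any set in
#' which no reaction fires (including the empty set).
#'
#' @inheritParams fireable
#' @param witness If `TRUE`, return the flux witness alongside the verdict.
#' @return Logical scalar, or (with `witness = TRUE`) a list with `ok` and
#'   `v`, the flux vector named by reaction id (`NULL` when infeasible).
#' @export
is_self_maintaining <- function(net, A, witness = FALSE) {
  ans <- self_maintaining_witness(net, set_to_mask(net, A))
  if (witness) ans else ans$ok
}

#' Largest self-maintaining subset generated by iterative removal
#'
#' Repeatedly solves a linear program maximising the minimum net production
#' over the current species set (with fluxes at least 1 on all fireable
#' reactions) and removes every species with negative net production at the
#' optimum, until no removal occurs.  For a self-maintaining input the
#' input is returned unchanged.
#'
#' @inheritParams fireable
#' @return Character vector: a self-maintaining subset of `A`.
#' @export
generate_self_maintaining <- function(net, A) {
  m <- net_masks(net)
  N <- stoichiometric_matrix(net)
  a <- set_to_mask(net, A)
  repeat {
    if (self_maintaining_witness(net, a, N, m)$ok)
      return(mask_to_set(net, a))
    rows <- which(bitwAnd(bitwShiftR(a, seq_along(net$species) - 1L), 1L) == 1L)
    fire <- which(bitwAnd(m$lhs, bitwNot(a)) == 0L)
    drop_rows <- maxmin_negative_rows(N[rows, fire, drop = FALSE])
    if (length(drop_rows) == 0) {
      # fallback: remove species that are strictly consumed by every
      # admissible flux (those with only consuming fireable reactions)
      prod_possible <- rowSums(N[rows, fire, drop = FALSE] > 0) > 0
      cons <- rowSums(N[rows, fire, drop = FALSE] < 0) > 0
      drop_rows <- which(cons & !prod_possible)
      if (length(drop_rows) == 0)
        abort("iterative removal stalled on a non-self-maintaining set")
    }
    drop_mask <- Reduce(bitwOr, bitwShiftL(1L, rows[drop_rows] - 1L), 0L)
    a <- bitwAnd(a, bitwNot(drop_mask))
  }
}

# Solve max t s.t. Nsub(w + 1) >= t, w >= 0, t <= 1; return indices of rows
# with negative value at the optimum (empty when the LP fails).
maxmin_negative_rows <- function(Nsub) {
  nr <- nrow(Nsub); nv <- ncol(Nsub)
  if (nr == 0 || nv == 0) return(integer())
  # variables: w (nv), tp, tn; maximise tp - tn
  A <- cbind(-Nsub, 1, -1)
  b <- as.vector(Nsub %*% rep(1, nv))
  A <- rbind(A, c(rep(0, nv), 1, 0))
  b <- c(b, 1)
  res <- tryCatch(
    pracma::linprog(cc = c(rep(0, nv), 1, -1), A = A, b = b,
                    maximize = TRUE, maxiter = 300 + 20 * nv),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$errno) || res$errno != 1) return(integer())
  v <- res$x[seq_len(nv)] + 1
  val <- as.vector(Nsub %*% v)
  which(val < -sm_tolerance)
}

#' Generate the organization of a species set
#'
#' Alternates closure and self-maintaining generation until a joint fixed
#' point that is both closed and self-maintaining is reached.  In consistent
#' networks one pass suffices; in non-consistent networks the
#' self-maintaining set of a closed set need not be closed, so the
#' alternation continues and the result is flagged.
#'
#' @inheritParams fireable
#' @param B Character vector of species to generate from.
#' @return A list of class `organization` with fields `members` (character,
#'   network order), `flux_witness` (named numeric flux vector), `closed`,
#'   `self_maintaining` (both always `TRUE`) and `consistent_pass` (`FALSE`
#'   when more than one closure/self-maintenance pass was needed).
#' @export
generate_organization <- function(net, B) {
  a <- closure(net, B)
  passes <- 1L
  repeat {
    s <- generate_self_maintaining(net, a)
    if (is_closed(net, s)) {
      w <- is_self_maintaining(net, s, witness = TRUE)
      return(structure(list(members = s, flux_witness = w$v,
                            closed = TRUE, self_maintaining = TRUE,
                            consistent_pass = passes == 1L),
                       class = "organization"))
    }
    a <- closure(net, s)
    passes <- passes + 1L
    if (passes > length(net$species) + 2L)
      abort("organization generation failed to reach a fixed point")
  }
}

#' @export
print.organization <- function(x, ...) {
  cat("<organization> {", paste(x$members, collapse = ", "), "}\n")
  invisible(x)
}

# ---- enumeration ----------------------------------------------------------

# All closed sets of a network.  Two strategies: an exhaustive sweep over
# all 2^|M| subsets (default up to 14 species) and a closure-driven
# exploration growing closed sets species by species from closure(empty)
# upward.  Both return the identical sorted set of masks.
closed_set_masks <- function(net, strategy = c("auto", "exhaustive", "explore")) {
  strategy <- match.arg(strategy)
  m <- net_masks(net)
  ns <- length(net$species)
  if (strategy == "auto")
    strategy <- if (ns <= 14) "exhaustive" else "explore"
  if (strategy == "exhaustive") {
    masks <- 0:m$full
    closed <- rep(TRUE, length(masks))
    for (j in seq_along(m$lhs)) {
      fires <- bitwAnd(masks, m$lhs[j]) == m$lhs[j]
      leaks <- bitwAnd(m$rhs[j], bitwNot(masks)) != 0L
      closed <- closed & !(fires & leaks)
    }
    sort(masks[closed])
  } else {
    seen <- new.env(parent = emptyenv())
    frontier <- closure_mask(m, 0L)
    assign(as.character(frontier), TRUE, envir = seen)
    queue <- list(frontier)
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(ns) - 1L) {
        bit <- bitwShiftL(1L, i)
        if (bitwAnd(cur, bit) != 0L) next
        nxt <- closure_mask(m, bitwOr(cur, bit))
        key <- as.character(nxt)
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          queue[[length(queue) + 1L]] <- nxt
        }
      }
    }
    sort(as.integer(ls(envir = seen)))
  }
}

#' Enumerate all organizations of a network
#'
#' Finds every species subset that is both closed and self-maintaining and
#' assembles them, together with the cover edges of their inclusion order,
#' into an organization lattice (Hasse diagram).  Closed sets are
#' enumerated exhaustively over the subset lattice for networks of at most
#' 14 species and by closure-driven exploration above that; each closed set
#' is then tested for self-maintenance by linear programming.
#'
#' @param net A `reaction_network`.
#' @param max_species Guard on network size (default 25).
#' @param strategy Closed-set enumeration strategy: `"auto"` (default),
#'   `"exhaustive"` or `"explore"`.  Both strategies yield identical
#'   results; the choice only affects running time.
#' @return An `org_lattice`: a list with `organizations` (list of
#'   `organization` objects ordered by size then lexicographically),
#'   `cover_edges` (two-column integer matrix of lattice indices,
#'   smaller -> larger) and the originating `network`.
#' @examples
#' net <- sac_model("model3")
#' enumerate_organizations(net)
#' @export
enumerate_organizations <- function(net, max_species = 25,
                                    strategy = c("auto", "exhaustive", "explore")) {
  stopifnot(inherits(net, "reaction_network"))
  if (length(net$species) > max_species)
    abort(sprintf("network has %d species, above the cap of %d",
                  length(net$species), max_species))
  m <- net_masks(net)
  N <- stoichiometric_matrix(net)
  masks <- closed_set_masks(net, match.arg(strategy))
  orgs <- list()
  for (a in masks) {
    w <- self_maintaining_witness(net, a, N, m)
    if (w$ok) {
      members <- mask_to_set(net, a)
      orgs[[length(orgs) + 1L]] <- structure(
        list(members = members, flux_witness = w$v, closed = TRUE,
             self_maintaining = TRUE, consistent_pass = TRUE, mask = a),
        class = "organization")
    }
  }
  orgs <- orgs[order(map_int(orgs, function(o) length(o$members)),
                     map_chr(orgs, function(o) paste(sort(o$members),
                                                     collapse = "\r")))]
  structure(list(organizations = orgs,
                 cover_edges = hasse_edges(map_int(orgs, "mask")),
                 network = net),
            class = "org_lattice")
}

# Transitive reduction of the inclusion order among organization masks.
hasse_edges <- function(masks) {
  n <- length(masks)
  edges <- matrix(integer(), 0, 2, dimnames = list(NULL, c("from", "to")))
  if (n < 2) return(edges)
  sub <- outer(masks, masks, function(a, b)
    bitwAnd(a, bitwNot(b)) == 0L) & outer(masks, masks, "!=")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!sub[i, j]) next
    if (any(sub[i, ] & sub[, j])) next  # an intermediate organization exists
    edges <- rbind(edges, c(i, j))
  }
  edges
}

#' @export
print.org_lattice <- function(x, ...) {
  cat(sprintf("<org_lattice> %d organizations, %d cover edges\n",
              length(x$organizations), nrow(x$cover_edges)))
  for (o in x$organizations)
    cat("  {", paste(o$members, collapse = ", "), "}\n")
  invisible(x)
}

#' Tidy an organization lattice into one row per organization
#'
#' @param x An `org_lattice`.
#' @param ... Unused.
#' @return A tibble with columns `organization` (index), `size`, `species`
#'   (comma-separated members) and `members` (list column).
#' @exportS3Method generics::tidy
tidy.org_lattice <- function(x, ...) {
  tibble(
    organization = seq_along(x$organizations),
    size = map_int(x$organizations, function(o) length(o$members)),
    species = map_chr(x$organizations, function(o)
      paste(o$members, collapse = ", ")),
    members = map(x$organizations, "members")
  )
}

#' @exportS3Method generics::glance
glance.org_lattice <- function(x, ...) {
  tibble(n_organizations = length(x$organizations),
         n_cover_edges = nrow(x$cover_edges),
         n_species = length(x$network$species))
}

# ---- interesting-organization predicates ----------------------------------

#' Parse a boolean species-presence predicate
#'
#' Grammar: `expr := term (OR term)*`, `term := factor (AND factor)*`,
#' `factor := species | "(" expr ")"`.  Atoms are case-sensitive species
#' names; with a network supplied, unknown atoms are reported with their
#' position in the input.
#'
#' @param text Predicate string, e.g.
#'   `"(KinA OR KinU) AND (Activator OR Inhibitor)"`.
#' @param net Optional `reaction_network` used to validate atoms.
#' @return An `org_predicate` object; evaluate with [predicate_holds()].
#' @export
parse_predicate <- function(text, net = NULL) {
  toks <- tokenize_predicate(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  ast <- parse_expr(st)
  if (st$pos <= nrow(st$toks))
    abort(sprintf("predicate syntax error at position %d: unexpected '%s'",
                  st$toks$at[st$pos], st$toks$token[st$pos]))
  atoms <- predicate_atoms(ast)
  if (!is.null(net)) {
    bad <- setdiff(atoms, net$species)
    if (length(bad)) {
      at <- st$toks$at[match(bad[1], st$toks$token)]
      abort(sprintf("unknown species '%s' at position %d", bad[1], at))
    }
  }
  structure(list(ast = ast, atoms = atoms, text = text),
            class = "org_predicate")
}

tokenize_predicate <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) abort("empty predicate")
  tibble(token = regmatches(text, gregexpr(pat, text))[[1]],
         at = as.integer(m))
}

peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$token[st$pos] else NA
advance <- function(st) st$pos <- st$pos + 1L

parse_expr <- function(st) {
  terms <- list(parse_term(st))
  while (!is.na(peek(st)) && peek(st) == "OR") {
    advance(st)
    terms[[length(terms) + 1L]] <- parse_term(st)
  }
  if (length(terms) == 1) terms[[1]] else list(op = "or", args = terms)
}

parse_term <- function(st) {
  factors <- list(parse_factor(st))
  while (!is.na(peek(st)) && peek(st) == "AND") {
    advance(st)
    factors[[length(factors) + 1L]] <- parse_factor(st)
  }
  if (length(factors) == 1) factors[[1]] else list(op = "and", args = factors)
}

parse_factor <- function(st) {
  tok <- peek(st)
  if (is.na(tok))
    abort("predicate syntax error: unexpected end of input")
  if (tok == "(") {
    advance(st)
    inner <- parse_expr(st)
    if (is.na(peek(st)) || peek(st) != ")")
      abort(sprintf("predicate syntax error: missing ')' near position %d",
                    st$toks$at[min(st$pos, nrow(st$toks))]))
    advance(st)
    return(inner)
  }
  if (tok %in% c("AND", "OR", ")"))
    abort(sprintf("predicate syntax error at position %d: unexpected '%s'",
                  st$toks$at[st$pos], tok))
  advance(st)
  list(op = "atom", name = tok)
}

predicate_atoms <- function(ast) {
  if (ast$op == "atom") return(ast$name)
  unique(unlist(map(ast$args, predicate_atoms)))
}

#' Evaluate a predicate on a species set
#'
#' @param pred An `org_predicate` from [parse_predicate()].
#' @param members Character vector of present species.
#' @return Logical scalar.
#' @export
predicate_holds <- function(pred, members) {
  stopifnot(inherits(pred, "org_predicate"))
  eval_pred(pred$ast, members)
}

eval_pred <- function(ast, members) {
  switch(ast$op,
         atom = ast$name %in% members,
         and = all(map_lgl(ast$args, eval_pred, members = members)),
         or = any(map_lgl(ast$args, eval_pred, members = members)))
}

#' @export
print.org_predicate <- function(x, ...) {
  cat("<org_predicate>", x$text, "\n")
  invisible(x)
}

#' Filter the interesting organizations of a lattice
#'
#' Applies a domain-knowledge boolean constraint over species presence to
#' the organizations of a lattice, preserving lattice order.
#'
#' @param lattice An `org_lattice`.
#' @param pred An `org_predicate` or a predicate string.
#' @return The sub-list of `organization` objects whose member sets satisfy
#'   the predicate.
#' @examples
#' lat <- enumerate_organizations(sac_model("model3"))
#' filter_interesting(lat, sac_predicate("model3"))
#' @export
filter_interesting <- function(lattice, pred) {
  stopifnot(inherits(lattice, "org_lattice"))
  if (is.character(pred)) pred <- parse_predicate(pred, lattice$network)
  bad <- setdiff(pred$atoms, lattice$network$species)
  if (length(bad))
    abort(paste0("predicate names unknown species: ",
                 paste(bad, collapse = ", ")))
  keep(lattice$organizations, function(o) predicate_holds(pred, o$members))
}

# ---- exports ---------------------------------------------------------------

#' Export an organization lattice
#'
#' @param lattice An `org_lattice`.
#' @param path Output file path.
#' @param format `"json"` (organizations as sorted name arrays plus cover
#'   edges) or `"dot"` (Graphviz source for the Hasse diagram).
#' @return `path`, invisibly.
#' @export
export_lattice <- function(lattice, path, format = c("json", "dot")) {
  format <- match.arg(format)
  orgs <- map(lattice$organizations, function(o) sort(o$members))
  if (format == "json") {
    jsonlite::write_json(
      list(organizations = orgs,
           cover_edges = if (nrow(lattice$cover_edges)) lattice$cover_edges
                         else matrix(integer(), 0, 2)),
      path, auto_unbox = FALSE)
  } else {
    lab <- map_chr(orgs, function(s)
      if (length(s)) paste(s, collapse = "\\n") else "{}")
    lines <- c("digraph organizations {",
               "  rankdir=BT;",
               sprintf("  n%d [shape=box, label=\"%s\"];",
                       seq_along(orgs), lab),
               if (nrow(lattice$cover_edges))
                 sprintf("  n%d -> n%d;", lattice$cover_edges[, 1],
                         lattice$cover_edges[, 2]),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Plot an organization lattice as a Hasse diagram
#'
#' @param object An `org_lattice`.
#' @param ... Unused.
#' @return A ggplot object: organizations arranged by size (bottom to top)
#'   with inclusion cover edges.
#' @exportS3Method ggplot2::autoplot
autoplot.org_lattice <- function(object, ...) {
  td <- tidy(object)
  td <- td |>
    group_by(.data$size) |>
    mutate(xpos = seq_len(n()) - (n() + 1) / 2) |>
    ungroup()
  td$label <- ifelse(td$species == "", "{}", gsub(", ", "\n", td$species))
  ed <- as_tibble(object$cover_edges)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$xpos, y = .data$size))
  if (nrow(ed)) {
    seg <- tibble(x = td$xpos[ed$from], y = td$size[ed$from],
                  xend = td$xpos[ed$to], yend = td$size[ed$to])
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$xend, yend = .data$yend),
      colour = "grey60")
  }
  p + ggplot2::geom_label(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_y_continuous(breaks = unique(td$size)) +
    ggplot2::labs(x = NULL, y = "organization size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
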