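# Bounded-population continuous-time Markov chain of a reaction network,
# SCC/BSCC/good-SCC decomposition, discrete organizations, expected leaving
# times and the coarse-grained chain over present-species blocks.

#' Build the bounded-population CTMC of a network
#'
#' The state space is every population count vector `q` over the species
#' with total count at most `N_max`.  A reaction `r` with reactant counts
#' `R` and product counts `P` induces a transition `q -> q - R + P`
#' whenever `q >= R` componentwise and the target total stays within the
#' cap, at mass-action rate `lambda_r * prod_s q(s)^(R(s))` (falling
#' factorials for coefficients above one).  Rates of parallel reactions
#' between the same state pair accumulate.
#'
#' @param net A `reaction_network`.
#' @param N_max Positive integer molecule cap.
#' @param initial Optional named integer vector of initial counts (the
#'   single initial state `Q0`); defaults to the all-zero state.
#' @param max_states Guard on state-space size (default 2e6).
#' @return A `ctmc` object: list with `network`, `N_max`, `states` (integer
#'   matrix, one row per state, lexicographically ordered so state ids are
#'   stable), `initial` (state id), and `transitions` (tibble with `from`,
#'   `to`, `reaction`, `rate`).
#' @examples
#' mc <- build_ctmc(sac_model("model3"), N_max = 2)
#' nrow(mc$states)
#' @export
build_ctmc <- function(net, N_max, initial = NULL, max_states = 2e6) {
  stopifnot(inherits(net, "reaction_network"), N_max >= 1)
  ns <- length(net$species)
  n_states <- choose(N_max + ns, ns)
  if (n_states > max_states)
    abort(sprintf("state space has %.0f states, above the cap of %.0f",
                  n_states, max_states))
  states <- compositions_upto(ns, N_max)
  colnames(states) <- net$species
  key <- apply(states, 1, paste, collapse = ",")
  index <- setNames(seq_len(nrow(states)), key)

  R <- matrix(0L, length(net$reactions), ns,
              dimnames = list(NULL, net$species))
  P <- R
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    R[j, names(r$reactants)] <- r$reactants
    P[j, names(r$products)] <- r$products
  }
  rates <- map_dbl(net$reactions, "rate")
  ids <- map_chr(net$reactions, "id")

  from <- integer(); to <- integer(); rx <- character(); rt <- numeric()
  for (j in seq_along(net$reactions)) {
    ok <- rep(TRUE, nrow(states))
    for (s in which(R[j, ] > 0)) ok <- ok & states[, s] >= R[j, s]
    if (!any(ok)) next
    tgt <- sweep(states[ok, , drop = FALSE], 2, P[j, ] - R[j, ], "+")
    within <- rowSums(tgt) <= N_max
    if (!any(within)) next
    src <- which(ok)[within]
    tgt <- tgt[within, , drop = FALSE]
    # mass-action propensity: falling factorial per reactant coefficient
    prop <- rep(rates[j], length(src))
    for (s in which(R[j, ] > 0)) for (k in seq_len(R[j, s]) - 1L)
      prop <- prop * (states[src, s] - k)
    from <- c(from, src)
    to <- c(to, index[apply(tgt, 1, paste, collapse = ",")])
    rx <- c(rx, rep(ids[j], length(src)))
    rt <- c(rt, prop)
  }
  keep_tr <- rt > 0
  init_id <- if (is.null(initial)) index[[paste(rep(0L, ns), collapse = ",")]]
  else {
    q0 <- rep(0L, ns); names(q0) <- net$species
    q0[names(initial)] <- as.integer(initial)
    if (sum(q0) > N_max) abort("initial counts exceed N_max")
    index[[paste(q0, collapse = ",")]]
  }
  structure(list(network = net, N_max = N_max, states = states,
                 initial = init_id,
                 transitions = tibble(from = from[keep_tr], to = to[keep_tr],
                                      reaction = rx[keep_tr],
                                      rate = rt[keep_tr])),
            class = "ctmc")
}

# All non-negative integer vectors of length ns with sum <= cap, in
# lexicographic order (deterministic, stable state ids).
compositions_upto <- function(ns, cap) {
  if (ns == 1) return(matrix(0:cap, ncol = 1))
  parts <- map(0:cap, function(first) {
    rest <- compositions_upto(ns - 1, cap - first)
    cbind(first, rest, deparse.level = 0)
  })
  do.call(rbind, parts)
}

#' @export
print.ctmc <- function(x, ...) {
  cat(sprintf("<ctmc> %d states (N_max = %d), %d transitions, %d species\n",
              nrow(x$states), x$N_max, nrow(x$transitions),
              length(x$network$species)))
  invisible(x)
}

# Present-species mask per state (phi).
state_phi <- function(ctmc) {
  ns <- ncol(ctmc$states)
  phi <- integer(nrow(ctmc$states))
  for (s in seq_len(ns))
    phi <- bitwOr(phi, bitwShiftL(as.integer(ctmc$states[, s] > 0), s - 1L))
  phi
}

#' Species present in a state
#'
#' @param ctmc A `ctmc`.
#' @param state State id (row index into `ctmc$states`).
#' @return Character vector of species with positive count.
#' @export
phi <- function(ctmc, state) {
  colnames(ctmc$states)[ctmc$states[state, ] > 0]
}

#' Strongly connected component decomposition of a CTMC
#'
#' Partitions the state space into SCCs of the transition graph, flags the
#' bottom components (no transition leaving the component) and records each
#' component's species footprint (union of present species over its
#' states).
#'
#' @param ctmc A `ctmc`.
#' @return An `scc_decomposition`: list with `membership` (component id per
#'   state) and `components`, a tibble with `component`, `n_states`,
#'   `bottom` and `footprint` (list column of species).
#' @export
scc_decomposition <- function(ctmc) {
  n <- nrow(ctmc$states)
  g <- igraph::graph_from_edgelist(
    cbind(ctmc$transitions$from, ctmc$transitions$to), directed = TRUE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g, mode = "strong")
  membership <- as.integer(comp$membership)
  leaving <- membership[ctmc$transitions$from] != membership[ctmc$transitions$to]
  bottom <- !(seq_len(comp$no) %in% membership[ctmc$transitions$from[leaving]])
  phis <- state_phi(ctmc)
  foot_mask <- map_int(seq_len(comp$no), function(k)
    Reduce(bitwOr, phis[membership == k], 0L))
  net <- ctmc$network
  structure(list(
    membership = membership,
    components = tibble(
      component = seq_len(comp$no),
      n_states = as.integer(tabulate(membership, comp$no)),
      bottom = bottom,
      footprint_mask = foot_mask,
      footprint = map(foot_mask, function(mk) mask_to_set(net, mk)))),
    class = "scc_decomposition")
}

#' @export
print.scc_decomposition <- function(x, ...) {
  cat(sprintf("<scc_decomposition> %d components (%d bottom)\n",
              nrow(x$components), sum(x$components$bottom)))
  invisible(x)
}

#' Good strongly connected components
#'
#' A component `T` is good when every reaction whose reactants all appear
#' in the footprint of `T` labels at least one transition between two
#' states of `T` (any internal transition of an SCC lies on a cycle).
#' Every bottom component is good.
#'
#' @param decomp An `scc_decomposition`.
#' @param ctmc The `ctmc` it was computed from.
#' @return Integer vector of good component ids.
#' @export
good_sccs <- function(decomp, ctmc) {
  m <- net_masks(ctmc$network)
  ids <- map_chr(ctmc$network$reactions, "id")
  tr <- ctmc$transitions
  internal <- decomp$membership[tr$from] == decomp$membership[tr$to]
  keep(decomp$components$component, function(k) {
    foot <- decomp$components$footprint_mask[k]
    possible <- ids[bitwAnd(m$lhs, bitwNot(foot)) == 0L]
    fired <- unique(tr$reaction[internal & decomp$membership[tr$from] == k])
    all(possible %in% fired)
  }) |> as.integer()
}

#' Discrete organizations of a bounded-population CTMC
#'
#' The footprint of every bottom SCC is a discrete organization (its states
#' are internal generators of it, even when the population cap truncates
#' reactions so that the footprint is not closed in the static sense).
#' Additionally, every good non-bottom SCC whose footprint is a closed set
#' contributes its footprint.  Footprints are deduplicated across
#' components, and each discrete organization carries its internal
#' generators: the union of member states of the contributing components.
#'
#' @param ctmc A `ctmc`.
#' @param decomp Optional precomputed `scc_decomposition`.
#' @return A tibble with `members` (list column of species vectors),
#'   `species` (display string) and `internal_generators` (list column of
#'   state ids), ordered by footprint size then lexicographically.
#' @examples
#' mc <- build_ctmc(sac_model("model3"), N_max = 3)
#' discrete_organizations(mc)$species
#' @export
discrete_organizations <- function(ctmc, decomp = scc_decomposition(ctmc)) {
  net <- ctmc$network
  good <- good_sccs(decomp, ctmc)
  rows <- decomp$components
  closed <- map_lgl(rows$footprint, function(f) is_closed(net, f))
  keep_comp <- rows$bottom | (rows$component %in% good & closed)
  rows <- rows[keep_comp, ]
  if (nrow(rows) == 0)
    return(tibble(members = list(), species = character(),
                  internal_generators = list()))
  key <- map_chr(rows$footprint, paste, collapse = "\r")
  out <- tibble(key = key, comp = rows$component, members = rows$footprint)
  out <- out |>
    group_by(.data$key) |>
    summarise(members = .data$members[1],
              internal_generators = list(sort(which(
                decomp$membership %in% .data$comp))),
              .groups = "drop")
  out$species <- map_chr(out$members, function(s)
    paste(s, collapse = ", "))
  out$size <- map_int(out$members, length)
  out <- arrange(out, .data$size, .data$species)
  select(out, "members", "species", "internal_generators")
}

#' Check whether a state is an internal generator of a species set
#'
#' Test oracle implementing the literal definition: the state's reachable
#' set must have footprint `D`, and a firing sequence covering every
#' eventually-fireable reaction must return all species of `D` to at least
#' their starting counts.  The sequence search is a bounded breadth-first
#' search over composed firings; exceeding the budget raises an error
#' rather than silently answering.
#'
#' @param ctmc A `ctmc`.
#' @param state State id.
#' @param D Character vector of species.
#' @param budget Maximum sequence length (default `4 * N_max * |R_q|`).
#' @return Logical scalar.
#' @export
is_internal_generator <- function(ctmc, state, D, budget = NULL) {
  net <- ctmc$network
  acc <- reachable_states(ctmc, state)
  phis <- state_phi(ctmc)
  foot <- Reduce(bitwOr, phis[acc], 0L)
  if (foot != set_to_mask(net, D)) return(FALSE)
  # reactions that eventually fire from this state
  tr <- ctmc$transitions
  rq <- unique(tr$reaction[tr$from %in% acc])
  if (length(rq) == 0) return(TRUE)  # empty sequence qualifies
  budget <- budget %||% (4L * ctmc$N_max * length(rq))
  q0 <- ctmc$states[state, ]
  didx <- match(D, colnames(ctmc$states))
  # BFS over (state, set of reactions fired so far); success when all of
  # rq fired and counts on D are back at or above q0.
  start_key <- paste(state, "", sep = "|")
  seen <- new.env(parent = emptyenv())
  assign(start_key, TRUE, envir = seen)
  frontier <- list(list(s = state, fired = character()))
  steps <- 0L
  by_from <- split(seq_len(nrow(tr)), tr$from)
  repeat {
    if (length(frontier) == 0) return(FALSE)
    steps <- steps + 1L
    if (steps > budget)
      abort("internal-generator search budget exceeded")
    nxt <- list()
    for (nd in frontier) {
      for (e in by_from[[as.character(nd$s)]] %||% integer()) {
        s2 <- tr$to[e]
        fired2 <- union(nd$fired, tr$reaction[e])
        if (setequal(fired2, rq) &&
            all(ctmc$states[s2, didx] >= q0[didx]))
          return(TRUE)
        key <- paste(s2, paste(sort(fired2), collapse = ","), sep = "|")
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- list(s = s2, fired = fired2)
        }
      }
    }
    frontier <- nxt
  }
}

reachable_states <- function(ctmc, state) {
  n <- nrow(ctmc$states)
  g <- igraph::graph_from_edgelist(
    cbind(ctmc$transitions$from, ctmc$transitions$to), directed = TRUE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  sort(as.integer(igraph::subcomponent(g, state, mode = "out")))
}

#' Partition CTMC states by present-species set
#'
#' Groups the states by their set of present species `phi(q)`, giving at
#' most `2^|M|` non-empty blocks.
#'
#' @param ctmc A `ctmc`.
#' @return A tibble with `block` (id), `species` (display string),
#'   `members` (list column of species vectors) and `states` (list column
#'   of state ids).
#' @export
lump_by_phi <- function(ctmc) {
  phis <- state_phi(ctmc)
  net <- ctmc$network
  um <- sort(unique(phis))
  tibble(
    block = seq_along(um),
    species = map_chr(um, function(mk)
      paste(mask_to_set(net, mk), collapse = ", ")),
    members = map(um, function(mk) mask_to_set(net, mk)),
    states = map(um, function(mk) which(phis == mk))
  )
}

# Embedded jump-chain rows for a state set: per-state exit rate and
# transition probabilities.
jump_rows <- function(ctmc) {
  tr <- ctmc$transitions
  exit_rate <- rep(0, nrow(ctmc$states))
  agg <- tr |> group_by(.data$from) |> summarise(r = sum(.data$rate))
  exit_rate[agg$from] <- agg$r
  list(tr = tr, exit_rate = exit_rate)
}

#' Expected time to leave a block of states
#'
#' First-passage time out of `block` from each member state, via the linear
#' system on the generator restricted to the block.  The exit probability
#' is computed first; states whose exit probability falls short of one are
#' reported as infinite, avoiding a singular expected-time solve.
#'
#' @param ctmc A `ctmc`.
#' @param block Integer vector of state ids.
#' @return Numeric vector (possibly `Inf`) of expected leaving times, one
#'   per state of `block`, in the order given.
#' @export
expected_leaving_time <- function(ctmc, block) {
  jr <- jump_rows(ctmc)
  nb <- length(block)
  pos <- setNames(seq_len(nb), block)
  inside <- jr$tr$from %in% block
  tr <- jr$tr[inside, ]
  lam <- jr$exit_rate[block]
  # internal jump probabilities
  Pin <- matrix(0, nb, nb)
  int_edges <- tr$to %in% block
  if (any(int_edges)) {
    ti <- tr[int_edges, ]
    for (k in seq_len(nrow(ti)))
      Pin[pos[[as.character(ti$from[k])]], pos[[as.character(ti$to[k])]]] <-
        Pin[pos[[as.character(ti$from[k])]], pos[[as.character(ti$to[k])]]] +
        ti$rate[k] / lam[pos[[as.character(ti$from[k])]]]
  }
  # exit probability per state: e = b + Pin e, with b the one-jump exit mass
  b <- numeric(nb)
  ext_edges <- !int_edges
  if (any(ext_edges)) {
    te <- tr[ext_edges, ]
    for (k in seq_len(nrow(te)))
      b[pos[[as.character(te$from[k])]]] <-
        b[pos[[as.character(te$from[k])]]] +
        te$rate[k] / lam[pos[[as.character(te$from[k])]]]
  }
  absorbing <- lam == 0
  A <- diag(nb) - Pin
  A[absorbing, ] <- 0; diag(A)[absorbing] <- 1
  b[absorbing] <- 0
  e <- tryCatch(solve(A, b), error = function(err)
    abort(paste0("singular exit-probability system on block of size ", nb)))
  out <- rep(Inf, nb)
  can_exit <- e > 1 - 1e-9
  if (any(can_exit)) {
    # t = 1/lam + Pin t restricted to states that exit almost surely
    idx <- which(can_exit)
    A2 <- diag(length(idx)) - Pin[idx, idx, drop = FALSE]
    b2 <- 1 / lam[idx]
    t2 <- tryCatch(solve(A2, b2), error = function(err)
      abort(paste0("singular expected-time system on block of size ", nb)))
    out[idx] <- t2
  }
  out
}

#' Coarse-grained chain over state blocks
#'
#' Builds the organization-level (or species-set-level) coarse-grained
#' Markov chain: for each block, the expected leaving time averaged over
#' the entry distribution and the probability that each other block is the
#' first one entered on leaving.  The default entry distribution is uniform
#' over the block's states; `"entry"` weights states by how often
#' transitions from outside the block enter them.
#'
#' @param ctmc A `ctmc`.
#' @param blocks A block table as returned by [lump_by_phi()], or `NULL`
#'   to lump by present-species set.
#' @param entry `"uniform"` (default) or `"entry"`.
#' @return A `coarse_chain`: list with `blocks` (tibble with `block`,
#'   `species`, `n_states`, `leaving_time`, `absorbing`) and `edges`
#'   (tibble with `from`, `to`, `probability`).
#' @export
block_transition_probabilities <- function(ctmc, blocks = NULL,
                                           entry = c("uniform", "entry")) {
  entry <- match.arg(entry)
  blocks <- blocks %||% lump_by_phi(ctmc)
  jr <- jump_rows(ctmc)
  n <- nrow(ctmc$states)
  state_block <- integer(n)
  for (i in seq_len(nrow(blocks))) state_block[blocks$states[[i]]] <- i
  edges <- list()
  leaving <- numeric(nrow(blocks))
  absorbing <- logical(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    bl <- blocks$states[[i]]
    lt <- expected_leaving_time(ctmc, bl)
    w <- entry_weights(ctmc, bl, state_block, i, entry)
    leaving[i] <- if (all(is.finite(lt))) sum(w * lt) else Inf
    hp <- block_hit_probabilities(ctmc, jr, bl, state_block, i)
    if (is.null(hp)) { absorbing[i] <- TRUE; next }
    agg <- colSums(w * hp)
    for (jb in which(agg > 1e-12))
      edges[[length(edges) + 1L]] <- tibble(from = i, to = jb,
                                            probability = agg[jb])
    absorbing[i] <- sum(agg) < 1e-12
  }
  structure(list(
    blocks = mutate(blocks, n_states = map_int(.data$states, length),
                    leaving_time = leaving, absorbing = absorbing) |>
      select("block", "species", "members", "n_states", "leaving_time",
             "absorbing"),
    edges = if (length(edges)) bind_rows(edges)
            else tibble(from = integer(), to = integer(),
                        probability = numeric())),
    class = "coarse_chain")
}

entry_weights <- function(ctmc, bl, state_block, i, entry) {
  w <- rep(1, length(bl))
  if (entry == "entry") {
    tr <- ctmc$transitions
    incoming <- tr[state_block[tr$from] != i & state_block[tr$to] == i, ]
    if (nrow(incoming)) {
      w <- map_dbl(bl, function(s) sum(incoming$rate[incoming$to == s]))
      if (sum(w) == 0) w <- rep(1, length(bl))
    }
  }
  w / sum(w)
}

# Probability, from each state of bl, that the first other block entered is
# b' (columns over all blocks).  NULL when no state can leave.
block_hit_probabilities <- function(ctmc, jr, bl, state_block, i) {
  nb <- length(bl)
  pos <- setNames(seq_len(nb), bl)
  tr <- jr$tr[jr$tr$from %in% bl, ]
  if (nrow(tr) == 0) return(NULL)
  lam <- jr$exit_rate[bl]
  nblocks <- max(state_block)
  Pin <- matrix(0, nb, nb)
  B <- matrix(0, nb, nblocks)
  for (k in seq_len(nrow(tr))) {
    fi <- pos[[as.character(tr$from[k])]]
    p <- tr$rate[k] / lam[fi]
    if (state_block[tr$to[k]] == i) {
      ti <- pos[[as.character(tr$to[k])]]
      Pin[fi, ti] <- Pin[fi, ti] + p
    } else {
      B[fi, state_block[tr$to[k]]] <- B[fi, state_block[tr$to[k]]] + p
    }
  }
  absorbing <- lam == 0
  A <- diag(nb) - Pin
  A[absorbing, ] <- 0; diag(A)[absorbing] <- 1
  B[absorbing, ] <- 0
  solve(A, B)
}

#' @export
print.coarse_chain <- function(x, ...) {
  cat(sprintf("<coarse_chain> %d blocks, %d edges\n",
              nrow(x$blocks), nrow(x$edges)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coarse_chain <- function(x, ...) {
  left_join(x$edges,
            select(x$blocks, from_block = "block", from_species = "species"),
            by = c(from = "from_block")) |>
    left_join(select(x$blocks, to_block = "block", to_species = "species"),
              by = c(to = "to_block"))
}

#' @exportS3Method generics::glance
glance.coarse_chain <- function(x, ...) {
  tibble(n_blocks = nrow(x$blocks),
         n_absorbing = sum(x$blocks$absorbing),
         n_edges = nrow(x$edges))
}

#' Export a CTMC state graph or coarse chain
#'
#' State graphs are written as Graphviz DOT with `index (c1,c2,...)` node
#' labels; coarse chains as JSON with blocks, leaving times and probability
#' edges.
#'
#' @param x A `ctmc` or `coarse_chain`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_state_graph <- function(x, path) {
  if (inherits(x, "ctmc")) {
    lab <- sprintf("%d (%s)", seq_len(nrow(x$states)),
                   apply(x$states, 1, paste, collapse = ","))
    lines <- c("digraph ctmc {",
               sprintf("  s%d [label=\"%s\"];", seq_len(nrow(x$states)), lab),
               sprintf("  s%d -> s%d [label=\"%s\"];",
                       x$transitions$from, x$transitions$to,
                       format(x$transitions$rate, digits = 6, trim = TRUE)),
               "}")
    writeLines(lines, path)
  } else if (inherits(x, "coarse_chain")) {
    jsonlite::write_json(
      list(blocks = map(seq_len(nrow(x$blocks)), function(i) list(
        block = x$blocks$block[i],
        species = as.list(x$blocks$members[[i]]),
        n_states = x$blocks$n_states[i],
        leaving_time = if (is.finite(x$blocks$leaving_time[i]))
          x$blocks$leaving_time[i] else "infinite",
        absorbing = x$blocks$absorbing[i])),
        edges = x$edges),
      path, auto_unbox = TRUE, digits = NA)
  } else abort("x must be a ctmc or coarse_chain")
  invisible(path)
}
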