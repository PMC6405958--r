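# Quasi-spatial discrete four-state kinetochore checkpoint model:
# synchronous stochastic updates with neighborhood-gated mitotic exit,
# Monte-Carlo success-probability estimation and parameter sweeps.

KINETOCHORE_STATES <- c("unattached", "attached", "about_to_exit", "exit")

#' Parameters of the four-state kinetochore lattice model
#'
#' @param n Number of kinetochore nodes (default 92, the human kinetochore
#'   count).
#' @param p_attach Per-step probability of the spontaneous
#'   unattached -> attached transition (default 0.005).
#' @param p_exit Per-step probability of the attached -> about-to-exit
#'   transition (the swept parameter, in `[0, 1]`).
#' @param radius Neighborhood distance threshold in plane units (geometric
#'   mode); two nodes are neighbors when their Euclidean distance is at
#'   most `radius`.
#' @param extent Side length of the square plane on which nodes are placed
#'   uniformly at random (default 10, so the radius axis spans 0-10).
#' @param graph Optional explicit neighborhood instead of the geometric
#'   rule: `"line"` (nodes in a row, 2 neighbors each, 1 at the ends),
#'   `"knn:k"` (ring with the k nearest neighbors, e.g. `"knn:5"`), or an
#'   n x n logical adjacency matrix.
#' @param max_steps Trial cap in synchronous steps (default 10000).
#' @return A `lattice_params` list.
#' @export
lattice_params <- function(n = 92, p_attach = 0.005, p_exit = 0.5,
                           radius = 5, extent = 10, graph = NULL,
                           max_steps = 10000) {
  stopifnot(n >= 1, p_attach >= 0, p_attach <= 1, p_exit >= 0, p_exit <= 1,
            radius >= 0, extent > 0, max_steps >= 1)
  structure(list(n = as.integer(n), p_attach = p_attach, p_exit = p_exit,
                 radius = radius, extent = extent, graph = graph,
                 max_steps = as.integer(max_steps)),
            class = "lattice_params")
}

#' Initialise a kinetochore lattice
#'
#' Places `n` nodes uniformly at random on the `extent` x `extent` plane
#' (or installs an explicit graph adjacency) with every node in the
#' `unattached` state.  Placement is seeded, so identical seeds give
#' identical positions.
#'
#' @param params A `lattice_params`.
#' @param seed Integer RNG seed for the placement.
#' @return A `lattice_model`: list with `params`, `positions` (n x 2 matrix
#'   or `NULL` in graph mode), `adjacency` (n x n logical, self excluded)
#'   and `state` (character vector).
#' @export
init_lattice <- function(params, seed = 1) {
  stopifnot(inherits(params, "lattice_params"))
  n <- params$n
  set.seed(seed)
  if (is.null(params$graph)) {
    positions <- cbind(x = stats::runif(n, 0, params$extent),
                       y = stats::runif(n, 0, params$extent))
    adjacency <- geometric_adjacency(positions, params$radius)
  } else {
    positions <- NULL
    adjacency <- explicit_adjacency(params$graph, n)
  }
  structure(list(params = params, positions = positions,
                 adjacency = adjacency,
                 state = rep("unattached", n)),
            class = "lattice_model")
}

geometric_adjacency <- function(positions, radius) {
  d <- as.matrix(stats::dist(positions))
  adj <- d <= radius
  diag(adj) <- FALSE
  adj
}

explicit_adjacency <- function(graph, n) {
  if (is.matrix(graph)) {
    stopifnot(nrow(graph) == n, ncol(graph) == n)
    adj <- graph | t(graph)
    diag(adj) <- FALSE
    return(adj)
  }
  if (identical(graph, "line")) {
    adj <- matrix(FALSE, n, n)
    if (n > 1) for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    return(adj)
  }
  if (grepl("^knn:[0-9]+$", graph)) {
    k <- as.integer(sub("^knn:", "", graph))
    adj <- matrix(FALSE, n, n)
    if (n > 1) for (i in seq_len(n)) {
      ring_d <- pmin(abs(i - seq_len(n)), n - abs(i - seq_len(n)))
      nb <- order(ring_d)[2:min(k + 1, n)]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    return(adj)
  }
  abort("graph must be 'line', 'knn:k' or an adjacency matrix")
}

#' Neighborhood adjacency at a given radius
#'
#' Symmetric adjacency by Euclidean distance, self excluded.  Only valid
#' for geometric-mode models.
#'
#' @param model A `lattice_model` with positions.
#' @param radius Distance threshold.
#' @return n x n logical matrix.
#' @export
neighbors <- function(model, radius) {
  stopifnot(inherits(model, "lattice_model"))
  if (is.null(model$positions)) abort("model has no positions (graph mode)")
  geometric_adjacency(model$positions, radius)
}

#' One synchronous update step
#'
#' All nodes update simultaneously, reading neighbor states from the
#' pre-step configuration: `unattached -> attached` with probability
#' `p_attach`; `attached -> about_to_exit` with probability `p_exit`; a
#' node in `about_to_exit` moves irreversibly to `exit` exactly when all
#' of its neighbors are in `about_to_exit` or `exit` (vacuously true for
#' an isolated node), and otherwise falls back to `attached`; `exit` is
#' absorbing.
#'
#' @param model A `lattice_model`.
#' @return The updated `lattice_model`.  Uses the current RNG stream; seed
#'   via [init_lattice()] or `set.seed()` for reproducibility.
#' @export
lattice_step <- function(model) {
  st <- model$state
  p <- model$params
  ready <- st %in% c("about_to_exit", "exit")
  n <- length(st)
  u <- stats::runif(n)
  new <- st
  new[st == "unattached" & u < p$p_attach] <- "attached"
  new[st == "attached" & u < p$p_exit] <- "about_to_exit"
  ate <- which(st == "about_to_exit")
  if (length(ate)) {
    blocked <- as.vector(model$adjacency[ate, , drop = FALSE] %*% !ready) > 0
    new[ate[blocked]] <- "attached"
    new[ate[!blocked]] <- "exit"
  }
  model$state <- new
  model
}

#' Run a single checkpoint trial
#'
#' Synchronous steps until every node has exited (`success`), the failure
#' predicate holds (`failure`: after a step, some node is in `exit` while
#' another is still `unattached`), or `max_steps` is reached (`timeout`,
#' meaning no failure was observed within the horizon).
#'
#' @param params A `lattice_params`.
#' @param seed Integer seed controlling placement and dynamics.
#' @return A list with `result` (`"success"`, `"failure"` or `"timeout"`)
#'   and `steps`.
#' @export
run_trial <- function(params, seed) {
  model <- init_lattice(params, seed = seed)
  for (step in seq_len(params$max_steps)) {
    model <- lattice_step(model)
    st <- model$state
    if (any(st == "exit") && any(st == "unattached"))
      return(list(result = "failure", steps = step))
    if (all(st == "exit"))
      return(list(result = "success", steps = step))
  }
  list(result = "timeout", steps = params$max_steps)
}

#' Monte-Carlo estimate of checkpoint success probability
#'
#' Runs independent seeded trials and reports the fraction in which the
#' checkpoint did not fail, with a Wilson 95% score interval.  Timeout
#' trials (no failure within `max_steps`) count as successes — a trial
#' fails only when an exited node coexists with an unattached one — and
#' are also reported separately.
#'
#' @param params A `lattice_params`.
#' @param trials Number of trials (>= 1).
#' @param seed Base seed; trial `i` uses `seed + i - 1`.
#' @return A one-row tibble with `estimate`, `ci_low`, `ci_high`,
#'   `failures`, `timeouts`, `completions` (trials in which every node
#'   exited) and `trials`.
#' @export
success_probability <- function(params, trials, seed = 1) {
  stopifnot(trials >= 1)
  res <- map_chr(seq_len(trials), function(i)
    run_trial(params, seed = seed + i - 1L)$result)
  failures <- sum(res == "failure")
  succ <- trials - failures
  ci <- wilson_interval(succ, trials)
  tibble(estimate = succ / trials, ci_low = ci[1], ci_high = ci[2],
         failures = failures, timeouts = sum(res == "timeout"),
         completions = sum(res == "success"), trials = trials)
}

wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Success-probability sweep over exit probability and radius
#'
#' Estimates checkpoint success on the full `p_exit` x `radius` grid.
#'
#' @param p_values Numeric vector of exit probabilities.
#' @param radii Numeric vector of neighborhood radii.
#' @param params Base `lattice_params` (its `p_exit`/`radius` are swept).
#' @param trials Trials per grid point.
#' @param seed Base seed.
#' @return A tibble with one row per grid point: `p_exit`, `radius`, plus
#'   the columns of [success_probability()].
#' @export
sweep_success <- function(p_values, radii, params = lattice_params(),
                          trials = 100, seed = 1) {
  stopifnot(length(p_values) >= 1, length(radii) >= 1)
  grid <- tidyr::expand_grid(p_exit = p_values, radius = radii)
  out <- map(seq_len(nrow(grid)), function(i) {
    pp <- params
    pp$p_exit <- grid$p_exit[i]
    pp$radius <- grid$radius[i]
    success_probability(pp, trials, seed = seed + (i - 1L) * trials)
  })
  bind_rows(dplyr::bind_cols(grid, bind_rows(out)))
}

#' Exact success probability of small instances by chain enumeration
#'
#' Test oracle: enumerates the synchronous Markov chain over all `4^n`
#' node-state configurations and propagates the distribution for
#' `max_steps` steps, accumulating the probability that a failure
#' configuration is ever visited.  Success is the complement (trials that
#' time out without failure count as success, as in the Monte-Carlo
#' estimator).  Feasible for `n <= 3` and small horizons.
#'
#' @param params A `lattice_params` (graph mode or fixed adjacency
#'   recommended so the neighborhood does not depend on placement).
#' @param adjacency Explicit n x n logical adjacency.
#' @return Exact success probability after `max_steps` steps.
#' @export
exact_success_probability <- function(params, adjacency) {
  n <- params$n
  stopifnot(n <= 8)
  nstates <- 4L^n
  config <- function(id) (id %/% 4L^(seq_len(n) - 1L)) %% 4L  # 0..3 per node
  fail_of <- map_lgl(0:(nstates - 1L), function(id) {
    cf <- config(id); any(cf == 3L) && any(cf == 0L)
  })
  # transition probabilities: product over nodes of per-node kernels
  dist <- numeric(nstates); dist[1] <- 1  # all unattached
  p_fail <- 0
  for (step in seq_len(params$max_steps)) {
    nxt <- numeric(nstates)
    for (id in which(dist > 0) - 1L) {
      cf <- config(id)
      ready <- cf >= 2L
      kernels <- map(seq_len(n), function(i) {
        s <- cf[i]
        if (s == 0L) c(`0` = 1 - params$p_attach, `1` = params$p_attach)
        else if (s == 1L) c(`1` = 1 - params$p_exit, `2` = params$p_exit)
        else if (s == 2L) {
          nb <- which(adjacency[i, ])
          if (all(ready[nb])) c(`3` = 1) else c(`1` = 1)
        } else c(`3` = 1)
      })
      # expand the product distribution over joint next configurations
      ids <- 0L; probs <- 1
      for (i in seq_len(n)) {
        k <- kernels[[i]]
        ids <- rep(ids, each = length(k)) +
          rep(as.integer(names(k)), times = length(ids)) * 4L^(i - 1L)
        probs <- rep(probs, each = length(k)) * rep(k, times = length(probs))
      }
      for (m in seq_along(ids))
        nxt[ids[m] + 1L] <- nxt[ids[m] + 1L] + dist[id + 1L] * probs[m]
    }
    p_fail <- p_fail + sum(nxt[fail_of])
    nxt[fail_of] <- 0
    dist <- nxt
  }
  1 - p_fail
}

#' Plot a success-probability sweep
#'
#' @param object A sweep tibble from [sweep_success()].
#' @param ... Unused.
#' @return A ggplot tile plot of success over the p x radius grid.
#' @export
plot_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$p_exit, .data$radius,
                                       fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "p (attached to about-to-exit)",
                  y = "neighborhood radius", fill = "success") +
    ggplot2::theme_minimal()
}
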