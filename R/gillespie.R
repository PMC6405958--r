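# Exact stochastic simulation (direct-method SSA) of a reaction network
# under mass-action propensities, without a population cap.  Well-mixed
# surrogate for particle-based simulation of the checkpoint models.

#' Simulate a stochastic trajectory (direct-method SSA)
#'
#' Exact simulation of the continuous-time jump process with mass-action
#' propensities `lambda_r * prod_s q(s)^(R(s))` (falling factorials for
#' coefficients above one).  Terminates at `t_max` or when the total
#' propensity reaches zero (absorbing state).
#'
#' @param net A `reaction_network`.
#' @param initial Named integer vector of initial counts; omitted species
#'   start at zero.
#' @param t_max Simulation horizon (time units of the rate constants).
#' @param seed Integer RNG seed recorded in the trajectory metadata.
#' @return A `trajectory`: list with `times` (numeric, starting at 0),
#'   `states` (integer matrix, one row per event epoch), `reactions`
#'   (character, fired reaction per event, `NA` for the initial row),
#'   `seed`, `t_max` and `network`.
#' @examples
#' traj <- ssa_simulate(sac_model("model3"),
#'                      c(KinU = 5, Activator = 10), t_max = 50, seed = 1)
#' tail(tidy(traj), 3)
#' @export
ssa_simulate <- function(net, initial, t_max, seed) {
  stopifnot(inherits(net, "reaction_network"), t_max > 0)
  ns <- length(net$species)
  q <- setNames(rep(0, ns), net$species)
  if (length(initial)) {
    unknown <- setdiff(names(initial), net$species)
    if (length(unknown))
      abort(paste0("unknown species in initial: ",
                   paste(unknown, collapse = ", ")))
    q[names(initial)] <- initial
  }
  if (any(q < 0)) abort("initial counts must be non-negative")
  nr <- length(net$reactions)
  R <- matrix(0L, nr, ns, dimnames = list(NULL, net$species))
  D <- matrix(0L, nr, ns, dimnames = list(NULL, net$species))
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    R[j, names(r$reactants)] <- r$reactants
    D[j, names(r$reactants)] <- D[j, names(r$reactants)] - r$reactants
    D[j, names(r$products)] <- D[j, names(r$products)] + r$products
  }
  lambda <- map_dbl(net$reactions, "rate")
  ids <- map_chr(net$reactions, "id")

  set.seed(seed)
  cap <- 4096L
  times <- numeric(cap)
  states <- matrix(0L, cap, ns, dimnames = list(NULL, net$species))
  fired <- character(cap)
  times[1] <- 0; states[1, ] <- q; fired[1] <- NA_character_
  n_ev <- 1L
  t <- 0
  propensity <- function(q) {
    a <- lambda
    for (j in seq_len(nr)) for (s in which(R[j, ] > 0))
      for (k in seq_len(R[j, s]) - 1L) a[j] <- a[j] * max(q[s] - k, 0)
    a
  }
  repeat {
    a <- propensity(q)
    a0 <- sum(a)
    if (a0 <= 0) break
    dt <- stats::rexp(1, a0)
    if (t + dt > t_max) break
    t <- t + dt
    j <- sample.int(nr, 1, prob = a)
    q <- q + D[j, ]
    n_ev <- n_ev + 1L
    if (n_ev > cap) {
      cap <- cap * 2L
      length(times) <- cap; length(fired) <- cap
      states <- rbind(states, matrix(0L, cap - nrow(states), ns))
    }
    times[n_ev] <- t; states[n_ev, ] <- q; fired[n_ev] <- ids[j]
  }
  structure(list(times = times[seq_len(n_ev)],
                 states = states[seq_len(n_ev), , drop = FALSE],
                 reactions = fired[seq_len(n_ev)],
                 seed = seed, t_max = t_max, network = net),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d events over [0, %.4g] (seed %d)\n",
              length(x$times) - 1L, max(x$times), x$seed))
  cat("final state:", paste(sprintf("%s=%d", colnames(x$states),
                                    x$states[nrow(x$states), ]),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Final state of a trajectory
#'
#' @param traj A `trajectory`.
#' @return Named integer vector of counts at the last event.
#' @export
final_state <- function(traj) {
  setNames(as.integer(traj$states[nrow(traj$states), ]),
           colnames(traj$states))
}

#' Counts on a time grid
#'
#' Right-continuous step interpolation of species counts at the given grid
#' points.
#'
#' @param traj A `trajectory`.
#' @param species Character vector of species (default all).
#' @param t_grid Numeric vector of times within `[0, t_max]`.
#' @return A tibble with column `time` and one column per species.
#' @export
occupancy <- function(traj, species = colnames(traj$states), t_grid) {
  stopifnot(all(t_grid >= 0), all(t_grid <= traj$t_max))
  idx <- findInterval(t_grid, traj$times)
  idx[idx < 1] <- 1L
  out <- tibble(time = t_grid)
  for (s in species) out[[s]] <- traj$states[idx, s]
  out
}

#' Tidy a trajectory into long event form
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return A tibble with `time`, `species` and `count`, one row per species
#'   per event epoch.
#' @exportS3Method generics::tidy
tidy.trajectory <- function(x, ...) {
  as_tibble(as.data.frame(x$states)) |>
    mutate(time = x$times) |>
    tidyr::pivot_longer(-"time", names_to = "species", values_to = "count")
}

#' @exportS3Method generics::glance
glance.trajectory <- function(x, ...) {
  tibble(n_events = length(x$times) - 1L, t_end = max(x$times),
         seed = x$seed, absorbed = max(x$times) < x$t_max)
}

#' Write a trajectory as CSV
#'
#' One row per event: `time` plus a column per species.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot species counts over time
#'
#' @param object A `trajectory`.
#' @param species Species to show (default all).
#' @param ... Unused.
#' @return A ggplot step plot.
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory <- function(object, species = colnames(object$states),
                                ...) {
  td <- tidy(object) |> filter(.data$species %in% !!species)
  ggplot2::ggplot(td, ggplot2::aes(.data$time, .data$count,
                                   colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "molecule count", colour = NULL) +
    ggplot2::theme_minimal()
}
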