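# Shared test fixtures: tiny hand-built networks and a seeded random
# network generator used by the property-style tests.

net_ab <- function(rate = 1) parse_network(sprintf("A -> B ; %g", rate))

net_ab_rev <- function() parse_network(c("A -> B ; 1 ; fwd",
                                         "B -> A ; 2 ; bwd"))

net_decay <- function() parse_network("A -> ; 0.5 ; decay")

# Random mass-action network: up to `n_species` species and `n_reactions`
# reactions with 0-2 reactants and 0-2 products each (empty sides allowed
# with low probability, giving occasional inflows/decays).
random_network <- function(seed, n_species = 6, n_reactions = 8) {
  set.seed(seed)
  sp <- paste0("s", seq_len(n_species))
  rxs <- lapply(seq_len(n_reactions), function(i) {
    nl <- sample(0:2, 1, prob = c(0.1, 0.6, 0.3))
    nr <- sample(0:2, 1, prob = c(0.1, 0.6, 0.3))
    if (nl == 0 && nr == 0) nr <- 1
    lhs <- table(sample(sp, nl, replace = TRUE))
    rhs <- table(sample(sp, nr, replace = TRUE))
    list(reactants = setNames(as.integer(lhs), names(lhs)),
         products = setNames(as.integer(rhs), names(rhs)),
         rate = round(stats::runif(1, 0.1, 2), 3))
  })
  reaction_network(rxs, species = sp)
}

# Independent brute-force enumeration of organizations: scan every species
# subset and test closure and self-maintenance directly.  The reference
# oracle for enumerate_organizations().
brute_force_organizations <- function(net) {
  sp <- species(net)
  subsets <- list(character())
  for (s in sp) subsets <- c(subsets, lapply(subsets, function(x) c(x, s)))
  keep <- Filter(function(A) is_closed(net, A) && is_self_maintaining(net, A),
                 subsets)
  sorted <- lapply(keep, function(A) sp[sp %in% A])
  sorted[order(lengths(sorted),
               vapply(sorted, function(A) paste(sort(A), collapse = "\r"), ""))]
}

org_members <- function(lattice) lapply(lattice$organizations, `[[`, "members")
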