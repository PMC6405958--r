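m3 <- sac_model("model3")

test_that("state-space size follows the stars-and-bars identity", {
  mc5 <- build_ctmc(m3, N_max = 5)
  expect_equal(nrow(mc5$states), choose(9, 4))   # 126
  mc2 <- build_ctmc(net_ab(), N_max = 3)
  expect_equal(nrow(mc2$states), choose(5, 2))
  for (nm in c(1, 2, 4)) {
    mc <- build_ctmc(sac_model("model3b"), N_max = nm)
    expect_equal(nrow(mc$states), choose(nm + 4, 4))
  }
})

test_that("states are encodable as count vectors and indexed stably", {
  mc <- build_ctmc(m3, N_max = 5)
  hit <- which(apply(mc$states, 1, function(q)
    all(q == c(KinU = 1, KinA = 0, Activator = 1, Inhibitor = 1))))
  expect_length(hit, 1)
  expect_setequal(phi(mc, hit), c("KinU", "Activator", "Inhibitor"))
  # rebuilding gives identical state order
  mc2 <- build_ctmc(m3, N_max = 5)
  expect_identical(mc$states, mc2$states)
})

test_that("transition rates are mass-action products, recomputable", {
  mc <- build_ctmc(m3, N_max = 4)
  rates <- setNames(sapply(m3$reactions, `[[`, "rate"),
                    sapply(m3$reactions, `[[`, "id"))
  for (k in seq_len(nrow(mc$transitions))) {
    tr <- mc$transitions[k, ]
    r <- m3$reactions[[match(tr$reaction, sapply(m3$reactions, `[[`, "id"))]]
    q <- mc$states[tr$from, ]
    expect_equal(tr$rate,
                 unname(r$rate * prod(q[names(r$reactants)]^r$reactants)))
    # target obeys q' = q - R + P
    q2 <- q
    q2[names(r$reactants)] <- q2[names(r$reactants)] - r$reactants
    q2[names(r$products)] <- q2[names(r$products)] + r$products
    expect_equal(unname(mc$states[tr$to, ]), unname(q2))
  }
  expect_true(all(rowSums(mc$states[mc$transitions$to, , drop = FALSE]) <=
                    mc$N_max))
})

test_that("initial states respect the cap and default to zero", {
  mc <- build_ctmc(m3, N_max = 3, initial = c(KinU = 2, Activator = 1))
  expect_equal(unname(mc$states[mc$initial, ]), c(2L, 0L, 1L, 0L))
  expect_error(build_ctmc(m3, N_max = 2, initial = c(KinU = 3)),
               "exceed")
  expect_error(build_ctmc(sac_model("model1"), N_max = 6, max_states = 1000),
               "above the cap")
})

test_that("SCC decomposition flags bottoms on elementary chains", {
  # pure decay A -> 0, N_max = 1: two singleton SCCs, one bottom
  mc <- build_ctmc(net_decay(), N_max = 1)
  d <- scc_decomposition(mc)
  expect_equal(nrow(d$components), 2)
  expect_equal(sum(d$components$bottom), 1)
  bot <- d$components[d$components$bottom, ]
  expect_equal(bot$footprint[[1]], character())

  # reversible A <-> B, N_max = 1: the two occupied states form one
  # bottom SCC, the empty state another
  mcr <- build_ctmc(net_ab_rev(), N_max = 1)
  dr <- scc_decomposition(mcr)
  sizes <- sort(dr$components$n_states)
  expect_equal(sizes, c(1L, 2L))
  expect_true(all(dr$components$bottom))
})

test_that("states without fireable reactions are singleton bottom SCCs", {
  mc <- build_ctmc(m3, N_max = 3)
  d <- scc_decomposition(mc)
  quiet <- which(mc$states[, "KinU"] == 0 & mc$states[, "Inhibitor"] == 0)
  for (q in quiet) {
    comp <- d$membership[q]
    expect_equal(d$components$n_states[comp], 1L)
    expect_true(d$components$bottom[comp])
  }
})

test_that("good SCCs: bottoms are good, transients with exits are not", {
  mc <- build_ctmc(m3, N_max = 5)
  d <- scc_decomposition(mc)
  good <- good_sccs(d, mc)
  expect_true(all(d$components$component[d$components$bottom] %in% good))
  # a singleton holding only KinU can fire attachment out of itself:
  # not good
  lone <- which(apply(mc$states, 1, function(q)
    q["KinU"] == 1 && sum(q) == 1))
  expect_false(d$membership[lone] %in% good)
  # reversible A <-> B at N_max = 1: the occupied component is good
  mcr <- build_ctmc(net_ab_rev(), N_max = 1)
  dr <- scc_decomposition(mcr)
  goodr <- good_sccs(dr, mcr)
  occupied <- dr$membership[which(rowSums(mcr$states) == 1)[1]]
  expect_true(occupied %in% goodr)
})

test_that("discrete organizations of the coarsest model match the statics", {
  mc <- build_ctmc(m3, N_max = 5)
  dorg <- discrete_organizations(mc)
  stat <- org_members(enumerate_organizations(m3))
  expect_equal(unname(lapply(dorg$members, sort)),
               unname(lapply(stat, sort)))
})

test_that("discrete organizations of elementary chains are exact", {
  mc <- build_ctmc(net_ab(), N_max = 1)
  dorg <- discrete_organizations(mc)
  expect_equal(lapply(dorg$members, identity), list(character(), "B"))
  # single species, no reactions
  mc1 <- build_ctmc(reaction_network(list(), species = "s"), N_max = 2)
  d1 <- discrete_organizations(mc1)
  expect_equal(lapply(d1$members, identity), list(character(), "s"))
})

test_that("every BSCC footprint is a discrete organization (random nets)", {
  for (seed in 1:5) {
    net <- random_network(seed + 10, n_species = 4, n_reactions = 5)
    mc <- build_ctmc(net, N_max = 3)
    d <- scc_decomposition(mc)
    dorg <- discrete_organizations(mc, d)
    keys <- vapply(dorg$members, function(s) paste(sort(s), collapse = "\r"),
                   "")
    for (k in which(d$components$bottom)) {
      foot <- paste(sort(d$components$footprint[[k]]), collapse = "\r")
      expect_true(foot %in% keys, info = paste("seed", seed))
    }
  }
})

test_that("internal generator checks follow the definition", {
  mc <- build_ctmc(m3, N_max = 3)
  # only Activator present: no reaction fireable, empty sequence qualifies
  only_a <- which(apply(mc$states, 1, function(q)
    all(q == c(0, 0, 1, 0))))
  expect_true(is_internal_generator(mc, only_a, "Activator"))
  # KinU + Activator: attachment eventually destroys KinU
  ka <- which(apply(mc$states, 1, function(q) all(q == c(1, 0, 1, 0))))
  expect_false(is_internal_generator(mc, ka, c("Activator", "KinU")))
  # any BSCC state generates that BSCC's footprint
  d <- scc_decomposition(mc)
  bots <- d$components$component[d$components$bottom]
  for (k in head(bots, 8)) {
    st <- which(d$membership == k)[1]
    expect_true(is_internal_generator(mc, st, d$components$footprint[[k]]))
  }
})

test_that("lumping by present species bounds the block count", {
  mc <- build_ctmc(m3, N_max = 10)
  expect_equal(nrow(mc$states), 1001)
  blocks <- lump_by_phi(mc)
  expect_lte(nrow(blocks), 16)
  expect_equal(sum(lengths(blocks$states)), 1001)
  empty <- blocks[blocks$species == "", ]
  expect_equal(lengths(empty$states), 1L)
  # N_max = 1: singleton blocks plus the zero state
  mc1 <- build_ctmc(m3, N_max = 1)
  b1 <- lump_by_phi(mc1)
  expect_true(all(lengths(b1$states) == 1))
})

test_that("expected leaving times solve the first-passage system", {
  # transient singleton with total exit rate lambda: 1/lambda
  mc <- build_ctmc(net_decay(), N_max = 3)
  s3 <- which(mc$states[, 1] == 3)
  expect_equal(expected_leaving_time(mc, s3), 1 / (0.5 * 3))
  # two-state transient chain: hand-solved 2x2 system.
  # A -> B (rate 1 per molecule); block {q(A)=2, q(A)=1}:
  # t(2) = 1/2 + t(1), t(1) = 1; exit only from q(A)=1.
  mcb <- build_ctmc(net_ab(), N_max = 2, initial = c(A = 2))
  blk <- c(which(mcb$states[, "A"] == 2 & mcb$states[, "B"] == 0),
           which(mcb$states[, "A"] == 1 & mcb$states[, "B"] == 1))
  lt <- expected_leaving_time(mcb, blk)
  expect_equal(lt, c(1.5, 1))
})

test_that("discrete-organization blocks of the coarsest model are stable", {
  mc <- build_ctmc(m3, N_max = 5)
  phis <- apply(mc$states > 0, 1, function(p)
    paste(colnames(mc$states)[p], collapse = ","))
  for (members in list("Activator", "KinA", c("KinA", "Activator"),
                       character())) {
    key <- paste(members, collapse = ",")
    block <- which(phis == key)
    expect_true(all(is.infinite(expected_leaving_time(mc, block))),
                info = key)
  }
})

test_that("block transition probabilities are proper and hand-checkable", {
  mc <- build_ctmc(m3, N_max = 4)
  cc <- block_transition_probabilities(mc)
  rows <- split(cc$edges$probability, cc$edges$from)
  for (p in rows) expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(cc$blocks$absorbing[is.infinite(cc$blocks$leaving_time)]))

  # 3-block linear chain: A -> B -> C as pure decays of distinct species
  net <- parse_network(c("A -> B ; 2", "B -> C ; 3"))
  mcl <- build_ctmc(net, N_max = 1, initial = c(A = 1))
  ccl <- block_transition_probabilities(mcl)
  lab <- ccl$blocks$species
  eA <- ccl$edges[ccl$edges$from == which(lab == "A"), ]
  expect_equal(eA$to, which(lab == "B"))
  expect_equal(eA$probability, 1)
  expect_equal(ccl$blocks$leaving_time[lab == "A"], 1 / 2)
  expect_equal(ccl$blocks$leaving_time[lab == "B"], 1 / 3)
  expect_true(ccl$blocks$absorbing[lab == "C"])
})

test_that("single-reaction-event reachability bounds coarse successors", {
  mcb <- build_ctmc(sac_model("model3"), N_max = 4)
  cc <- block_transition_probabilities(mcb)
  lab <- cc$blocks$species
  from_iu <- which(lab == "KinU, Inhibitor")
  succ <- sort(lab[cc$edges$to[cc$edges$from == from_iu]])
  # one reaction event from {I, KinU} states can only reach blocks whose
  # species sets differ by one reaction's stoichiometry
  expect_true(all(succ %in% c("KinA, Inhibitor", "KinU, KinA, Inhibitor",
                              "KinU, Activator, Inhibitor", "KinU, Activator",
                              "KinU", "KinA")))
})

test_that("state graph and coarse chain exports are written", {
  mc <- build_ctmc(net_ab(), N_max = 1)
  f1 <- withr::local_tempfile(fileext = ".dot")
  export_state_graph(mc, f1)
  expect_match(paste(readLines(f1), collapse = ""), "digraph")
  cc <- block_transition_probabilities(mc)
  f2 <- withr::local_tempfile(fileext = ".json")
  export_state_graph(cc, f2)
  parsed <- jsonlite::read_json(f2)
  expect_length(parsed$blocks, nrow(cc$blocks))
})
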