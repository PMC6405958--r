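m3 <- sac_model("model3")
m3b <- sac_model("model3b")

test_that("fireable reactions require all reactants", {
  expect_length(fireable(m3b, "KinU"), 0)
  expect_equal(fireable(m3b, c("Activator", "KinU")), "inhibition")
  expect_setequal(fireable(m3, species(m3)),
                  c("attachment", "inhibition", "relaxation"))
  net <- parse_network(" -> X ; 1 ; inflow")
  expect_equal(fireable(net, character()), "inflow")
  expect_error(fireable(m3, "NoSuch"), "unknown species")
})

test_that("direct production is the union of fireable products", {
  expect_setequal(directly_produced(m3b, c("Activator", "KinU")),
                  c("KinU", "Inhibitor"))
  expect_length(directly_produced(m3, character()), 0)
  m1 <- sac_model("model1")
  expect_true("C-Mad2" %in% directly_produced(m1, c("KinU", "O-Mad2")))
})

test_that("closedness follows the definition", {
  expect_true(is_closed(m3, c("Activator", "KinA")))
  expect_false(is_closed(m3b, c("Activator", "KinU")))
  expect_true(is_closed(m3, character()))
})

test_that("closure reaches the smallest closed superset", {
  expect_setequal(closure(m3b, c("Activator", "KinU")),
                  c("Activator", "Inhibitor", "KinU"))
  expect_equal(closure(m3, character()), character())
  cl <- closure(m3, c("KinU"))
  expect_true(is_closed(m3, cl))
})

test_that("closure is extensive, monotone and idempotent on random networks", {
  for (seed in 1:8) {
    net <- random_network(seed, n_species = 8, n_reactions = 10)
    sp <- species(net)
    set.seed(seed * 100)
    for (k in 1:5) {
      B <- sample(sp, sample(0:8, 1))
      A <- sample(B, min(length(B), sample(0:4, 1)))
      clB <- closure(net, B)
      expect_true(all(B %in% clB))                      # extensive
      expect_true(all(closure(net, A) %in% clB))        # monotone
      expect_setequal(closure(net, clB), clB)           # idempotent
    }
  }
})

test_that("self-maintenance is decided with a valid flux witness", {
  w <- is_self_maintaining(m3b, c("Activator", "Inhibitor", "KinU"),
                           witness = TRUE)
  expect_true(w$ok)
  N <- stoichiometric_matrix(m3b)
  expect_true(all(N %*% w$v >= -1e-9))
  expect_true(all(w$v[fireable(m3b, c("Activator", "Inhibitor", "KinU"))] > 0))
  # balanced fluxes certify the set: v_inhibition = v_relaxation
  v <- c(inhibition = 1, relaxation = 1)
  expect_true(all((N[, names(v)] %*% v) >= 0))

  expect_false(is_self_maintaining(m3, c("KinU", "KinA")))
  expect_true(is_self_maintaining(m3, character()))
})

test_that("iterative removal generates a self-maintaining subset", {
  out <- generate_self_maintaining(m3b, c("Activator", "Inhibitor", "KinA"))
  expect_setequal(out, c("Activator", "KinA"))
  keepset <- c("Activator", "Inhibitor", "KinU")
  expect_setequal(generate_self_maintaining(m3b, keepset), keepset)
  out2 <- generate_self_maintaining(m3, c("Inhibitor", "Activator"))
  expect_setequal(out2, "Activator")
  expect_true(is_self_maintaining(m3, out2))
})

test_that("organization generation alternates to a closed fixed point", {
  o <- generate_organization(m3b, c("Activator", "Inhibitor", "KinA"))
  expect_setequal(o$members, c("Activator", "KinA"))
  expect_length(generate_organization(m3, character())$members, 0)
  o2 <- generate_organization(m3b, c("Activator", "KinU"))
  expect_setequal(o2$members, c("Activator", "Inhibitor", "KinU"))
  expect_true(o2$closed && o2$self_maintaining)
})

test_that("the coarsest model has 4 organizations at the long timescale", {
  lat <- enumerate_organizations(m3)
  expect_equal(
    org_members(lat),
    list(character(), "Activator", "KinA", c("KinA", "Activator")))
})

test_that("the coarsest pro-metaphase model has 8 organizations", {
  lat <- enumerate_organizations(m3b)
  expect_length(lat$organizations, 8)
  ms <- org_members(lat)
  expect_true(list(c("KinU", "Activator", "Inhibitor")) %in% ms ||
                any(vapply(ms, setequal, TRUE,
                           c("KinU", "Activator", "Inhibitor"))))
})

test_that("one species and no reactions give the two trivial organizations", {
  net <- reaction_network(list(), species = "s")
  lat <- enumerate_organizations(net)
  expect_equal(org_members(lat), list(character(), "s"))
})

test_that("every enumerated organization verifies independently", {
  for (net in list(m3, m3b, sac_model("model2b"))) {
    lat <- enumerate_organizations(net)
    for (o in lat$organizations) {
      expect_true(is_closed(net, o$members))
      expect_true(is_self_maintaining(net, o$members))
      # fixed-point property
      expect_setequal(generate_organization(net, o$members)$members,
                      o$members)
    }
  }
})

test_that("enumeration matches the brute-force subset oracle", {
  for (net in list(m3, m3b, sac_model("model2"), sac_model("model2b"))) {
    expect_equal(org_members(enumerate_organizations(net)),
                 brute_force_organizations(net))
  }
  for (seed in 1:6) {
    net <- random_network(seed, n_species = 6, n_reactions = 8)
    expect_equal(org_members(enumerate_organizations(net)),
                 brute_force_organizations(net), info = seed)
  }
})

test_that("exhaustive and exploratory closed-set strategies agree", {
  for (net in list(m3, m3b, sac_model("model2"))) {
    a <- enumerate_organizations(net, strategy = "exhaustive")
    b <- enumerate_organizations(net, strategy = "explore")
    expect_equal(org_members(a), org_members(b))
  }
  for (seed in 1:4) {
    net <- random_network(seed + 50, n_species = 7, n_reactions = 9)
    expect_equal(org_members(enumerate_organizations(net, strategy = "exhaustive")),
                 org_members(enumerate_organizations(net, strategy = "explore")))
  }
})

test_that("Hasse edges are the transitive reduction of inclusion", {
  lat <- enumerate_organizations(m3b)
  ms <- org_members(lat)
  subs <- function(i, j) all(ms[[i]] %in% ms[[j]]) && length(ms[[i]]) < length(ms[[j]])
  for (i in seq_along(ms)) for (j in seq_along(ms)) {
    covered <- subs(i, j) &&
      !any(vapply(seq_along(ms), function(k) subs(i, k) && subs(k, j), TRUE))
    has_edge <- any(lat$cover_edges[, 1] == i & lat$cover_edges[, 2] == j)
    expect_equal(has_edge, covered)
  }
})

test_that("predicates parse, evaluate and report errors", {
  p <- parse_predicate("(KinA OR KinU) AND (Activator OR Inhibitor)")
  expect_true(predicate_holds(p, c("Activator", "KinA")))
  expect_false(predicate_holds(p, c("KinU", "KinA")))
  expect_false(predicate_holds(parse_predicate("KinA"), character()))
  # nesting and associativity
  q <- parse_predicate("A AND (B OR (C AND D))")
  expect_true(predicate_holds(q, c("A", "C", "D")))
  expect_false(predicate_holds(q, c("A", "C")))
  expect_error(parse_predicate("A AND"), "syntax")
  expect_error(parse_predicate("(A OR B"), "missing ')'")
  expect_error(parse_predicate("KinZ", m3), "unknown species 'KinZ'")
})

test_that("interesting-organization filtering reproduces the SAC counts", {
  lat3 <- enumerate_organizations(m3)
  int3 <- filter_interesting(lat3, sac_predicate("model3"))
  expect_length(int3, 1)
  expect_setequal(int3[[1]]$members, c("Activator", "KinA"))

  lat3b <- enumerate_organizations(m3b)
  int3b <- filter_interesting(lat3b, sac_predicate("model3b"))
  expect_length(int3b, 3)

  expect_length(filter_interesting(lat3, "KinU AND KinA"), 0)
})

test_that("lattice export writes JSON and DOT", {
  lat <- enumerate_organizations(m3)
  jf <- withr::local_tempfile(fileext = ".json")
  export_lattice(lat, jf, "json")
  parsed <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_length(parsed$organizations, 4)
  df <- withr::local_tempfile(fileext = ".dot")
  export_lattice(lat, df, "dot")
  expect_match(readLines(df)[1], "digraph")
})

test_that("lattice tidiers and plot builders run", {
  lat <- enumerate_organizations(m3)
  td <- tidy(lat)
  expect_equal(td$size, c(0L, 1L, 1L, 2L))
  expect_equal(glance(lat)$n_organizations, 4)
  p <- autoplot(lat)
  expect_s3_class(p, "ggplot")
})
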