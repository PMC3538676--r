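# Network builders: CPT contents, cross-builder consistency, the summary
# node, and the folded-vs-explicit root representations.

test_that("scenario validation enforces the parameter invariants", {
  expect_s3_class(scenario(10, 3, 0.01), "scenario")
  expect_error(scenario(0, 1, 0.01), class = "invalid_scenario")
  expect_error(scenario(5, 6, 0.01), class = "invalid_scenario")
  expect_error(scenario(5, 2, 1.5), class = "invalid_scenario")
  expect_error(scenario(3, 2, 0.01, priors = c(0.5, 0.5)), class = "invalid_scenario")
  expect_error(scenario(3, 2, 0.01, priors = c(0.7, 0.5, -0.2)), class = "invalid_scenario")
  expect_equal(scenario_priors(scenario(4, 1, 0.1)), rep(0.25, 4))
})

test_that("island network encodes the H prior and match-rate tables", {
  for (N in c(2, 10, 100, 1000)) {
    net <- build_island_network(scenario(N, 1, 0.01))
    expect_identical(nrow(validate_network(net)), 0L)
    expect_equal(unname(net$nodes$H$cpt[["."]]), c(1 / N, (N - 1) / N))
  }
  for (g in c(0.01, 0.1)) {
    net <- build_island_network(scenario(100, 1, g))
    expect_equal(unname(net$nodes$M1$cpt[["H1"]]), c(1, 0))
    expect_equal(unname(net$nodes$M1$cpt[["H1_bar"]]), c(g, 1 - g))
  }
})

test_that("two-member database network reproduces the exclusion tables", {
  for (g in c(0.01, 0.1)) {
    net <- build_two_member_db_network(scenario(100, 2, g))
    expect_identical(nrow(validate_network(net)), 0L)
    # X2 columns: no-match first; certain exclusion impossible under H2
    expect_equal(unname(net$nodes$X2$cpt[["H1"]]), c(1 - g, g))
    expect_equal(unname(net$nodes$X2$cpt[["H2"]]), c(0, 1))
    expect_equal(unname(net$nodes$X2$cpt[["H3_N"]]), c(1 - g, g))
    expect_equal(unname(net$nodes$M1$cpt[["H2"]]), c(g, 1 - g))
  }
  net <- build_two_member_db_network(sc_pair100())
  expect_equal(unname(net$nodes$H$cpt[["."]]), c(0.01, 0.01, 0.98))
  post <- infer_posterior(net, "H", c(M1 = "match", X2 = "no-match"))
  expect_equal(round(post$probabilities[["H1"]], 4), 0.5051)
  x2 <- infer_posterior(net, "X2", c(M1 = "match"))
  expect_equal(round(x2$probabilities[["no-match"]], 4), 0.9850)
  expect_error(build_two_member_db_network(scenario(100, 3, 0.01)),
               class = "wrong_builder")
})

test_that("general network handles exclusion-only evidence and edge sizes", {
  # n = N: excluding everyone else makes the suspect the certain source
  net_all <- build_general_db_network(scenario(100, 100, 0.01))
  expect_equal(unname(net_all$nodes$H$cpt[["."]]), c(0.01, 0.99, 0))  # zero-prior state kept
  post <- infer_posterior(net_all, "H", c(X2_Xn = "no-match-all"))
  expect_equal(post$probabilities[["H1"]], 1)
  # N = 1000, n = 100: 1/(N - n + 1)
  post2 <- infer_posterior(build_general_db_network(sc_big_db()), "H",
                           c(X2_Xn = "no-match-all"))
  expect_equal(post2$probabilities[["H1"]], 1 / 901, tolerance = 1e-12)
  # n = 1: the aggregate exclusion node is vacuous
  net1 <- build_general_db_network(scenario(50, 1, 0.2))
  for (hs in net1$nodes$H$states) {
    expect_equal(unname(net1$nodes$X2_Xn$cpt[[hs]]), c(1, 0))
  }
  expect_identical(nrow(validate_network(net1)), 0L)
})

test_that("general builder agrees with the two-member builder at n = 2", {
  for (fx in generate_fixtures(seed = 3, count = 15)) {
    sc2 <- scenario(max(fx$N, 2), 2, fx$gamma, priors = NULL)
    g2 <- build_general_db_network(sc2)
    t2 <- build_two_member_db_network(sc2)
    for (ev2 in list(c(M1 = "match"),
                     c(X2 = "no-match"),
                     c(M1 = "match", X2 = "no-match"))) {
      evg <- ev2
      names(evg)[names(evg) == "X2"] <- "X2_Xn"
      evg[evg == "no-match" & names(evg) == "X2_Xn"] <- "no-match-all"
      pg <- infer_posterior(g2, "H", evg)$probabilities
      pt <- infer_posterior(t2, "H", ev2)$probabilities
      expect_equal(unname(pg), unname(pt), tolerance = 1e-12)
    }
  }
})

test_that("with no exclusion evidence the general network reduces to the island model", {
  for (fx in generate_fixtures(seed = 5, count = 15)) {
    pg <- infer_posterior(build_general_db_network(fx), "H",
                          c(M1 = "match"))$probabilities[["H1"]]
    expect_equal(pg, island_posterior(fx)$posterior_suspect, tolerance = 1e-12)
  }
})

test_that("growing the database never weakens the case against a matching suspect", {
  for (N in c(10, 100, 1000)) {
    for (g in c(0.001, 0.01, 0.1, 0.5)) {
      posts <- vapply(seq_len(min(N, 12)), function(n) {
        infer_posterior(build_general_db_network(scenario(N, n, g)), "H",
                        c(M1 = "match", X2_Xn = "no-match-all"))$probabilities[["H1"]]
      }, numeric(1))
      expect_true(all(diff(posts) >= -1e-12))
    }
  }
})

test_that("summary node regroups H and supports likelihood-ratio conditioning", {
  net <- attach_summary_node(build_general_db_network(sc_big_db()))
  expect_identical(nrow(validate_network(net)), 0L)
  post <- infer_posterior(net, "H", c(H1 = "H1_bar"))
  expect_equal(round(post$probabilities[["H2_n"]], 4), 0.0991)
  expect_equal(round(post$probabilities[["Hn+1_N"]], 4), 0.9009)
  expect_equal(infer_posterior(net, "H", c(H1 = "H1"))$probabilities[["H1"]], 1)
  expect_error(attach_summary_node(net), class = "summary_exists")
})

test_that("explicit numeric root nodes and folded constants give identical posteriors", {
  cases <- list(sc_island100(), sc_three(), sc_big_db(),
                scenario(7, 4, 0.001, priors = c(0.4, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)))
  for (sc in cases) {
    folded <- build_general_db_network(sc)
    explicit <- build_general_db_network(sc, explicit_roots = TRUE)
    expect_identical(nrow(validate_network(explicit)), 0L)
    for (ev in list(character(0), c(M1 = "match"),
                    c(M1 = "match", X2_Xn = "no-match-all"))) {
      expect_equal(infer_posterior(folded, "H", ev)$probabilities,
                   infer_posterior(explicit, "H", ev)$probabilities,
                   tolerance = 1e-12)
    }
  }
  sc2 <- sc_pair100()
  expect_equal(
    infer_posterior(build_two_member_db_network(sc2, explicit_roots = TRUE),
                    "H", c(M1 = "match", X2 = "no-match"))$probabilities,
    infer_posterior(build_two_member_db_network(sc2), "H",
                    c(M1 = "match", X2 = "no-match"))$probabilities,
    tolerance = 1e-12)
  expect_equal(
    infer_posterior(build_island_network(sc_island100(), explicit_roots = TRUE),
                    "H", c(M1 = "match"))$probabilities,
    infer_posterior(build_island_network(sc_island100()), "H",
                    c(M1 = "match"))$probabilities,
    tolerance = 1e-12)
})
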