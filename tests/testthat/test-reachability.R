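test_that("reachability reproduces analytic values on canonical topologies", {
  expect_equal(
    reachability(fixture_network("single_edge"), "s", "t", probabilities = 0.7),
    0.7
  )
  expect_equal(
    reachability(fixture_network("parallel"), "s", "t", probabilities = c(0.5, 0.5)),
    0.75
  )
  expect_equal(
    reachability(fixture_network("series"), "s", "t", probabilities = c(0.5, 0.5),
      method = "enumerate"),
    0.25
  )
  expect_equal(
    reachability(fixture_network("diamond"), "s", "t", probabilities = rep(0.5, 4)),
    0.4375
  )
  # conventions: empty path for s == t, zero when graph-disconnected
  net <- signal_network(data.frame(from = "A", to = "B"),
    sources = "A", targets = "B", nodes = c("A", "B", "Z"))
  expect_equal(reachability(net, "A", "A", probabilities = 0.3), 1)
  expect_equal(reachability(net, "B", "A", probabilities = 0.3), 0)
  expect_equal(reachability(net, "A", "Z", probabilities = 0.3), 0)
  expect_error(reachability(net, "A", "missing", probabilities = 0.3), "unknown node")
  expect_error(reachability(net, "A", "B", probabilities = c(0.3, 0.4)), "length")
})

test_that("collapse engine agrees with subset enumeration on random instances", {
  for (seed in 1:40) {
    inst <- random_small_instance(seed)
    engine <- reachability(inst$network, inst$s, inst$t, probabilities = inst$p)
    oracle <- reachability(inst$network, inst$s, inst$t, probabilities = inst$p,
      method = "enumerate")
    expect_equal(engine, oracle, tolerance = 1e-12)
  }
})

test_that("enumeration refuses oversized networks", {
  big <- generate_network(25, 24, 1, 1, seed = 2, max_tries = 2000)
  expect_error(
    reachability(big, big$sources, big$targets,
      probabilities = rep(0.5, n_edges(big)), method = "enumerate"),
    "20 edges"
  )
})

test_that("reachability matrices cover all pairs and degenerate probabilities", {
  one <- fixture_network("single_edge")
  expect_equal(
    reachability_matrix(one, probabilities = 0.3),
    matrix(0.3, 1, 1, dimnames = list("s", "t"))
  )
  net <- generate_network(8, 12, 2, 2, seed = 7)
  R1 <- reachability_matrix(net, probabilities = rep(1, 12))
  for (s in net$sources) {
    for (t in net$targets) {
      connected <- sigreach:::edge_subset_reaches(
        match(net$edges$from, net$nodes), match(net$edges$to, net$nodes),
        n_nodes(net), seq_len(12), match(s, net$nodes), match(t, net$nodes)
      )
      expect_equal(R1[s, t], as.numeric(connected))
    }
  }
  expect_true(all(reachability_matrix(net, probabilities = rep(0, 12)) == 0))
  bare <- signal_network(data.frame(from = "A", to = "B"))
  expect_error(reachability_matrix(bare, probabilities = 0.5), "non-empty source")
})

test_that("reachability is monotone in every single edge probability", {
  for (seed in c(3, 8, 15)) {
    inst <- random_small_instance(seed)
    base <- reachability(inst$network, inst$s, inst$t, probabilities = inst$p)
    for (e in seq_len(n_edges(inst$network))) {
      up <- inst$p
      up[e] <- min(1, up[e] + 0.3)
      expect_gte(
        reachability(inst$network, inst$s, inst$t, probabilities = up) - base,
        -1e-12
      )
    }
  }
})

test_that("deferred-edge coefficients give the exact affine decomposition", {
  expect_equal(
    linear_coefficients(fixture_network("single_edge"), 1, "s", "t",
      probabilities = 0.2),
    list(alpha = 0, beta = 1)
  )
  expect_equal(
    linear_coefficients(fixture_network("parallel"), 1, "s", "t",
      probabilities = c(0.9, 0.5)),
    list(alpha = 0.5, beta = 0.5)
  )
  expect_equal(
    linear_coefficients(fixture_network("series"), 1, "s", "t",
      probabilities = c(0.9, 0.5)),
    list(alpha = 0, beta = 0.5)
  )
  expect_error(
    linear_coefficients(fixture_network("series"), 7, "s", "t",
      probabilities = c(0.9, 0.5)),
    "edge index"
  )

  for (seed in 1:15) {
    inst <- random_small_instance(seed)
    m <- n_edges(inst$network)
    e <- withr::with_seed(seed + 1000, sample.int(m, 1))
    lin <- linear_coefficients(inst$network, e, inst$s, inst$t,
      probabilities = inst$p)
    expect_gte(lin$alpha, 0)
    expect_gte(lin$beta, 0)
    expect_lte(lin$alpha + lin$beta, 1 + 1e-12)
    for (pe in c(0, 0.25, 0.5, 0.75, 1)) {
      q <- inst$p
      q[e] <- pe
      expect_equal(
        lin$alpha + lin$beta * pe,
        reachability(inst$network, inst$s, inst$t, probabilities = q),
        tolerance = 1e-9
      )
    }
  }
})

test_that("every term surviving a deferred-edge pass is completed by that edge", {
  # multiply all binomials except one via the stepwise mechanics; each
  # surviving non-free term must lack an s->t path on its own but gain one
  # when the deferred edge is added
  net <- fixture_network("bridge")
  p <- c(0.6, 0.3, 0.5, 0.7, 0.4)
  ef <- match(net$edges$from, net$nodes)
  et <- match(net$edges$to, net$nodes)
  s <- match("s", net$nodes)
  t <- match("t", net$nodes)
  for (deferred in seq_len(5)) {
    poly <- xy_polynomial(5)
    for (e in setdiff(seq_len(5), deferred)) {
      poly <- multiply_edge(poly, e, p[e])
      poly <- collapse_terms(poly, net, "s", "t")
    }
    for (key in names(poly$terms)) {
      present <- sigreach:::key_edges(key)
      expect_false(sigreach:::edge_subset_reaches(ef, et, 4, present, s, t))
      expect_true(sigreach:::edge_subset_reaches(ef, et, 4, c(present, deferred), s, t))
    }
    # and alpha/beta from the compiled engine match the stepwise polynomial
    lin <- linear_coefficients(net, deferred, "s", "t", probabilities = p)
    expect_equal(lin$alpha, poly$b, tolerance = 1e-12)
    expect_equal(lin$beta, sum(unlist(poly$terms)), tolerance = 1e-12)
  }
})
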