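test_that("quality is fitness on a percentage scale", {
  C <- matrix(c(0.4, 0.9), 1, 2)
  expect_equal(reach_quality(C, C), 100)
  expect_equal(reach_quality(matrix(1), matrix(0)), 0)
  R <- matrix(c(0.5, 0.7), 1, 2)
  expect_equal(reach_quality(C, R), 100 * solution_fitness(C, R))
})

test_that("bin entropy hits its analytic limits and range", {
  expect_equal(probability_entropy(rep(0.05, 12)), 0)
  expect_equal(probability_entropy(seq(0.05, 0.95, by = 0.1)), log(10))
  expect_equal(probability_entropy(c(0.05, 0.05, 0.95, 0.95)), log(2))
  # the final bin is closed: 1.0 falls into [0.9, 1]
  expect_equal(probability_entropy(c(1, 0.95)), 0)
  expect_equal(probability_entropy(c(0.1, 0.05)), log(2)) # 0.1 opens bin 2
  expect_error(probability_entropy(numeric(0)), "non-empty")
  expect_error(probability_entropy(c(0.5, 1.2)), "\\[0, 1\\]")
  for (seed in 1:5) {
    vals <- withr::with_seed(seed, runif(50))
    h <- probability_entropy(vals)
    expect_gte(h, 0)
    expect_lte(h, log(10))
  }
})

test_that("condition distances form a valid summary", {
  same <- list(a = c(0.1, 0.2), b = c(0.1, 0.2))
  d0 <- condition_distances(same)
  expect_true(all(d0$distances == 0))

  cd <- condition_distances(list(a = c(0, 0), b = c(0.3, 0.4)))
  expect_equal(cd$distances["a", "b"], 0.5) # 3-4-5 triangle scaled into [0,1]

  three <- list(a = c(0, 0), b = c(0.3, 0.4), c = c(0.6, 0.8))
  d3 <- condition_distances(three)
  expect_equal(
    d3$mean_distance$mean_distance,
    c(mean(c(0.5, 1.0)), mean(c(0.5, 0.5)), mean(c(1.0, 0.5)))
  )
  # symmetry, zero diagonal, triangle inequality
  m <- d3$distances
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_lte(m["a", "c"], m["a", "b"] + m["b", "c"] + 1e-12)

  expect_error(condition_distances(list(a = 1:2)), "at least 2")
  expect_error(condition_distances(list(a = 1:2, b = 1:3)), "same number")

  # wide data-frame input is equivalent
  df <- tibble::tibble(condition = c("a", "b"), e1 = c(0, 0.3), e2 = c(0, 0.4))
  expect_equal(condition_distances(df)$distances["a", "b"], 0.5)
  tl <- tidy(cd)
  expect_equal(tl$distance, 0.5)
})

test_that("outstanding interactions follow the 2-sigma rule with population sd", {
  net <- signal_network(
    data.frame(from = c("u1", "u2"), to = c("v1", "v2")),
    sources = "u1", targets = "v2"
  )
  # edge 1: {0.5 x6, 0.9}; population mu ~ 0.557, sigma ~ 0.140;
  # |0.9 - mu| ~ 0.343 >= 2 sigma -> flagged in the deviant condition only
  probs <- cbind(c(rep(0.5, 6), 0.9), rep(0.3, 7))
  rownames(probs) <- paste0("cond", 1:7)
  rep <- outstanding_interactions(probs, net)
  mu <- mean(probs[, 1])
  sigma <- sqrt(mean((probs[, 1] - mu)^2))
  expect_equal(rep$edge_stats$mu, c(mu, 0.3))
  expect_equal(rep$edge_stats$sigma, c(sigma, 0))
  expect_gte(abs(0.9 - mu), 2 * sigma)
  expect_equal(nrow(rep$flagged), 1)
  expect_equal(rep$flagged$condition, "cond7")
  expect_equal(rep$flagged$edge, 1L)
  # both endpoints of the flagged edge enter the outstanding gene set L
  expect_setequal(rep$genes$gene[rep$genes$condition == "cond7"], c("u1", "v1"))

  # identical conditions: sigma = 0 everywhere, nothing flagged
  flat <- matrix(0.4, nrow = 3, ncol = 2,
    dimnames = list(paste0("c", 1:3), NULL))
  expect_equal(nrow(outstanding_interactions(flat, net)$flagged), 0)

  # invariant to condition ordering
  shuffled <- probs[c(7, 3, 1, 2, 5, 4, 6), ]
  rep2 <- outstanding_interactions(shuffled, net)
  expect_equal(rep2$flagged$condition, "cond7")
  expect_equal(rep2$flagged$probability, rep$flagged$probability)

  expect_error(outstanding_interactions(probs[1:2, ], net), "at least 3")
  expect_error(outstanding_interactions(probs[, 1, drop = FALSE], net), "edges")
})

test_that("removal centrality scores reachability contribution", {
  chain <- fixture_network("series")
  ct <- node_centrality(chain, probabilities = c(0.5, 0.5))
  expect_equal(ct$centrality[ct$node == "m"], 0.25) # R drops 0.25 -> 0
  # endpoints are excluded from their own pairs, leaving no pair at all here
  expect_equal(ct$centrality[ct$node == "s"], 0)
  expect_equal(ct$centrality[ct$node == "t"], 0)

  # a node off every source->target path has centrality 0
  side <- signal_network(
    data.frame(from = c("s", "s", "a", "x"), to = c("a", "x", "t", "y")),
    sources = "s", targets = "t"
  )
  ct2 <- node_centrality(side, probabilities = c(0.6, 0.9, 0.7, 0.9))
  expect_equal(ct2$centrality[ct2$node %in% c("x", "y")], c(0, 0))
  # the sole intermediate carries the full pair reachability
  expect_equal(ct2$centrality[ct2$node == "a"], 0.6 * 0.7)
  expect_true(all(ct2$centrality >= 0))
})
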