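test_that("the closed-form single-edge update matches hand-computable cases", {
  one <- fixture_network("single_edge")
  C <- matrix(0.8, 1, 1, dimnames = list("s", "t"))
  expect_equal(optimal_edge_probability(one, C, 1, psi = 0.1), 0.8)

  # series with the downstream edge fixed at 0.5 and C = 1: the
  # unconstrained optimum 2 is clipped to 1
  chain <- fixture_network("series")
  C1 <- matrix(1, 1, 1, dimnames = list("s", "t"))
  expect_equal(optimal_edge_probability(chain, C1, 1, psi = c(0.3, 0.5)), 1)

  # an edge off every source->target path is left untouched
  dangling <- signal_network(
    data.frame(from = c("s", "x"), to = c("t", "y")),
    sources = "s", targets = "t"
  )
  expect_equal(
    optimal_edge_probability(dangling, C, 2, psi = c(0.5, 0.37)),
    0.37
  )
  expect_error(optimal_edge_probability(one, C, 9, psi = 0.1), "edge index")
})

test_that("the closed-form update beats a fine grid search", {
  for (seed in 1:10) {
    inst <- random_small_instance(seed)
    net <- inst$network
    C <- withr::with_seed(seed + 500, {
      matrix(runif(1), 1, 1, dimnames = list(net$sources, net$targets))
    })
    e <- withr::with_seed(seed + 600, sample.int(n_edges(net), 1))
    opt <- optimal_edge_probability(net, C, e, psi = inst$p)
    sse_at <- function(p) {
      q <- inst$p
      q[e] <- p
      sum((C - reachability_matrix(net, probabilities = q))^2)
    }
    grid_sse <- vapply(seq(0, 1, length.out = 1001), sse_at, numeric(1))
    expect_lte(sse_at(opt), min(grid_sse) + 1e-12)
  }
})

test_that("hill climbing is a monotone descent that stops at fixed points", {
  one <- fixture_network("single_edge")
  C <- matrix(0.8, 1, 1, dimnames = list("s", "t"))
  res <- hill_climb(one, C, psi0 = 0.1)
  expect_equal(res$psi, 0.8)
  expect_equal(res$sse, 0, tolerance = 1e-16)
  expect_true(res$converged)

  # an already-optimal start is returned unchanged after one sweep
  again <- hill_climb(one, C, psi0 = res$psi)
  expect_equal(again$psi, res$psi)
  expect_equal(again$sweeps, 1L)

  for (seed in c(2, 5, 9)) {
    net <- generate_network(9, 12, 2, 2, seed = seed)
    inst <- generate_instance(net, seed = seed + 50)
    psi0 <- withr::with_seed(seed + 100, runif(12))
    res <- hill_climb(net, inst$C_clean, psi0 = psi0)
    sse0 <- sum((inst$C_clean - reachability_matrix(net, probabilities = psi0))^2)
    expect_lte(res$sse, sse0)
    expect_true(all(diff(res$sse_trace) <= 1e-12))
    expect_true(res$converged)
    expect_true(all(res$psi >= 0 & res$psi <= 1))
  }
})

test_that("the affine decomposition is consistent with full reachability", {
  net <- generate_network(8, 11, 2, 2, seed = 31)
  psi <- withr::with_seed(32, runif(11))
  R <- reachability_matrix(net, probabilities = psi)
  for (e in c(1, 5, 11)) {
    lin <- sigreach:::linear_pair_matrices(net, psi, e)
    expect_equal(lin$alpha + lin$beta * psi[e], R, tolerance = 1e-9)
    expect_true(all(lin$alpha >= 0 & lin$beta >= 0))
    expect_true(all(lin$alpha + lin$beta <= 1 + 1e-12))
  }
})

test_that("non-identifiable edges are reported", {
  dangling <- signal_network(
    data.frame(from = c("s", "x"), to = c("t", "y")),
    sources = "s", targets = "t"
  )
  C <- matrix(0.8, 1, 1, dimnames = list("s", "t"))
  res <- hill_climb(dangling, C, psi0 = c(0.2, 0.37))
  expect_equal(res$non_identifiable, c(FALSE, TRUE))
  expect_equal(res$psi[2], 0.37) # untouched
})
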