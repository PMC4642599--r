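test_that("fitness and gap follow their defining formulas", {
  C <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(solution_fitness(C, C), 1) # identical matrices: 100 % accurate
  expect_equal(solution_fitness(matrix(1), matrix(0)), 0)
  expect_equal(solution_fitness(C, matrix(c(0.1, 0.8), 1, 2)), 0.75)

  expect_equal(solution_gap(C, C), 0)
  expect_equal(solution_gap(matrix(c(0.9, 0.8), 1, 2), matrix(c(0.5, 0.6), 1, 2)), 0.6)
  expect_equal(solution_gap(matrix(0.1), matrix(0.5)), -0.4)
  expect_error(solution_fitness(matrix(0.5), C), "dimensions")
  expect_error(solution_gap(matrix(0.5), C), "dimensions")
})

test_that("crossover picks entries by the parents' gap signs", {
  expect_equal(ga_crossover(0.3, 0.7, gap1 = 1, gap2 = 2, 0.9, 0.9), 0.7)
  expect_equal(ga_crossover(0.3, 0.7, gap1 = -1, gap2 = -2, 0.9, 0.9), 0.3)
  # zero gap counts as positive
  expect_equal(ga_crossover(0.3, 0.7, gap1 = 0, gap2 = 1, 0.9, 0.9), 0.7)
  # mixed signs with degenerate fitness: always the fit parent
  withr::with_seed(1, {
    child <- ga_crossover(rep(0.3, 50), rep(0.7, 50),
      gap1 = 1, gap2 = -1, fitness1 = 1, fitness2 = 0)
    expect_true(all(child == 0.3))
  })
  # mixed signs with equal fitness: entries come from both parents
  withr::with_seed(2, {
    child <- ga_crossover(rep(0.3, 200), rep(0.7, 200),
      gap1 = 1, gap2 = -1, fitness1 = 0.5, fitness2 = 0.5)
    expect_true(all(child %in% c(0.3, 0.7)))
    expect_gt(sum(child == 0.3), 50)
    expect_gt(sum(child == 0.7), 50)
  })
  expect_error(ga_crossover(c(0.1, 0.2), 0.3, 1, 1, 1, 1), "equal length")
})

test_that("mutation resamples entries at the Bernoulli rate", {
  psi <- seq(0, 1, length.out = 20)
  expect_identical(ga_mutate(psi, rate = 0), psi)
  withr::with_seed(3, {
    all_new <- ga_mutate(psi, rate = 1)
    expect_true(all(all_new >= 0 & all_new <= 1))
    expect_false(any(all_new == psi))
  })
  withr::with_seed(4, {
    big <- rep(0.5, 1e5)
    frac <- mean(ga_mutate(big, rate = 0.01) != big)
    se <- sqrt(0.01 * 0.99 / 1e5)
    expect_lt(abs(frac - 0.01), 3 * se)
  })
})

test_that("selection keeps the elite and returns exactly the target size", {
  withr::with_seed(5, {
    fitness <- runif(100)
    keep <- ga_select(fitness, n_keep = 50, n_elite = 5)
    expect_length(keep, 50)
    expect_length(unique(keep), 50)
    expect_true(which.max(fitness) %in% keep)
    expect_true(all(order(fitness, decreasing = TRUE)[1:5] %in% keep))
  })
  expect_error(ga_select(runif(80), n_keep = 50), "exactly 100")
  # degenerate all-equal fitness still selects without error
  withr::with_seed(6, expect_length(ga_select(rep(0.5, 100), 50, 5), 50))
  withr::with_seed(7, expect_length(ga_select(rep(0, 100), 50, 5), 50))
})

test_that("the genetic algorithm is reproducible, elitist, and size-stable", {
  net <- generate_network(8, 10, 2, 2, seed = 21)
  inst <- generate_instance(net, seed = 22)
  a <- run_ga(net, inst$C_clean, iterations = 5, seed = 99)
  b <- run_ga(net, inst$C_clean, iterations = 5, seed = 99)
  expect_identical(a$psi, b$psi)
  expect_identical(a$trace, b$trace)

  expect_true(all(a$trace$population == 50))
  expect_true(all(diff(a$trace$best_fitness) >= 0))
  expect_true(all(a$psi >= 0 & a$psi <= 1))
  # the archive can only improve on the initial population
  init <- withr::with_seed(99, ga_initialize(net, inst$C_clean))
  expect_gte(a$fitness, max(init$fitness))
})

test_that("initialization draws a uniform scored population of the stated size", {
  net <- fixture_network("diamond")
  C <- matrix(0.4, 1, 1, dimnames = list("s", "t"))
  pop <- withr::with_seed(8, ga_initialize(net, C, size = 50))
  expect_equal(dim(pop$psi), c(50, 4))
  expect_true(all(pop$psi >= 0 & pop$psi <= 1))
  expect_length(pop$fitness, 50)
  # cached scores are recomputable from the cached matrices
  expect_equal(pop$fitness[1], solution_fitness(C, pop$R[[1]]))
  expect_equal(pop$gap[1], solution_gap(C, pop$R[[1]]))
  pop2 <- withr::with_seed(8, ga_initialize(net, C, size = 50))
  expect_identical(pop$psi, pop2$psi)
})

test_that("the GA concentrates near the optimum of a one-edge problem", {
  net <- fixture_network("single_edge")
  C <- matrix(0.8, 1, 1, dimnames = list("s", "t"))
  res <- run_ga(net, C, iterations = 50, seed = 13)
  expect_lt(abs(res$psi[1] - 0.8), 0.05)
})
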