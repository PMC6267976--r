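test_that("entropy matches closed forms and validates input", {
  expect_equal(entropy(c(1, 0, 0)), 0)
  expect_equal(entropy(c(0.5, 0.5)), log(2))
  expect_equal(entropy(rep(0.2, 5)), log(5))
  expect_error(entropy(c(-0.1, 1.1)), "nonnegative")
  expect_error(entropy(c(0.2, 0.2)), "simplex")
})

test_that("fully determined problems are solved exactly", {
  # normalization + one constraint pin down a two-species solution
  pr <- maxent_problem(matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "x")),
                       c(x = 0.7))
  sol <- solve_maxent(pr)
  expect_equal(unname(sol$p), c(0.3, 0.7), tolerance = 1e-8)
  expect_true(sol$converged)
  expect_equal(sol$entropy, -(0.3 * log(0.3) + 0.7 * log(0.7)), tolerance = 1e-10)

  # centroid target with uniform prior gives the uniform distribution
  set.seed(5)
  tm <- matrix(rnorm(15), 5, 3,
               dimnames = list(paste0("s", 1:5), paste0("t", 1:3)))
  sol_u <- solve_maxent(maxent_problem(tm, colMeans(tm)))
  expect_equal(unname(sol_u$p), rep(0.2, 5), tolerance = 1e-8)

  # J >= S-1 independent constraints force the linear-algebra solution
  tm2 <- matrix(c(1, 2, 4, 1, 3, 9), 3, 2,
                dimnames = list(paste0("s", 1:3), c("u", "v")))
  w <- c(0.2, 0.5, 0.3)
  sol2 <- solve_maxent(maxent_problem(tm2, as.numeric(crossprod(tm2, w))))
  expect_equal(unname(sol2$p), w, tolerance = 1e-7)
})

test_that("the three-species grid oracle agrees with the solver", {
  tm <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("s", 1:3), "x"))
  sol <- solve_maxent(maxent_problem(tm, c(x = 0.5)))
  # feasible point for the oracle: mixture attaining the target
  oracle <- oracle_maxent_grid(tm, 0.5, c(0.5, 0.5, 0))
  expect_gte(sol$entropy, oracle$entropy - 1e-6)
  expect_lte(max(sol$residuals_std), 1e-8)
  expect_equal(unname(sol$p), oracle$p, tolerance = 1e-3)
})

test_that("solution is invariant to affine trait rescaling", {
  set.seed(9)
  for (rep in 1:5) {
    pb <- random_maxent_problem(S = 5, J = 2)
    sol <- solve_maxent(maxent_problem(pb$traits, pb$target))
    tm2 <- pb$traits
    tm2[, 1] <- 3.7 * tm2[, 1] - 11
    tgt2 <- pb$target
    tgt2[1] <- 3.7 * tgt2[1] - 11
    sol2 <- solve_maxent(maxent_problem(tm2, tgt2))
    expect_equal(unname(sol2$p), unname(sol$p), tolerance = 1e-8)
  }
})

test_that("tightening a constraint toward one species raises its abundance", {
  tm <- matrix(c(1, 4, 10), 3, 1, dimnames = list(paste0("s", 1:3), "x"))
  targets <- seq(3, 9.5, by = 0.5)
  p3 <- vapply(targets, function(tg) {
    solve_maxent(maxent_problem(tm, c(x = tg)))$p[3]
  }, numeric(1))
  expect_true(all(diff(p3) > 0))
})

test_that("duplicate trait vectors receive equal predicted abundances", {
  tm <- matrix(c(0, 0, 1, 5, 5, 2), 3, 2,
               dimnames = list(c("dup1", "dup2", "other"), c("u", "v")))
  sol <- solve_maxent(maxent_problem(tm, as.numeric(crossprod(tm, c(0.3, 0.3, 0.4)))))
  expect_equal(unname(sol$p["dup1"]), unname(sol$p["dup2"]), tolerance = 1e-9)
})

test_that("feasibility check classifies targets against the trait hull", {
  two <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "x"))
  expect_true(check_feasibility(maxent_problem(two, c(x = 0.5)))$feasible)

  # outside the hull: projection lands on the nearest vertex; with
  # unstandardized traits the distance is in raw trait units
  rep_raw <- check_feasibility(
    maxent_problem(two, c(x = 1.5), standardize = FALSE))
  expect_false(rep_raw$feasible)
  expect_equal(unname(rep_raw$projected_constraints), 1.0, tolerance = 1e-8)
  expect_equal(rep_raw$distance, 0.5, tolerance = 1e-8)

  # the centroid of any species pool is always attainable
  tr <- grass_traits()
  centroid <- colMeans(trait_matrix(tr))
  expect_true(check_feasibility(maxent_problem(tr, centroid))$feasible)

  # infeasible targets abort by default and project on request
  pr_bad <- maxent_problem(two, c(x = 1.5))
  expect_error(solve_maxent(pr_bad), "convex hull")
  sol_pr <- solve_maxent(pr_bad, on_infeasible = "project")
  expect_true(sol_pr$projected)
  expect_equal(unname(sol_pr$p), c(0, 1), tolerance = 1e-6)
})

test_that("random feasible problems match the exhaustive grid oracle", {
  set.seed(31)
  for (rep in 1:20) {
    S <- sample(3:4, 1)
    J <- sample(1:2, 1)
    pb <- random_maxent_problem(S, J)
    sol <- solve_maxent(maxent_problem(pb$traits, pb$target))
    oracle <- oracle_maxent_grid(pb$traits, pb$target, pb$w)
    expect_gte(sol$entropy, oracle$entropy - 1e-6)
    expect_lte(max(sol$residuals_std), 1e-6)
  }
})

test_that("a non-uniform prior tilts the solution toward abundant species", {
  tm <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "x"))
  sol <- solve_maxent(maxent_problem(tm, c(x = 0.5), prior = c(0.9, 0.1)))
  # constraint still binds exactly; the prior cannot move a pinned solution
  expect_equal(unname(sol$p), c(0.5, 0.5), tolerance = 1e-8)
  tm3 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "x"))
  sol_flat <- solve_maxent(maxent_problem(tm3, c(x = 1)))
  sol_tilt <- solve_maxent(maxent_problem(tm3, c(x = 1), prior = c(0.8, 0.1, 0.1)))
  expect_gt(sol_tilt$p["a"], sol_flat$p["a"])
  expect_equal(sum(sol_tilt$p * c(0, 1, 2)), 1, tolerance = 1e-7)
})

test_that("predict_abundances returns a simplex row per constraint unit", {
  tr <- grass_traits()
  cons <- treatment_constraints()
  res <- predict_abundances(tr, cons)
  expect_equal(rownames(res$predicted), cons$unit_id)
  expect_equal(unname(rowSums(res$predicted)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(vapply(res$solutions, `[[`, logical(1), "converged")))
  achieved <- unclass(res$predicted) %*% trait_matrix(tr)
  expect_equal(unname(achieved), unname(as.matrix(cons[trait_names(tr)])),
               tolerance = 1e-5)
})
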