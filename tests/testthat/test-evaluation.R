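test_that("fit statistics match hand computation and handle edge cases", {
  obs <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  pred <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(fit_r2(obs, obs), 1.0)

  # longhand Pearson formula over the four flattened cells
  x <- as.vector(obs); y <- as.vector(pred)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit_r2(obs, pred), r_hand^2)

  expect_equal(rmse_sqrt(obs, obs), 0)
  expect_equal(rmse_sqrt(rbind(c(1, 0)), rbind(c(0, 1))), 1.0)

  # symmetry in the two arguments
  expect_equal(fit_r2(obs, pred), fit_r2(pred, obs))
  expect_equal(rmse_sqrt(obs, pred), rmse_sqrt(pred, obs))

  expect_error(fit_r2(rbind(c(0.5, 0.5)), rbind(c(0.5, 0.5))), "zero variance")
  expect_error(rmse_sqrt(rbind(c(-0.1, 1.1)), rbind(c(0.5, 0.5))), "nonnegative")
  expect_error(fit_r2(obs, pred[1, , drop = FALSE]), "matching shapes")
})

test_that("rmse_sqrt falls monotonically as predictions approach observations", {
  set.seed(3)
  obs <- matrix(rgamma(20, 1), 4, 5); obs <- obs / rowSums(obs)
  pred0 <- matrix(rgamma(20, 1), 4, 5); pred0 <- pred0 / rowSums(pred0)
  alphas <- seq(0, 1, by = 0.1)
  errs <- vapply(alphas, function(a) rmse_sqrt(obs, (1 - a) * pred0 + a * obs),
                 numeric(1))
  expect_true(all(diff(errs) < 1e-12))
})

test_that("permutation p-values are valid, reproducible and bounded", {
  set.seed(7)
  obs <- matrix(rgamma(20, 1), 4, 5); obs <- obs / rowSums(obs)

  # perfect fit with all-distinct values beats every non-identical permutation
  res <- permutation_test(obs, obs, "r2", n_perm = 99, seed = 2)
  expect_equal(res$p_value, 1 / 100)
  expect_gte(res$p_value, 1 / (res$n_perm + 1))

  res_r <- permutation_test(obs, obs, "rmse_sqrt", n_perm = 99, seed = 2)
  expect_equal(res_r$p_value, 1 / 100)

  # same seed, same null stream; different seed differs
  a <- permutation_test(obs, 0.5 * obs + 0.1, "r2", n_perm = 49, seed = 5)
  b <- permutation_test(obs, 0.5 * obs + 0.1, "r2", n_perm = 49, seed = 5)
  d <- permutation_test(obs, 0.5 * obs + 0.1, "r2", n_perm = 49, seed = 6)
  expect_identical(a$null, b$null)
  expect_false(identical(a$null, d$null))

  expect_error(permutation_test(obs, obs, "r2", n_perm = 0), "n_perm")

  # whole-row scheme is available as an alternative null
  rr <- permutation_test(obs, obs, "r2", n_perm = 49, seed = 1, scheme = "rows")
  expect_true(all(rr$null <= 1))
})

test_that("Monte-Carlo p agrees with exhaustive enumeration on 2x3 matrices", {
  set.seed(12)
  for (rep in 1:4) {
    obs <- matrix(rgamma(6, 1), 2, 3); obs <- obs / rowSums(obs)
    pred <- matrix(rgamma(6, 1), 2, 3); pred <- pred / rowSums(pred)
    for (statistic in c("r2", "rmse_sqrt")) {
      p_exact <- oracle_exhaustive_p(obs, pred, statistic)
      n_perm <- 999
      p_mc <- permutation_test(obs, pred, statistic, n_perm = n_perm,
                               seed = rep)$p_value
      se <- sqrt(p_exact * (1 - p_exact) / n_perm)
      expect_lt(abs(p_mc - p_exact), 3 * se + 2 / n_perm)
    }
  }
})

test_that("CWM concordance reports per-trait Pearson correlations", {
  obs <- cbind(t1 = c(1, 2, 3, 4), t2 = c(2, 1, 4, 3))
  expect_equal(cwm_concordance(obs, obs)$r, c(1, 1))
  rev_tab <- cwm_concordance(cbind(t1 = c(1, 2, 3, 4)), cbind(t1 = c(4, 3, 2, 1)))
  expect_equal(rev_tab$r, -1)
  expect_equal(rev_tab$p_value,
               cor.test(c(1, 2, 3, 4), c(4, 3, 2, 1))$p.value)
  expect_error(cwm_concordance(cbind(t1 = c(1, 1, 1)), cbind(t1 = c(1, 2, 3))),
               "zero variance")
  expect_error(cwm_concordance(obs[1:2, ], obs[1:2, ]), "at least 3")
})

test_that("dominant-species accuracy follows the tie rule and excludes empty pots", {
  pred <- rbind(trt1 = c(0.4, 0.3, 0.1, 0.1, 0.1))
  colnames(pred) <- paste0("sp", 1:5)
  pots <- matrix(0, 4, 5, dimnames = list(paste0("pot", 1:4), paste0("sp", 1:5)))
  pots[1, ] <- c(0.6, 0.1, 0.1, 0.1, 0.1)
  pots[2, ] <- c(0.5, 0.5, 0, 0, 0)       # tie including the predicted top
  pots[3, ] <- c(0.4, 0.6, 0, 0, 0)       # miss
  pots[4, ] <- 0                          # empty: excluded
  cm <- community_matrix(pots, kind = "relative",
                         treatment = rep("trt1", 4))
  acc <- top_species_accuracy(cm, pred)
  expect_equal(acc$pot_fraction, 2 / 3)
  expect_true(acc$per_treatment$hit[1])

  expect_error(top_species_accuracy(
    community_matrix(pots[1:2, ], kind = "relative",
                     treatment = c("trt1", "ghost")), pred), "ghost")
})

test_that("treatment means average only the pots where something emerged", {
  m <- community_matrix(
    rbind(p1 = c(2, 2), p2 = c(0, 4), p3 = c(0, 0)),
    kind = "count", treatment = c("A", "A", "A"))
  rel <- relativize(m)
  tm <- treatment_means(rel)
  expect_equal(unname(tm["A", ]), c(0.25, 0.75))
})
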