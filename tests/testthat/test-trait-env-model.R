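# A linear generating surface used in several checks: the smooth additive
# model must recover it almost exactly when noise is tiny.
linear_cwm_data <- function(n = 96, noise_sd = 0.01, seed = 101) {
  set.seed(seed)
  env <- environment_table(data.frame(
    sample_id = sprintf("q%03d", 1:n),
    soil_ph = runif(n, 5.5, 7.5),
    pine_ba = runif(n, 0, 59)))
  truth <- 2 + 0.5 * env$soil_ph - 0.02 * env$pine_ba
  cwm <- data.frame(unit_id = env$sample_id,
                    seed_mass = truth + rnorm(n, 0, noise_sd))
  class(cwm) <- c("cwm_table", "data.frame")
  list(env = env, cwm = cwm, truth = truth)
}

test_that("smooth fit recovers a linear CWM surface", {
  d <- linear_cwm_data()
  fit <- fit_cwm_model(d$cwm, d$env, "seed_mass")
  expect_s3_class(fit, "cwm_fit")
  expect_true(all(abs(fitted(fit$gam) - d$truth) < 0.05))
  expect_lte(fit$basis_dim, 10)

  # prediction at a training point matches the generating function
  pred <- predict_cwm(fit, d$env$soil_ph[1], d$env$pine_ba[1])
  expect_lt(abs(pred$cwm - d$truth[1]), 0.05)
  expect_false(pred$extrapolated)

  # residual sum of squares no worse than the intercept-only model
  rss <- sum(residuals(fit$gam)^2)
  rss0 <- sum((d$cwm$seed_mass - mean(d$cwm$seed_mass))^2)
  expect_lte(rss, rss0)
})

test_that("pure-noise CWM yields near-zero adjusted R-squared", {
  # under the null, adjusted R2 of the smooth fit centers near zero; GCV
  # occasionally overfits a single replicate, so the check is on the mean
  r2s <- vapply(1:8, function(seed) {
    set.seed(seed)
    n <- 96
    env <- environment_table(data.frame(
      sample_id = sprintf("q%03d", 1:n),
      soil_ph = runif(n, 5.5, 7.5), pine_ba = runif(n, 0, 59)))
    cwm <- data.frame(unit_id = env$sample_id, srl = rnorm(n))
    class(cwm) <- c("cwm_table", "data.frame")
    fit_cwm_model(cwm, env, "srl")$adj_r2
  }, numeric(1))
  expect_lte(mean(r2s), 0.1)
  expect_true(all(r2s < 0.3))
})

test_that("degenerate designs are refused or flagged", {
  d <- linear_cwm_data()
  env_const <- d$env
  env_const$pine_ba <- rep(10, nrow(env_const))
  expect_error(fit_cwm_model(d$cwm, environment_table(as.data.frame(env_const)),
                             "seed_mass"), "degenerate")

  small <- d
  small$cwm <- small$cwm[1:10, ]
  expect_error(fit_cwm_model(small$cwm, small$env, "seed_mass"), "at least 20")

  const <- d
  const$cwm$seed_mass <- rep(3, nrow(const$cwm))
  fit <- fit_cwm_model(const$cwm, const$env, "seed_mass")
  expect_true(fit$degenerate)
  expect_equal(fit$adj_r2, 0)
})

test_that("predictions outside the training range carry an extrapolation flag", {
  d <- linear_cwm_data()
  fit <- fit_cwm_model(d$cwm, d$env, "seed_mass")
  expect_warning(pred <- predict_cwm(fit, 2.0, 10), "training range")
  expect_true(pred$extrapolated)
  expect_true(is.finite(pred$cwm))
  expect_error(predict_cwm(fit, NA_real_, 10), "finite")
})

test_that("infinite smoothing penalty recovers the least-squares plane", {
  d <- linear_cwm_data(noise_sd = 0.3)
  fit <- fit_cwm_model(d$cwm, d$env, "seed_mass", sp = c(1e9, 1e9))
  ols <- lm(seed_mass ~ soil_ph + pine_ba,
            data = cbind(d$cwm, d$env[c("soil_ph", "pine_ba")]))
  expect_equal(unname(fitted(fit$gam)), unname(fitted(ols)), tolerance = 1e-4)
})

test_that("fits serialize to JSON and reconstruct identically", {
  d <- linear_cwm_data(noise_sd = 0.2)
  fit <- fit_cwm_model(d$cwm, d$env, "seed_mass")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_cwm_fit(fit, tmp)
  back <- read_cwm_fit(tmp)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-8)
  grid <- expand.grid(soil_ph = c(5.9, 6.8), pine_ba = c(10, 50))
  expect_equal(predict_cwm(back, grid$soil_ph, grid$pine_ba)$cwm,
               predict_cwm(fit, grid$soil_ph, grid$pine_ba)$cwm,
               tolerance = 1e-10)
  # refitting on the same data reproduces the fit exactly
  again <- fit_cwm_model(d$cwm, d$env, "seed_mass")
  expect_identical(again$coefficients, fit$coefficients)
})

test_that("treatment-level constraint prediction produces one row per treatment", {
  d <- linear_cwm_data(noise_sd = 0.05)
  fits <- list(seed_mass = fit_cwm_model(d$cwm, d$env, "seed_mass"))
  treatments <- data.frame(
    treatment = c("sun-limestone", "sun-basalt", "shade-limestone", "shade-basalt"),
    soil_ph = c(6.8, 5.9, 6.8, 5.9), pine_ba = c(0, 0, 59, 59))
  tab <- suppressWarnings(predict_cwm_table(fits, treatments))
  expect_equal(tab$unit_id, treatments$treatment)
  expect_equal(tab$seed_mass,
               suppressWarnings(predict_cwm(fits$seed_mass, treatments$soil_ph,
                                            treatments$pine_ba))$cwm)
  # BA = 0 lies below the sampled field range here, so the flag is raised
  expect_true(any(attr(tab, "extrapolated")))
})
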