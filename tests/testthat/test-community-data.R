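test_that("trait table CSV round-trips and validates", {
  tr <- grass_traits()
  expect_s3_class(tr, "trait_table")
  expect_equal(nrow(tr), 5)
  expect_equal(tr$species_id[1], "Bouteloua_gracilis")  # row order preserved

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(tr, tmp)
  expect_equal(as.data.frame(read_trait_table(tmp)), as.data.frame(tr))

  df <- as.data.frame(tr)
  df$species_id[2] <- df$species_id[1]
  expect_error(trait_table(df), "duplicate species_id")

  df <- as.data.frame(tr)
  df$srl[3] <- -1
  expect_error(trait_table(df), df$species_id[3])

  expect_error(trait_table(data.frame(species_id = "a", seed_mass = 1)),
               "missing column")
  df <- as.data.frame(tr)
  df$flowering_date[1] <- 400
  expect_error(trait_table(df), "flowering_date")
})

test_that("relativize divides rows by their totals and flags empty samples", {
  m <- community_matrix(rbind(q1 = c(30, 10, 10), q2 = c(0, 0, 0)),
                        kind = "cover")
  rel <- relativize(m)
  expect_equal(unname(rel[1, ]), c(0.6, 0.2, 0.2))
  expect_equal(unname(rel[2, ]), c(0, 0, 0))
  expect_equal(unname(attr(rel, "zero_rows")), c(FALSE, TRUE))
  expect_identical(attr(rel, "kind"), "relative")

  single <- relativize(community_matrix(matrix(7, 1, 1), kind = "count"))
  expect_equal(as.numeric(single), 1)

  # idempotent on relative input
  expect_equal(unclass(relativize(rel)), unclass(rel), tolerance = 1e-12)

  expect_error(community_matrix(matrix(c(-1, 2), 1), kind = "cover"),
               "nonnegative")
})

test_that("community matrix CSV round-trips with treatment labels", {
  obs <- pot_counts()
  expect_equal(dim(obs), c(66, 5))
  expect_equal(as.integer(table(attr(obs, "treatment"))[c("sun-limestone", "sun-basalt")]),
               c(17L, 17L))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_community_matrix(obs, tmp)
  back <- read_community_matrix(tmp, kind = "count")
  expect_equal(unclass(back), unclass(obs))
  expect_equal(attr(back, "treatment"), attr(obs, "treatment"))
})

test_that("compute_cwm is the abundance-weighted trait mean", {
  tr <- toy_traits(c(5, 9))
  rel <- community_matrix(
    matrix(c(1, 0.5, 0, 0.5), 2, dimnames = list(c("u1", "u2"), tr$species_id)),
    kind = "relative")
  cwm <- compute_cwm(rel, tr)
  expect_equal(cwm$seed_mass, c(5, 7))

  tr3 <- toy_traits(c(1, 2, 3), trait = "srl")
  rel3 <- community_matrix(
    matrix(c(0.2, 0.3, 0.5), 1, dimnames = list("u", tr3$species_id)),
    kind = "relative")
  expect_equal(compute_cwm(rel3, tr3)$srl, 2.3)

  # species missing from the trait table is a named lookup error
  rel_bad <- community_matrix(
    matrix(c(0.5, 0.5), 1, dimnames = list("u", c("sp1", "ghost"))),
    kind = "relative")
  expect_error(compute_cwm(rel_bad, tr), "ghost")
})

test_that("CWM properties: uniform weights, permutation equivariance, convexity", {
  set.seed(11)
  tr <- trait_table(data.frame(
    species_id = paste0("s", 1:8),
    seed_mass = rlnorm(8), srl = rlnorm(8, 4), flowering_date = runif(8, 100, 250)))
  p <- matrix(1 / 8, 3, 8, dimnames = list(paste0("u", 1:3), tr$species_id))
  cwm <- compute_cwm(community_matrix(p, kind = "relative"), tr)
  for (trn in trait_names(tr)) {
    expect_equal(cwm[[trn]], rep(mean(tr[[trn]]), 3))
  }

  # random simplex rows; permuting species columns together with trait rows
  w <- matrix(rgamma(5 * 8, 1), 5, 8)
  w <- w / rowSums(w)
  dimnames(w) <- list(paste0("u", 1:5), tr$species_id)
  base <- compute_cwm(community_matrix(w, kind = "relative"), tr)
  perm <- sample(8)
  tr_p <- trait_table(as.data.frame(tr)[perm, ])
  w_p <- w[, perm]
  also <- compute_cwm(community_matrix(w_p, kind = "relative"), tr_p)
  expect_equal(as.data.frame(also), as.data.frame(base))

  # convexity: CWM within [min, max] of traits of species present
  for (trn in trait_names(tr)) {
    expect_true(all(base[[trn]] >= min(tr[[trn]]) - 1e-12 &
                      base[[trn]] <= max(tr[[trn]]) + 1e-12))
  }

  # zero rows give missing CWMs
  w0 <- rbind(w, u6 = rep(0, 8))
  cwm0 <- compute_cwm(community_matrix(w0, kind = "relative"), tr)
  expect_true(all(is.na(cwm0[6, trait_names(tr)])))
})

test_that("environment table validates ranges and uniqueness", {
  env <- environment_table(data.frame(sample_id = c("a", "b"),
                                      soil_ph = c(6.1, 7.0), pine_ba = c(0, 30)))
  expect_s3_class(env, "environment_table")
  expect_error(environment_table(data.frame(sample_id = c("a", "a"),
                                            soil_ph = c(6, 6), pine_ba = c(1, 1))),
               "duplicate")
  expect_error(environment_table(data.frame(sample_id = "a", soil_ph = 6,
                                            pine_ba = -2)), "pine_ba")
  expect_error(environment_table(data.frame(sample_id = "a", soil_ph = 12,
                                            pine_ba = 1)), "soil_ph")
})
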