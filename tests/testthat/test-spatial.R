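test_that("cross-class NN distances match hand geometry", {
  src <- point_set(0, 0)
  tgt <- point_set(c(3, 10), c(4, 0))
  s <- nn_distances(src, tgt)
  expect_identical(s$distances, 5)           # 3-4-5 triangle
  expect_identical(s$median_distance, 5)
  expect_equal(s$mode, "point_to_point")

  s2 <- nn_distances(point_set(c(0, 10), c(0, 0)), point_set(0, 0))
  expect_identical(s2$distances, c(0, 10))
  expect_identical(s2$median_distance, 5)    # even-count median
})

test_that("empty source or target is an error, not distance Inf", {
  pts <- point_set(1, 1)
  none <- point_set(numeric(0), numeric(0))
  expect_error(nn_distances(none, pts), class = "nncoloc_empty_source")
  expect_error(nn_distances(pts, none), class = "nncoloc_empty_target")
  expect_error(nn_distances_self(pts), class = "nncoloc_too_few_points")
  expect_error(distance_to_region(pts, matrix(FALSE, 3, 3)),
               class = "nncoloc_empty_target")
})

test_that("self NN distances exclude by index so duplicates are neighbours", {
  s <- nn_distances_self(point_set(c(0, 0, 4), c(0, 3, 3)))
  expect_identical(s$distances, c(3, 3, 4))
  expect_identical(s$median_distance, 3)
  dup <- nn_distances_self(point_set(c(1, 1), c(1, 1)))
  expect_identical(dup$distances, c(0, 0))
  expect_identical(dup$median_distance, 0)
})

test_that("point-to-region distance uses nearest region pixel center", {
  region <- matrix(FALSE, 8, 8); region[, 1] <- TRUE      # column x = 0
  s <- distance_to_region(point_set(3, 5), region)
  expect_identical(s$distances, 3)
  on_px <- distance_to_region(point_set(2, 4), region | (row(region) == 5))
  expect_identical(on_px$distances, 0)
})

test_that("all three NN operations equal brute force bitwise on random inputs", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(1:120, 1); m <- sample(1:80, 1)
    src <- rand_points(n, c(256, 256)); tgt <- rand_points(m, c(256, 256))
    expect_identical(nn_distances(src, tgt)$distances,
                     bf_nn(src$x, src$y, tgt$x, tgt$y))
  }
  for (rep in 1:30) {
    n <- sample(2:150, 1)
    p <- rand_points(n, c(128, 128))
    expect_identical(nn_distances_self(p)$distances, bf_nn_self(p$x, p$y))
  }
  for (rep in 1:15) {
    region <- matrix(runif(40 * 40) < 0.05, 40, 40)
    if (!any(region)) region[17, 23] <- TRUE
    p <- rand_points(sample(1:50, 1), c(40, 40))
    expect_identical(distance_to_region(p, region)$distances,
                     bf_region(p$x, p$y, region))
  }
})

test_that("null sampling is deterministic and supports a single valid pixel", {
  mask1 <- region_mask(matrix(c(rep(FALSE, 12), TRUE, rep(FALSE, 12)), 5, 5))
  tgt <- point_set(2, 2)   # the lone valid pixel center
  null <- sample_null(1, tgt, mask1, n_rounds = 10, seed = 4)
  expect_true(all(null$sampled_medians <= sqrt(0.5) + 1e-12))
  expect_lt(null$sd_median, 0.5)

  mask <- full_mask(64)
  tgt2 <- rand_points(10, c(64, 64))
  a <- sample_null(20, tgt2, mask, n_rounds = 50, seed = 99)
  b <- sample_null(20, tgt2, mask, n_rounds = 50, seed = 99)
  expect_identical(a$sampled_medians, b$sampled_medians)
})

test_that("null mean matches an independent pure-R CSR simulation", {
  set.seed(31)
  shape <- c(256, 256)
  tgt <- rand_points(50, shape)
  mask <- full_mask(256)
  null <- sample_null(100, tgt, mask, n_rounds = 2000, seed = 8)

  # independent oracle: vectorized R simulation of the same null
  oracle <- replicate(4000, {
    px <- sample.int(256, 100, TRUE) - 1 + runif(100, -0.5, 0.5)
    py <- sample.int(256, 100, TRUE) - 1 + runif(100, -0.5, 0.5)
    median(bf_nn(px, py, tgt$x, tgt$y))
  })
  se <- sqrt(null$sd_median^2 / 2000 + var(oracle) / 4000)
  expect_lt(abs(null$mean_median - mean(oracle)), 3 * se)
})

test_that("association score follows the normalization and sign convention", {
  null <- mc_null(c(8, 9, 10, 11, 12))   # mean 10, pop sd sqrt(2)
  sdv <- sqrt(2)
  obs_eq <- nn_summary(rep(10, 5))
  expect_identical(association_score(obs_eq, null)$score, 0)

  obs_near <- nn_summary(rep(10 - 2 * sdv, 5))
  expect_equal(association_score(obs_near, null)$score, 2)
  obs_far <- nn_summary(rep(10 + 2 * sdv, 5))
  expect_equal(association_score(obs_far, null)$score, -2)
  # percentile: strict inequality, ties count against association
  expect_identical(association_score(obs_eq, null)$percentile, 2 / 5)

  degen <- mc_null(rep(3, 10))
  expect_error(association_score(obs_eq, degen),
               class = "nncoloc_degenerate_null")
  null_self <- mc_null(c(8, 12), mode = "self")
  expect_error(association_score(nn_summary(10, "point_to_point"), null_self),
               class = "nncoloc_mode_mismatch")
})

test_that("analyze_sample recovers attraction, randomness and repulsion", {
  base <- list(shape = c(256L, 256L), n_parents = 20L, n_offspring = 80L)
  att <- generate_sample(synthetic_spec(shape = base$shape,
                                        n_parents = base$n_parents,
                                        n_offspring = base$n_offspring,
                                        pattern = "attracted", sigma_c = 5,
                                        seed = 71L))
  fit_att <- analyze_sample(att$offspring, att$parents, att$mask,
                            n_rounds = 2000, seed = 11)
  expect_gt(fit_att$score, 2)

  inh <- generate_sample(synthetic_spec(shape = base$shape,
                                        n_parents = base$n_parents,
                                        n_offspring = base$n_offspring,
                                        pattern = "inhibited", r_min = 30,
                                        seed = 71L))
  fit_inh <- analyze_sample(inh$offspring, inh$parents, inh$mask,
                            n_rounds = 2000, seed = 11)
  expect_lt(fit_inh$score, 0)

  csr <- generate_sample(synthetic_spec(shape = base$shape,
                                        n_parents = base$n_parents,
                                        n_offspring = base$n_offspring,
                                        pattern = "csr", seed = 71L))
  fit_csr <- analyze_sample(csr$offspring, csr$parents, csr$mask,
                            n_rounds = 2000, seed = 11)
  expect_lt(abs(fit_csr$score), 3)
})

test_that("the score is invariant under coordinate scaling and translation", {
  set.seed(17)
  meds <- runif(500, 20, 30)
  dists <- runif(101, 10, 40)
  base <- association_score(nn_summary(dists), mc_null(meds))
  for (c in c(2, 0.5)) {           # power-of-two scale: exact in floats
    scaled <- association_score(nn_summary(dists * c), mc_null(meds * c))
    expect_identical(scaled$score, base$score)
    expect_identical(scaled$observed$median_distance,
                     base$observed$median_distance * c)
    expect_identical(scaled$null$mean_median, base$null$mean_median * c)
    expect_identical(scaled$percentile, base$percentile)
  }
  gen <- association_score(nn_summary(dists * 1.7), mc_null(meds * 1.7))
  expect_equal(gen$score, base$score, tolerance = 1e-12)

  src <- rand_points(30, c(100, 100)); tgt <- rand_points(12, c(100, 100))
  d0 <- nn_distances(src, tgt)$distances
  src_t <- point_set(src$x + 37, src$y - 12)
  tgt_t <- point_set(tgt$x + 37, tgt$y - 12)
  expect_equal(nn_distances(src_t, tgt_t)$distances, d0, tolerance = 1e-12)
})

test_that("empirical percentile agrees with the normal approximation", {
  set.seed(5)
  tgt <- rand_points(50, c(512, 512))
  mask <- full_mask(512)
  null <- sample_null(150, tgt, mask, n_rounds = 10000, seed = 21)
  for (k in c(-1, 0, 1, 2)) {
    obs <- nn_summary(rep(null$mean_median - k * null$sd_median, 151))
    fit <- association_score(obs, null)
    expect_lt(abs(fit$percentile - pnorm(fit$score)), 0.02)
  }
})

test_that("per-sample seeds derived from one base seed are order-independent", {
  s1 <- derive_seed(42, "sampleA")
  expect_identical(s1, derive_seed(42, "sampleA"))
  expect_false(s1 == derive_seed(42, "sampleB"))
  expect_false(s1 == derive_seed(43, "sampleA"))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("analyze_sample is bit-reproducible and mode-complete", {
  set.seed(9)
  mask <- full_mask(64)
  src <- rand_points(25, c(64, 64)); tgt <- rand_points(10, c(64, 64))
  a <- analyze_sample(src, tgt, mask, n_rounds = 300, seed = 2, sample_id = "s")
  b <- analyze_sample(src, tgt, mask, n_rounds = 300, seed = 2, sample_id = "s")
  expect_identical(a$score, b$score)
  expect_identical(a$null$sampled_medians, b$null$sampled_medians)

  region <- matrix(FALSE, 64, 64); region[1:4, ] <- TRUE
  mask_r <- region_mask(matrix(TRUE, 64, 64) & !region,
                        excluded = list(epithelium = region))
  fr <- analyze_sample(src, "epithelium", mask_r, mode = "point_to_region",
                       n_rounds = 300, seed = 2)
  expect_equal(fr$observed$mode, "point_to_region")
  expect_true(is.finite(fr$score))

  fs <- analyze_sample(src, NULL, mask, mode = "self", n_rounds = 300, seed = 2)
  expect_equal(fs$observed$mode, "self")
  expect_true(is.finite(fs$score))
})

test_that("nn_assoc methods expose the fit consistently", {
  set.seed(13)
  mask <- full_mask(48)
  fit <- analyze_sample(rand_points(20, c(48, 48)), rand_points(8, c(48, 48)),
                        mask, n_rounds = 200, seed = 3, sample_id = "m")
  expect_identical(unname(coef(fit)), fit$score)
  expect_output(print(fit), "association score")
  sm <- summary(fit)
  expect_true(sm$call %in% c("association", "none", "repulsion"))
  draws <- simulate(fit, nsim = 50, seed = 1)
  expect_true(all(draws %in% fit$null$sampled_medians))
  expect_length(residuals(fit), fit$observed$n_source)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
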