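test_that("the deterministic recursion reproduces hand-iterated values", {
  tr <- expected_frequency_trajectory(10)
  # F1 (0.5, 0) -> F2 (0.25, 0.5) -> F3 (0.375, 0.25)
  expect_equal(tr$q_f[1:3], c(0.5, 0.25, 0.375))
  expect_equal(tr$q_m[1:3], c(0, 0.5, 0.25))
  expect_equal(tr$q_f[6], 0.328125)
  expect_equal(tr$q_f[10], 0.3330078125)
  # the weighted frequency is conserved exactly at every generation
  expect_equal(tr$weighted, rep(1 / 3, 10))
  expect_error(expected_frequency_trajectory(5, c(q_f = 1.2, q_m = 0)),
               "frequencies")
})

test_that("expected dominant carrier frequencies follow the product rule", {
  tr <- expected_frequency_trajectory(10)
  ph <- expected_dominant_phenotype(tr)
  expect_equal(ph$carrier_freq[1], 1)        # all F1 daughters carry m
  expect_equal(ph$carrier_freq[2], 1)        # 1 - 0.5 * 0
  expect_equal(ph$carrier_freq[6], 0.892578125)
  # boundary: an all-y parental pool leaves no carriers
  tr_y <- data.frame(generation = 1:2, q_f = c(1, 1), q_m = c(1, 1))
  expect_equal(expected_dominant_phenotype(tr_y)$carrier_freq[2], 0)
})

test_that("the stochastic simulator conserves the weighted frequency", {
  cfg <- marker_config("codominant")
  rep1 <- simulate_wf_replicate(cfg, seed = 1)
  rep2 <- simulate_wf_replicate(cfg, seed = 1)
  expect_identical(rep1, rep2)
  expect_equal(rep1$trajectory$q_f[1], 0.5)
  expect_equal(rep1$trajectory$q_m[1], 0)
  sim <- venomevol:::sim_wf_batch(cfg, n_pop = 10000, n_generations = 10,
                                  seed = 2)
  w10 <- (2 * sim$q_f[10, ] + sim$q_m[10, ]) / 3
  expect_lt(abs(mean(w10) - 1 / 3), 3 * sd(w10) / sqrt(length(w10)))
})

test_that("summary statistics aggregate observed-expected deviations", {
  ds <- data.frame(replicate = c(1, 2), generation = c(6, 6),
                   n_mm = c(4, 4), n_my = c(4, 4), n_yy = c(2, 2))
  attr(ds, "kind") <- "codominant"
  # allele counting: (2*2 + 4) / 20 = 0.4
  expect_equal(venomevol:::observed_frequencies(ds)$freq, c(0.4, 0.4))
  expect_equal(summary_statistic(ds, c("6" = 0.4)), 0)
  # deviations +0.1 and -0.3 average to -0.1
  expect_equal(summary_statistic(ds, c("6" = 0.3)) * 2, 0.2)
  ds$n_yy <- c(5, 1); ds$n_mm <- c(1, 5)
  f <- venomevol:::observed_frequencies(ds)$freq
  expect_equal(summary_statistic(ds, c("6" = f[1] - 0.1)),
               mean(c(0.1, f[2] - f[1] + 0.1)))
  expect_equal(summary_statistic(ds, c("6" = 0.5), type = "abs_dev"),
               mean(abs(f - 0.5)))
  expect_error(summary_statistic(ds[0, ], c("6" = 0.4)), "empty")
})

test_that("the doubled unilateral p-value follows the stated convention", {
  cfg <- marker_config("codominant", n_replicates = 2,
                       generations_assayed = 6)
  toy_null <- structure(list(stats = c(-0.2, -0.1, 0.0, 0.1),
                             expected = c("6" = 0.475),
                             cfg = cfg, n_sim = 4, seed = NULL,
                             type = "mean_dev"),
                        class = "null_distribution")
  # observed frequencies 0.35 and 0.30 against expected 0.475:
  # statistic = mean(-0.125, -0.175) = -0.15
  ds <- data.frame(replicate = 1:2, generation = 6,
                   n_mm = c(4, 4), n_my = c(5, 6), n_yy = c(1, 0))
  attr(ds, "kind") <- "codominant"
  class(ds) <- c("marker_dataset", "data.frame")
  expect_equal(summary_statistic(ds, toy_null$expected), -0.15)
  dt <- drift_test(ds, cfg, null = toy_null)
  # lower tail, k = 1 null value <= observed: p = min(1, 2 * 2 / 5) = 0.8
  expect_equal(dt$tail, "lower")
  expect_equal(dt$p_value, 0.8)
  # a central observed statistic caps at p = 1
  ds_mid <- data.frame(replicate = 1:2, generation = 6,
                       n_mm = c(3, 3), n_my = c(4, 5), n_yy = c(3, 2))
  attr(ds_mid, "kind") <- "codominant"
  class(ds_mid) <- c("marker_dataset", "data.frame")
  toy_null$expected <- c("6" = 0.525)  # observed statistic becomes -0.05
  dt_mid <- drift_test(ds_mid, cfg, null = toy_null)
  expect_equal(dt_mid$p_value, 1)
})

test_that("drift test wiring validates the design and reports expectations", {
  cfg <- marker_config("codominant")
  obs <- simulate_marker_dataset(cfg, seed = 3)$dataset
  null <- build_null_distribution(cfg, n_sim = 1000, seed = 4)
  dt <- drift_test(obs, cfg, null = null)
  expect_true(dt$p_value > 0 && dt$p_value <= 1)
  # simulated-mean expectations track the deterministic recursion
  expect_equal(unname(dt$expected), unname(dt$expected_deterministic),
               tolerance = 0.02)
  bad_cfg <- marker_config("codominant", n_replicates = 4)
  expect_error(drift_test(obs, bad_cfg, null = null), "replicates")
  expect_warning(build_null_distribution(cfg, n_sim = 200, seed = 1),
                 "coarse")
})

test_that("dominant-marker nulls carry the drift-induced covariance", {
  cfg <- marker_config("dominant")
  null <- build_null_distribution(cfg, n_sim = 2000, seed = 5)
  tr <- expected_frequency_trajectory(10)
  det <- expected_dominant_phenotype(tr)
  # the simulator mean carrier frequency sits below the infinite-population
  # product formula (drift makes q_f and q_m positively covary)
  det6 <- det$carrier_freq[det$generation == 6]
  expect_lt(unname(null$expected["6"]), det6)
  expect_equal(unname(null$expected["6"]), det6, tolerance = 0.05)
  obs <- simulate_marker_dataset(cfg, seed = 6)$dataset
  dt <- drift_test(obs, cfg, null = null)
  expect_true(dt$p_value > 0 && dt$p_value <= 1)
})

test_that("Box-Cox transforms apply the stated branches", {
  expect_equal(boxcox_transform(3, 1), 2)
  expect_equal(boxcox_transform(exp(1), 0), 1)
  expect_equal(boxcox_transform(1, 0.23), 0)
  expect_error(boxcox_transform(c(2, -1), 0.23), "positive")
  # inverse round trip on both branches
  x <- c(0.5, 1, 4.7)
  expect_equal(venomevol:::inv_boxcox(boxcox_transform(x, 0.23), 0.23), x)
  expect_equal(venomevol:::inv_boxcox(boxcox_transform(x, 0), 0), x)
})

test_that("the corrected Western quantity is a median ratio", {
  expect_equal(corrected_lbgap2(10, c(2, 4, 6)), 2.5)
  expect_equal(corrected_lbgap2(7, rep(3.5, 5)), 2)
  # common exposure scaling cancels
  expect_equal(corrected_lbgap2(10 * 3, c(2, 4, 6) * 3),
               corrected_lbgap2(10, c(2, 4, 6)))
  expect_error(corrected_lbgap2(10, numeric(0)), "reference")
  expect_error(corrected_lbgap2(10, c(0, 0, 0)), "reference")
})

test_that("the mixed model recovers cell structure and nulls", {
  # identical cell means, no random-effect variance: contrasts estimate zero
  d <- design_table(n_replicates = 4, n_per_cell = 5, reduced_cell = NULL)
  lb <- simulate_lbgap2_dataset(d, effects = list(mu = 2, host_R = 0,
                                                  slope_S = 0, slope_R = 0),
                                sd_population = 0, sd_residual = 0.1,
                                seed = 1)
  fit <- lbgap2_mixed_model(lb)
  est <- fit$tukey$test$coefficients
  se <- fit$tukey$test$sigma
  expect_true(all(abs(est) < 4 * se))
  expect_equal(fit$lambda, 0.23)
  expect_length(fit$letters, 6)
  expect_error(lbgap2_mixed_model(lb[, -which(names(lb) == "host")]),
               "host")
  lb_bad <- lb; lb_bad$value[1] <- -1
  expect_error(lbgap2_mixed_model(lb_bad), "positive")
})

test_that("the mixed model flags a host-specific decline, not the other host", {
  # decline of 2 residual sd between F2 and F6 on the R host only
  d <- design_table()
  hit_r <- hit_s <- logical(40)
  for (s in seq_len(40)) {
    lb <- simulate_lbgap2_dataset(
      d, effects = list(mu = 2, host_R = 0, slope_S = 0, slope_R = -0.15),
      sd_population = 0.1, sd_residual = 0.3, seed = 900 + s)
    fit <- lbgap2_mixed_model(lb)
    pv <- fit$tukey$test$pvalues
    names(pv) <- rownames(fit$tukey$linfct)
    hit_r[s] <- pv[["R_F6 - R_F2"]] < 0.05
    hit_s[s] <- pv[["S_F6 - S_F2"]] < 0.05
  }
  expect_gte(mean(hit_r), 0.8)
  expect_lte(mean(hit_s), 0.1)
})

test_that("the Tukey stage controls the family-wise error under the null", {
  d <- design_table()
  any_rej <- logical(200)
  for (s in seq_len(200)) {
    lb <- simulate_lbgap2_dataset(
      d, effects = list(mu = 2, host_R = 0, slope_S = 0, slope_R = 0),
      sd_population = 0.1, sd_residual = 0.3, seed = 5000 + s)
    fit <- lbgap2_mixed_model(lb)
    any_rej[s] <- any(fit$tukey$test$pvalues < 0.05)
  }
  expect_gte(mean(any_rej), 0.02)
  expect_lte(mean(any_rej), 0.08)
})
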