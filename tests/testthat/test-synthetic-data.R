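test_that("default design reproduces the study layout", {
  d <- design_table()
  expect_s3_class(d, "design_table")
  expect_equal(nrow(d), 474)
  # population determined by (replicate, host); 16 populations
  expect_equal(length(unique(d$population)), 16)
  expect_true(all(tapply(d$population,
                         paste(d$replicate, d$host),
                         function(x) length(unique(x))) == 1))
  # every cell has 10 females except the one reduced F2 S cell with 4
  cell_n <- table(d$replicate, d$host, d$generation)
  expect_equal(sum(cell_n == 4), 1)
  expect_equal(cell_n["1", "S", "2"], 4, ignore_attr = TRUE)
  expect_true(all(cell_n %in% c(4, 10)))
  # deterministic
  expect_identical(d, design_table())
  expect_error(design_table(reduced_cell = list(replicate = 99, host = "S",
                                                generation = 2, n = 4)),
               "reduced_cell")
})

test_that("parental profiles are deterministic with mixed origins", {
  p <- default_parental_profiles(34)
  expect_equal(nrow(p), 34)
  expect_true(all(diff(p$position) > 0))
  expect_true(all(p$position > 0 & p$position < 1))
  expect_true(all(p$intensity_ISm + p$intensity_ISy > 0))
  o <- band_origins(p)
  expect_true(any(o > 0.5) && any(o < 0.5) && any(o == 0.5))
  # two-band fixture pins the origin arithmetic
  expect_equal(band_origins(default_parental_profiles(2)), c(0.8, 0))
  expect_identical(default_parental_profiles(34), p)
  expect_error(default_parental_profiles(1), "n_bands")
})

test_that("noise-free band simulation degenerates to the baseline", {
  d <- small_design()
  p <- default_parental_profiles(6)
  eff <- effect_spec(p, replicate_sd = 0, residual_sd = 0)
  sim <- simulate_band_matrix(d, p, eff, seed = 1)
  baseline <- (p$intensity_ISm + p$intensity_ISy) / 2
  expect_equal(sim$matrix$intensity,
               matrix(baseline, nrow(d), 6, byrow = TRUE,
                      dimnames = dimnames(sim$matrix$intensity)))
  expect_false(any(sim$truth$selected_S | sim$truth$selected_R))
})

test_that("band simulation recovers an imposed trend by least squares", {
  # ~10k individuals; the S-host regression of intensity on generation must
  # recover the simulated slope of 2 within 3 standard errors
  d <- design_table(n_replicates = 2, n_per_cell = 850, reduced_cell = NULL)
  p <- default_parental_profiles(4)
  eff <- effect_spec(p, slope_S = c(2, 0, 0, 0), replicate_sd = 0,
                     residual_sd = 1, baseline = 20)
  sim <- simulate_band_matrix(d, p, eff, seed = 2)
  s <- d$host == "S"
  fit <- summary(lm(sim$matrix$intensity[s, 1] ~ I(d$generation[s] - 2)))
  expect_lt(abs(fit$coefficients[2, 1] - 2), 3 * fit$coefficients[2, 2])
  expect_true(all(sim$matrix$intensity >= 0))
  expect_equal(sim$truth$selected_S, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("passenger bands track their source at the requested correlation", {
  d <- design_table()
  p <- default_parental_profiles(8)
  eff <- recovery_effect_spec(p, n_direct = 2, n_passenger = 1, rho = 0.8)
  sim <- simulate_band_matrix(d, p, eff, seed = 3)
  m <- sim$matrix$intensity
  expect_equal(cor(m[, 3], m[, 1]), 0.8, tolerance = 0.05)
  expect_true(sim$truth$passenger[3])
  expect_identical(sim$truth$source[3], 1L)
})

test_that("lane simulation matches closed-form peak properties", {
  p <- default_parental_profiles(3)
  d <- design_table(n_replicates = 1, hosts = "S", generations = 2,
                    n_per_cell = 1, reduced_cell = NULL)
  # zero heights, zero noise, no baseline -> flat zero profile
  bm0 <- band_matrix(matrix(0, 1, 3), d)
  g0 <- gel_params(noise_sd = 0, baseline_intercept = 0, baseline_slope = 0)
  lanes0 <- simulate_lane_profiles(bm0, p, g0, seed = 1)
  expect_equal(max(abs(lanes0[[1]]$intensity)), 0)
  # one band of height h: apex = h at the band position within one grid step
  h <- 3.7
  bm1 <- band_matrix(matrix(c(0, h, 0), 1), d)
  lane1 <- simulate_lane_profiles(bm1, p, g0, seed = 1)[[1]]
  # apex sits on the sampling grid, so it can sit half a grid step off-peak
  expect_equal(max(lane1$intensity), h, tolerance = 5e-3)
  dx <- diff(lane1$distance[1:2])
  expect_lt(abs(lane1$distance[which.max(lane1$intensity)] - p$position[2]),
            dx + 1e-12)
  # peak areas integrate to h * sigma * sqrt(2 pi) within 1% (trapezoid)
  heights <- c(2, 5, 1)
  bm3 <- band_matrix(matrix(heights, 1), d)
  g3 <- gel_params(n_points = 4000, noise_sd = 0, baseline_intercept = 0,
                   baseline_slope = 0)
  lane3 <- simulate_lane_profiles(bm3, p, g3, seed = 1)[[1]]
  x <- lane3$distance; y <- lane3$intensity
  cuts <- c(0, (p$position[-3] + p$position[-1]) / 2, 1)
  for (b in 1:3) {
    sel <- x >= cuts[b] & x <= cuts[b + 1]
    area <- sum(diff(x[sel]) * (y[sel][-1] + y[sel][-sum(sel)]) / 2)
    expect_equal(area, heights[b] * g3$peak_sd * sqrt(2 * pi),
                 tolerance = 0.01)
  }
  # control lanes appear once per gel, with both parental roles
  bm <- band_matrix(matrix(1, 30, 3), small_design(n_replicates = 5, n_per_cell = 1))
  lanes <- simulate_lane_profiles(bm, p, gel_params(lanes_per_gel = 12), seed = 1)
  roles <- vapply(lanes, function(l) l$role, character(1))
  expect_equal(sum(roles == "ISm_control"), 3)
  expect_equal(sum(roles == "ISy_control"), 3)
})

test_that("marker simulation obeys Mendelian and selective limits", {
  cfg <- marker_config("codominant")
  md1 <- simulate_marker_dataset(cfg, seed = 9)
  md2 <- simulate_marker_dataset(cfg, seed = 9)
  expect_identical(md1, md2)
  expect_equal(nrow(md1$dataset), 8 * 2)
  expect_true(all(md1$dataset$n_mm + md1$dataset$n_my + md1$dataset$n_yy == 10))
  # lethal selection against allele y in both sexes: y lost by F3
  lethal <- marker_config("codominant",
                          fitness_female = c(mm = 1, my = 0, yy = 0),
                          fitness_male = c(m = 1, y = 0))
  tr <- simulate_marker_dataset(lethal, seed = 4)$frequencies
  expect_true(all(tr$q_f[tr$generation >= 3] == 0))
  expect_true(all(tr$q_m[tr$generation >= 3] == 0))
  # a configuration in which no producible genotype is viable must error
  stuck <- marker_config("codominant",
                         fitness_female = c(mm = 0, my = 0, yy = 1))
  expect_error(simulate_marker_dataset(stuck, seed = 5), "stuck population")
  # dominant and codominant observation models agree on the same genotypes
  cfg_d <- marker_config("dominant")
  co <- simulate_marker_dataset(cfg, seed = 11)$dataset
  do <- simulate_marker_dataset(cfg_d, seed = 11)$dataset
  expect_equal(do$n_carrier, co$n_mm + co$n_my)
  expect_equal(do$n, rep(10, nrow(do)))
})

test_that("neutral drift conserves the weighted allele frequency", {
  # martingale: (2 q_f + q_m) / 3 stays at 1/3 in expectation
  cfg <- marker_config("codominant")
  sim <- venomevol:::sim_wf_batch(cfg, n_pop = 4000, n_generations = 10,
                                  seed = 12)
  w <- (2 * sim$q_f + sim$q_m) / 3
  mc_se <- sd(w[10, ]) / sqrt(ncol(w))
  expect_lt(abs(mean(w[10, ]) - 1 / 3), 3 * mc_se)
  expect_lt(abs(mean(w[6, ]) - 1 / 3), 3 * sd(w[6, ]) / sqrt(ncol(w)))
})

test_that("tiny populations fix by drift at the exact Markov-chain rate", {
  # with one female and one male the (female genotype, male allele) chain has
  # absorbing states (mm, m) and (yy, y); iterating the exact chain from the
  # F1 state (my, m) gives P(not fixed at F10) = 0.140625
  u <- 1; v <- 0                      # u = P{(my, m) or (my, y)}, v = bounce states
  for (g in 2:10) {
    u_new <- 0.5 * u + v
    v <- 0.25 * u
    u <- u_new
  }
  p_fixed <- 1 - (u + v)
  expect_equal(p_fixed, 0.859375)
  cfg <- marker_config("codominant", n_females = 1, n_males = 1)
  sim <- venomevol:::sim_wf_batch(cfg, n_pop = 2000, n_generations = 10,
                                  seed = 13)
  fixed <- sim$q_f[10, ] %in% c(0, 1) & sim$q_m[10, ] == sim$q_f[10, ]
  mc_se <- sqrt(p_fixed * (1 - p_fixed) / 2000)
  expect_lt(abs(mean(fixed) - p_fixed), 3 * mc_se)
})

test_that("continuous-marker generator respects its Box-Cox structure", {
  d <- small_design()
  # no effects, no noise, lambda = 1: inverse transform of mu is mu + 1
  lb <- simulate_lbgap2_dataset(d, effects = list(mu = 2, host_R = 0,
                                                  slope_S = 0, slope_R = 0),
                                sd_population = 0, sd_residual = 0,
                                lambda = 1, seed = 1)
  expect_equal(lb$value, rep(3, nrow(d)))
  # population sd >> residual sd: intraclass correlation near 1 (log branch
  # keeps the inverse transform defined for any linear predictor)
  lb2 <- simulate_lbgap2_dataset(design_table(), sd_population = 2,
                                 sd_residual = 0.02, lambda = 0, seed = 2)
  z <- boxcox_transform(lb2$value, 0)
  between <- var(tapply(z, lb2$population, mean))
  within <- mean(tapply(z, lb2$population, var))
  expect_gt(between / (between + within), 0.99)
})
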