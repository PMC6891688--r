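test_that("axis correlations capture monotone association with control", {
  set.seed(1)
  n <- 474
  scores <- cbind(rnorm(n), rnorm(n))
  m <- cbind(scores[, 1],            # identical to axis 1
             -scores[, 2],           # reversed ranks of axis 2
             rnorm(n),               # noise
             rep(2, n))              # constant band
  tab <- axis_correlations(m, scores)
  expect_equal(tab$rho[tab$band == 1 & tab$axis == 1], 1)
  expect_true(tab$significant[tab$band == 1 & tab$axis == 1])
  expect_equal(tab$rho[tab$band == 2 & tab$axis == 2], -1)
  # constant band: undefined correlation, flagged non-significant
  expect_true(all(is.na(tab$rho[tab$band == 4])))
  expect_false(any(tab$significant[tab$band == 4]))
  # Bonferroni family defaults to 2B
  expect_equal(attr(tab, "family"), 8)
  expect_equal(tab$p_adj, pmin(1, tab$p * 8))
})

test_that("UPGMA clustering follows the absolute-correlation metric", {
  # perfectly anti-correlated bands have distance 0 and share a cluster
  set.seed(2)
  b1 <- rnorm(50)
  m <- cbind(b1, -b1, rnorm(50))
  cl <- upgma_band_clusters(m, threshold = 0.4)
  expect_equal(cl$cluster[[1]], cl$cluster[[2]])
  expect_false(cl$cluster[[3]] == cl$cluster[[1]])
  # hand-checkable UPGMA on an exact correlation structure:
  # |cor| = 0.9 between bands 1-2 and 0.1 with band 3
  C <- rbind(c(1, 0.9, 0.1), c(0.9, 1, 0.1), c(0.1, 0.1, 1))
  x <- matrix_with_correlation(40, C, seed = 3)
  expect_equal(cor(x), C)  # the construction is exact
  cl2 <- upgma_band_clusters(x, threshold = 0.4)
  expect_equal(cl2$cluster[[1]], cl2$cluster[[2]])
  expect_equal(length(unique(cl2$cluster)), 2)
  # merge heights: {1,2} at 0.1, then with 3 at mean(0.9, 0.9) = 0.9
  expect_equal(cl2$tree$height, c(1 - 0.9, 1 - 0.1))
  # constant band: distance 1 to all others, singleton, warned
  expect_warning(cl3 <- upgma_band_clusters(cbind(b1, rnorm(50), rep(1, 50))),
                 "constant")
  expect_equal(length(unique(cl3$cluster)), 3)
})

test_that("independent noise bands end as singletons at threshold 0.4", {
  set.seed(4)
  m <- matrix(rnorm(2000 * 6), 2000)
  cl <- upgma_band_clusters(m, threshold = 0.4)
  expect_equal(length(unique(cl$cluster)), 6)
})

test_that("partial correlations separate direct from indirect association", {
  # axis tracks band A; band B is a noisy copy of A (indirect only)
  set.seed(5)
  retained_a <- retained_b <- logical(200)
  for (s in seq_len(200)) {
    n <- 474
    a <- rnorm(n)
    axis <- a + rnorm(n)
    b <- a + rnorm(n)
    m <- cbind(A = a, B = b, C = rnorm(n))
    scores <- cbind(axis, rnorm(n))
    init <- axis_correlations(m, scores)
    cl <- upgma_band_clusters(m)
    fin <- partial_axis_correlations(m, cl, scores, init)
    retained_a[s] <- fin$significant[fin$band == 1 & fin$axis == 1]
    retained_b[s] <- fin$significant[fin$band == 2 & fin$axis == 1]
  }
  expect_gte(mean(retained_a), 0.9)
  expect_lte(mean(retained_b), 0.1)
})

test_that("degenerate and singleton clusters pass through correctly", {
  set.seed(6)
  n <- 200
  a <- rnorm(n)
  axis <- a + 0.5 * rnorm(n)
  m <- cbind(A = a, B = a, C = rnorm(n))  # B an exact copy of A
  scores <- cbind(axis, rnorm(n))
  init <- axis_correlations(m, scores)
  cl <- upgma_band_clusters(m)
  expect_equal(cl$cluster[[1]], cl$cluster[[2]])
  fin <- partial_axis_correlations(m, cl, scores, init)
  # collinear copies: residuals are numerically zero, neither can remain
  expect_false(fin$significant[fin$band == 1 & fin$axis == 1])
  expect_false(fin$significant[fin$band == 2 & fin$axis == 1])
  expect_equal(unique(fin$stage[fin$band %in% 1:2]), "partial")
  # singleton cluster: final result identical to the initial result
  expect_equal(fin$stage[fin$band == 3], c("initial", "initial"))
  expect_equal(fin$rho[fin$band == 3], init$rho[init$band == 3])
})

test_that("band evolution classification mirrors the reported patterns", {
  mk_final <- function(rho1, p1, rho2, p2) {
    data.frame(band = rep(1:length(rho1), 2),
               axis = rep(1:2, each = length(rho1)),
               rho = c(rho1, rho2), p = c(p1, p2) / 10,
               p_adj = c(p1, p2),
               significant = c(p1, p2) < 0.05,
               stage = "partial", cluster = 1L)
  }
  # a band up on S / down on R of ISm origin, like a strongly selected
  # ISm-line band; and a band down on R only of ISy origin
  fin <- mk_final(rho1 = c(0.4, -0.1), p1 = c(0.001, 0.6),
                  rho2 = c(-0.2, -0.3), p2 = c(0.03, 0.02))
  ev <- classify_band_evolution(fin, origin = c(0.86, 0.06))
  expect_equal(ev$direction_S, c("up", "none"))
  expect_equal(ev$direction_R, c("down", "down"))
  expect_equal(ev$origin_side, c("ISm", "ISy"))
  expect_true(all(ev$selected))
  # nothing significant: no direction, not selected
  fin0 <- mk_final(rho1 = c(0.1, 0.1), p1 = c(0.5, 0.7),
                   rho2 = c(0.1, 0.1), p2 = c(0.6, 0.8))
  ev0 <- classify_band_evolution(fin0, origin = c(0.5, 0.4))
  expect_true(all(ev0$direction_S == "none" & ev0$direction_R == "none"))
  expect_false(any(ev0$selected))
  # the discrimination gate silences all calls when the LDA is not significant
  ev_gate <- classify_band_evolution(fin, origin = c(0.86, 0.06),
                                     discrimination_p = 0.4)
  expect_false(any(ev_gate$selected))
  expect_true(all(ev_gate$direction_S == "none"))
})

test_that("classification is invariant to pre-orientation axis signs", {
  d <- design_table(n_replicates = 3, n_per_cell = 4, reduced_cell = NULL)
  p <- default_parental_profiles(8)
  eff <- effect_spec(p, slope_S = c(0.4, rep(0, 7)),
                     slope_R = c(rep(0, 7), -0.4))
  sim <- simulate_band_matrix(d, p, eff, seed = 7)
  cen <- replicate_center(sim$matrix)
  res <- discriminant_analysis(cen, hg_groups(d))
  classify_from <- function(r) {
    r <- orient_axes(r, d)
    init <- axis_correlations(sim$matrix, r$scores)
    cl <- upgma_band_clusters(sim$matrix)
    fin <- partial_axis_correlations(sim$matrix, cl, r$scores, init)
    classify_band_evolution(fin, band_origins(p))
  }
  ev1 <- classify_from(res)
  res_fl <- res
  for (ax in 1:2) {
    res_fl$loadings[, ax] <- -res_fl$loadings[, ax]
    res_fl$scores[, ax] <- -res_fl$scores[, ax]
    res_fl$centroids[, ax] <- -res_fl$centroids[, ax]
  }
  ev2 <- classify_from(res_fl)
  expect_equal(ev2$direction_S, ev1$direction_S)
  expect_equal(ev2$direction_R, ev1$direction_R)
  expect_equal(ev2$selected, ev1$selected)
})

test_that("axis trade-off summarizes the correlation table", {
  set.seed(8)
  rho1 <- runif(10, -1, 1)
  fin <- data.frame(band = rep(1:10, 2), axis = rep(1:2, each = 10),
                    rho = c(rho1, -rho1 + rnorm(10, 0, 0.05)),
                    p = 0.01, p_adj = 0.01, significant = TRUE,
                    stage = "partial", cluster = 1L)
  tr <- axis_tradeoff(fin)
  expect_lt(tr$rho, -0.8)
  expect_s3_class(tr$regression, "lm")
})

test_that("gated band calling is calibrated under the exchangeable null", {
  # no trends, no population drift: the pipeline should call any band
  # selected in at most ~alpha of the experiments
  d <- design_table(n_replicates = 4, n_per_cell = 3, reduced_cell = NULL)
  p <- default_parental_profiles(12)
  eff <- effect_spec(p, replicate_sd = 0)
  groups <- hg_groups(d)
  any_flag <- logical(150)
  for (s in seq_len(150)) {
    sim <- simulate_band_matrix(d, p, eff, seed = 40000 + s)
    cen <- replicate_center(sim$matrix)
    lda <- orient_axes(discriminant_analysis(cen, groups), d)
    pt <- lda_permutation_test(cen, groups, strata = d$replicate,
                               n_perm = 199, seed = 50000 + s)
    init <- axis_correlations(sim$matrix, lda$scores)
    cl <- upgma_band_clusters(sim$matrix)
    fin <- partial_axis_correlations(sim$matrix, cl, lda$scores, init)
    ev <- classify_band_evolution(fin, band_origins(p),
                                  discrimination_p = pt$p_value)
    any_flag[s] <- any(ev$selected)
  }
  # binomial 3-sigma envelope around the nominal 0.05
  expect_lte(mean(any_flag), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})
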