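#' Deterministic expected allele frequencies under neutrality and panmixia
#'
#' Iterates the infinite-population haplodiploid recursion for a bi-allelic
#' locus: females receive one maternal and one paternal allele
#' (`q_f' = (q_f + q_m) / 2`) while males are produced from unfertilized eggs
#' and carry only a maternal allele (`q_m' = q_f`). The weighted frequency
#' `(2 q_f + q_m) / 3` (two allele copies per female, one per male) is
#' conserved exactly. The default initial state is the F1 of the ISm female x
#' ISy male cross: all F1 females heterozygous (`q_f = 0.5` for allele y),
#' all F1 males carrying the maternal ISm allele (`q_m = 0`).
#'
#' @param n_generations number of generations to report (F1 = generation 1).
#' @param initial named vector `c(q_f = , q_m = )`, allele-y frequencies in
#'   the F1 females and males.
#' @return A data.frame with columns `generation`, `q_f`, `q_m`, `weighted`.
#' @examples
#' expected_frequency_trajectory(10)
#' @export
expected_frequency_trajectory <- function(n_generations = 10,
                                          initial = c(q_f = 0.5, q_m = 0)) {
  q_f <- initial[["q_f"]]; q_m <- initial[["q_m"]]
  if (q_f < 0 || q_f > 1 || q_m < 0 || q_m > 1)
    stop("initial frequencies must lie in [0, 1]")
  out <- data.frame(generation = seq_len(n_generations), q_f = NA_real_,
                    q_m = NA_real_)
  for (g in seq_len(n_generations)) {
    out$q_f[g] <- q_f
    out$q_m[g] <- q_m
    new_f <- (q_f + q_m) / 2
    q_m <- q_f
    q_f <- new_f
  }
  out$weighted <- (2 * out$q_f + out$q_m) / 3
  out
}

#' Expected carrier frequency for a dominant marker
#'
#' Infinite-population expected frequency of females carrying at least one
#' copy of the dominant allele m among daughters of generation `t`: a
#' daughter misses m only when both her maternal and paternal alleles are y,
#' so the carrier frequency is `1 - q_f(t-1) * q_m(t-1)`. At the F1 all
#' females are heterozygous carriers by construction.
#'
#' @param traj trajectory from [expected_frequency_trajectory()] (allele-y
#'   frequencies).
#' @return A data.frame with `generation` and `carrier_freq`.
#' @export
expected_dominant_phenotype <- function(traj) {
  n <- nrow(traj)
  carrier <- c(1, 1 - traj$q_f[-n] * traj$q_m[-n])
  data.frame(generation = traj$generation, carrier_freq = carrier)
}

# Vectorized forward simulation of many independent haplodiploid populations.
# Allele coding: 1 = allele y (ISy), 0 = allele m (ISm). Females carry two
# alleles (A1, A2), males one (M). Each generation: every breeding female is
# assigned one mate uniformly with replacement among the males; daughters and
# sons draw a uniform random mother; viability selection by rejection
# sampling. Assay samples are additional independent daughters of the same
# parents (venom-assayed females are never used as breeders).
sim_wf_batch <- function(cfg, n_pop, n_generations = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_f <- cfg$n_females; n_m <- cfg$n_males
  wf <- cfg$fitness_female / max(cfg$fitness_female)
  wm <- cfg$fitness_male / max(cfg$fitness_male)
  sel_f <- any(wf < 1); sel_m <- any(wm < 1)
  polyandry <- identical(cfg$mating, "polyandry")

  a1 <- matrix(0L, n_f, n_pop)  # maternal allele (m from ISm grandmothers)
  a2 <- matrix(1L, n_f, n_pop)  # paternal allele (y from ISy grandfathers)
  mm <- matrix(0L, n_m, n_pop)  # F1 males carry the maternal (m) allele
  q_f <- matrix(NA_real_, n_generations, n_pop)
  q_m <- matrix(NA_real_, n_generations, n_pop)
  q_f[1, ] <- colMeans((a1 + a2) / 2)
  q_m[1, ] <- colMeans(mm)
  assay <- list()

  col_f <- rep(seq_len(n_pop), each = n_f)
  draw_daughters <- function(k, pat_by_mother) {
    cols <- rep(seq_len(n_pop), each = k)
    mat_a <- pat_a <- matrix(0L, k, n_pop)
    todo <- rep(TRUE, k * n_pop)
    iter <- 0L
    while (any(todo)) {
      iter <- iter + 1L
      if (iter > 10000L)
        stop("stuck population: no viable female offspring can be produced ",
             "under the configured fitness", call. = FALSE)
      nt <- sum(todo)
      mo <- sample.int(n_f, nt, replace = TRUE)
      idx <- mo + (cols[todo] - 1L) * n_f
      ma <- ifelse(stats::runif(nt) < 0.5, a1[idx], a2[idx])
      pa <- if (polyandry) {
        fa <- sample.int(n_m, nt, replace = TRUE)
        mm[fa + (cols[todo] - 1L) * n_m]
      } else pat_by_mother[idx]
      if (sel_f) {
        acc <- stats::runif(nt) < wf[ma + pa + 1L]
      } else acc <- rep(TRUE, nt)
      ti <- which(todo)[acc]
      mat_a[ti] <- ma[acc]
      pat_a[ti] <- pa[acc]
      todo[which(todo)[acc]] <- FALSE
    }
    list(a1 = mat_a, a2 = pat_a)
  }
  draw_sons <- function(k) {
    cols <- rep(seq_len(n_pop), each = k)
    al <- matrix(0L, k, n_pop)
    todo <- rep(TRUE, k * n_pop)
    iter <- 0L
    while (any(todo)) {
      iter <- iter + 1L
      if (iter > 10000L)
        stop("stuck population: no viable male offspring can be produced ",
             "under the configured fitness", call. = FALSE)
      nt <- sum(todo)
      mo <- sample.int(n_f, nt, replace = TRUE)
      idx <- mo + (cols[todo] - 1L) * n_f
      a <- ifelse(stats::runif(nt) < 0.5, a1[idx], a2[idx])
      if (sel_m) {
        acc <- stats::runif(nt) < wm[a + 1L]
      } else acc <- rep(TRUE, nt)
      al[which(todo)[acc]] <- a[acc]
      todo[which(todo)[acc]] <- FALSE
    }
    al
  }

  for (g in seq(2, n_generations)) {
    # one mate per breeding female, uniform with replacement
    mate <- matrix(sample.int(n_m, n_f * n_pop, replace = TRUE), n_f, n_pop)
    pat_by_mother <- matrix(mm[as.vector(mate) + (col_f - 1L) * n_m],
                            n_f, n_pop)
    daughters <- draw_daughters(n_f, pat_by_mother)
    sons <- draw_sons(n_m)
    if (g %in% cfg$generations_assayed) {
      smp <- draw_daughters(cfg$assay_sample_size, pat_by_mother)
      geno <- smp$a1 + smp$a2  # copies of allele y: 0 = mm, 1 = my, 2 = yy
      assay[[as.character(g)]] <- data.frame(
        pop = seq_len(n_pop), generation = g,
        n_mm = colSums(geno == 0L), n_my = colSums(geno == 1L),
        n_yy = colSums(geno == 2L))
    }
    a1 <- daughters$a1
    a2 <- daughters$a2
    mm <- sons
    q_f[g, ] <- colMeans((a1 + a2) / 2)
    q_m[g, ] <- colMeans(mm)
  }
  assay_counts <- if (length(assay) > 0) {
    do.call(rbind, assay)
  } else {
    data.frame(pop = integer(0), generation = integer(0), n_mm = integer(0),
               n_my = integer(0), n_yy = integer(0))
  }
  rownames(assay_counts) <- NULL
  list(q_f = q_f, q_m = q_m, assay_counts = assay_counts)
}

#' Forward-simulate one haplodiploid replicate population
#'
#' Single-population wrapper around the batch Wright-Fisher engine: starting
#' from the F1 cross state, each generation assigns every breeding female a
#' mate drawn uniformly with replacement among the males, draws the next
#' generation's females and males from uniform random mothers with Mendelian
#' allele transmission, applies viability selection by rejection sampling,
#' and draws an independent assay sample of daughters at assayed generations.
#'
#' @param cfg a [marker_config()].
#' @param n_generations number of generations (F1 = 1).
#' @param seed optional integer seed.
#' @return A list with `trajectory` (per-generation `q_f`, `q_m`, `weighted`
#'   allele-y frequencies among breeders) and `assay` (genotype counts of the
#'   assay samples).
#' @export
simulate_wf_replicate <- function(cfg, n_generations = 10, seed = NULL) {
  sim <- sim_wf_batch(cfg, n_pop = 1, n_generations = n_generations,
                      seed = seed)
  traj <- data.frame(generation = seq_len(n_generations),
                     q_f = sim$q_f[, 1], q_m = sim$q_m[, 1])
  traj$weighted <- (2 * traj$q_f + traj$q_m) / 3
  list(trajectory = traj, assay = sim$assay_counts)
}

# Simulate n_exp independent experiments under cfg in one batch (a single
# RNG stream) and return their drift_test p-values against a shared null.
# Used by the size/power studies, where thousands of experiments are needed.
drift_test_batch <- function(cfg, null, n_exp, n_generations = 10,
                             seed = NULL) {
  batch <- sim_wf_batch(cfg, n_pop = n_exp * cfg$n_replicates,
                        n_generations = n_generations, seed = seed)
  counts <- batch$assay_counts
  n <- counts$n_mm + counts$n_my + counts$n_yy
  freq <- if (cfg$kind == "codominant") {
    (2 * counts$n_yy + counts$n_my) / (2 * n)
  } else {
    (counts$n_mm + counts$n_my) / n
  }
  dev <- freq - null$expected[as.character(counts$generation)]
  if (null$type == "abs_dev") dev <- abs(dev)
  sim_id <- (counts$pop - 1L) %/% cfg$n_replicates + 1L
  stats <- as.numeric(tapply(dev, sim_id, mean))
  k <- vapply(stats, function(s) {
    if (s < 0) sum(null$stats <= s) else sum(null$stats >= s)
  }, numeric(1))
  pmin(1, 2 * (k + 1) / (null$n_sim + 1))
}

# per-cell observed frequency of a marker dataset
observed_frequencies <- function(observed) {
  kind <- attr(observed, "kind")
  if (is.null(kind))
    kind <- if ("n_carrier" %in% names(observed)) "dominant" else "codominant"
  if (kind == "codominant") {
    n <- observed$n_mm + observed$n_my + observed$n_yy
    freq <- (2 * observed$n_yy + observed$n_my) / (2 * n)
  } else {
    freq <- observed$n_carrier / observed$n
  }
  data.frame(replicate = observed$replicate, generation = observed$generation,
             freq = freq, kind = kind)
}

#' Summary statistic of departure from the neutral expectation
#'
#' The default statistic is the signed mean, over all replicate x assayed
#' generation cells, of the difference between the observed marker frequency
#' (allele-y frequency `(2 n_yy + n_my) / (2n)` for codominant markers,
#' carrier frequency `n_carrier / n` for dominant ones) and its expected
#' value under neutral drift. The sign carries the direction of the
#' deviation; an absolute-deviation variant is provided. Expectations can be
#' restricted to a single generation via `generation`.
#'
#' @param observed a `marker_dataset` data.frame.
#' @param expected named numeric vector of expected frequencies, names =
#'   assayed generations.
#' @param type `"mean_dev"` (signed, default) or `"abs_dev"`.
#' @param generation optional single generation to restrict the statistic to.
#' @return A single number.
#' @export
summary_statistic <- function(observed, expected,
                              type = c("mean_dev", "abs_dev"),
                              generation = NULL) {
  type <- match.arg(type)
  if (nrow(observed) == 0) stop("empty marker dataset")
  obs <- observed_frequencies(observed)
  if (!is.null(generation)) obs <- obs[obs$generation %in% generation, ]
  exp_g <- expected[as.character(obs$generation)]
  if (any(is.na(exp_g)))
    stop("`expected` must be named with every assayed generation")
  dev <- obs$freq - exp_g
  if (type == "abs_dev") dev <- abs(dev)
  mean(dev)
}

#' Null distribution of the drift summary statistic
#'
#' Simulates `n_sim` pseudo-experiments, each of `cfg$n_replicates` neutral
#' haplodiploid populations with the observation step included (an assay
#' sample of daughters is genotyped, so binomial observation noise is part of
#' the null). Expected per-generation frequencies are taken as the mean of
#' the simulated observed frequencies — under neutrality these track the
#' deterministic recursion but additionally carry the genotype-frequency
#' covariance that drift induces for dominant markers.
#'
#' @param cfg a [marker_config()] (its fitness values are ignored: the null
#'   is always neutral).
#' @param n_sim number of pseudo-experiments (the study used 20,000); fewer
#'   than 1,000 triggers a warning.
#' @param n_generations generations simulated.
#' @param seed optional integer seed.
#' @param type statistic variant, see [summary_statistic()].
#' @return A list of class `null_distribution`: `stats` (length `n_sim`),
#'   `expected` (named per-generation mean simulated frequency), `cfg`,
#'   `n_sim`, `seed`, `type`.
#' @export
build_null_distribution <- function(cfg, n_sim = 20000, n_generations = 10,
                                    seed = NULL, type = "mean_dev") {
  if (n_sim < 1000)
    warning("null distributions below 1,000 simulations give coarse p-values")
  neutral <- cfg
  neutral$fitness_female <- c(mm = 1, my = 1, yy = 1)
  neutral$fitness_male <- c(m = 1, y = 1)
  sim <- sim_wf_batch(neutral, n_pop = n_sim * cfg$n_replicates,
                      n_generations = n_generations, seed = seed)
  counts <- sim$assay_counts
  n <- counts$n_mm + counts$n_my + counts$n_yy
  freq <- if (cfg$kind == "codominant") {
    (2 * counts$n_yy + counts$n_my) / (2 * n)
  } else {
    (counts$n_mm + counts$n_my) / n
  }
  expected <- tapply(freq, counts$generation, mean)
  dev <- if (type == "abs_dev") {
    abs(freq - expected[as.character(counts$generation)])
  } else {
    freq - expected[as.character(counts$generation)]
  }
  sim_id <- (counts$pop - 1L) %/% cfg$n_replicates + 1L
  stats <- as.numeric(tapply(dev, sim_id, mean))
  structure(list(stats = stats,
                 expected = stats::setNames(as.numeric(expected),
                                            names(expected)),
                 cfg = cfg, n_sim = n_sim, seed = seed, type = type),
            class = "null_distribution")
}

#' Simulation-based drift test for a venom marker
#'
#' Tests whether observed marker frequencies in the replicated populations
#' depart from neutral haplodiploid drift. The summary statistic of the
#' observed dataset is compared with its simulated null distribution; the
#' tail is chosen by the sign of the observed statistic (a unilateral test)
#' and the p-value doubles the add-one tail proportion:
#' `p = min(1, 2 (k + 1) / (n_sim + 1))` with `k` the number of null
#' statistics at least as extreme.
#'
#' @param observed a `marker_dataset` data.frame (see
#'   [simulate_marker_dataset()] or [read_marker_dataset()]).
#' @param cfg the [marker_config()] matching the observed design.
#' @param null optional precomputed [build_null_distribution()]; built on the
#'   fly otherwise.
#' @param n_sim,n_generations,seed forwarded to [build_null_distribution()]
#'   when `null` is not supplied.
#' @param type statistic variant, see [summary_statistic()].
#' @return A list of class `drift_test`: `statistic`, `tail`, `p_value`,
#'   `n_sim`, `expected` (simulated-mean expectations used in the statistic),
#'   `expected_deterministic` (infinite-population recursion values, reported
#'   for reference), `observed_freq` (per-cell observed frequencies) and
#'   `seed`.
#' @export
drift_test <- function(observed, cfg, null = NULL, n_sim = 20000,
                       n_generations = 10, seed = NULL, type = "mean_dev") {
  gens <- sort(unique(observed$generation))
  if (!all(gens %in% cfg$generations_assayed))
    stop("observed generations do not match `cfg$generations_assayed`")
  reps <- unique(observed$replicate)
  if (length(reps) != cfg$n_replicates)
    stop("observed dataset has ", length(reps), " replicates but cfg expects ",
         cfg$n_replicates)
  if (is.null(null)) {
    null <- build_null_distribution(cfg, n_sim = n_sim,
                                    n_generations = n_generations,
                                    seed = seed, type = type)
  }
  stat <- summary_statistic(observed, null$expected, type = null$type)
  tail <- if (stat < 0) "lower" else "upper"
  k <- if (tail == "lower") sum(null$stats <= stat) else sum(null$stats >= stat)
  p <- min(1, 2 * (k + 1) / (null$n_sim + 1))

  traj <- expected_frequency_trajectory(n_generations)
  det <- if (cfg$kind == "codominant") {
    stats::setNames(traj$q_f, traj$generation)[as.character(gens)]
  } else {
    ph <- expected_dominant_phenotype(traj)
    stats::setNames(ph$carrier_freq, ph$generation)[as.character(gens)]
  }
  structure(list(statistic = stat, tail = tail, p_value = p,
                 n_sim = null$n_sim, expected = null$expected,
                 expected_deterministic = det,
                 observed_freq = observed_frequencies(observed),
                 kind = cfg$kind, seed = null$seed),
            class = "drift_test")
}

#' @export
print.drift_test <- function(x, ...) {
  cat(sprintf("drift_test (%s marker): statistic = %.4f (%s tail)\n",
              x$kind, x$statistic, x$tail))
  cat(sprintf("  p = %.4g (doubled unilateral, %d neutral simulations)\n",
              x$p_value, x$n_sim))
  invisible(x)
}

#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda` for `lambda != 0`, natural log at `lambda = 0`.
#'
#' @param x positive values.
#' @param lambda power parameter.
#' @return Transformed values.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0)) stop("Box-Cox transform requires strictly positive values")
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

# inverse Box-Cox; exponential branch at lambda = 0
inv_boxcox <- function(z, lambda) {
  if (lambda == 0) return(exp(z))
  base <- lambda * z + 1
  if (any(base <= 0))
    stop("inverse Box-Cox undefined: lambda * z + 1 must be positive")
  base^(1 / lambda)
}

#' Corrected Western-blot quantity
#'
#' Normalizes a Western-blot signal by a proxy of the amount of venom loaded:
#' the median of the raw (unnormalized) reference-band intensities of the
#' same individual's silver-stained lane.
#'
#' @param western_intensity Western-blot signal intensity.
#' @param reference_intensities raw reference-band intensities of the
#'   corresponding lane.
#' @return `western_intensity / median(reference_intensities)`.
#' @export
corrected_lbgap2 <- function(western_intensity, reference_intensities) {
  if (length(reference_intensities) < 1 || all(reference_intensities <= 0))
    stop("at least one positive reference intensity is required")
  med <- stats::median(reference_intensities)
  if (med == 0) stop("median reference intensity is zero; ratio undefined")
  western_intensity / med
}

#' Mixed-model analysis of a continuous venom marker
#'
#' Fits a linear mixed model to the Box-Cox-transformed corrected intensity
#' with the six host x generation cell means as fixed effects and random
#' intercepts for the experimental populations nested within replicates
#' (REML, \pkg{nlme}), then performs simultaneous Tukey all-pairs comparisons
#' of the six cells with single-step adjustment (\pkg{multcomp}) and a
#' compact letter display.
#'
#' @param data data.frame with columns `host`, `generation`, `replicate`,
#'   `population` and `value` (positive corrected intensities), e.g. from
#'   [simulate_lbgap2_dataset()].
#' @param lambda Box-Cox parameter (the study value 0.23 by default);
#'   `NULL` estimates it by profile likelihood (\pkg{MASS}).
#' @return A list of class `lbgap2_fit`: `model` (the `lme` fit), `tukey`
#'   (the `summary.glht`), `letters` (compact letter display), `cell_means`
#'   (transformed scale), `lambda`.
#' @export
lbgap2_mixed_model <- function(data, lambda = 0.23) {
  need <- c("host", "generation", "replicate", "population", "value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("data is missing column(s): ", paste(miss, collapse = ", "))
  if (any(data$value <= 0)) stop("responses must be positive")
  if (is.null(lambda)) {
    if (!requireNamespace("MASS", quietly = TRUE))
      stop("lambda estimation requires the MASS package")
    prof <- MASS::boxcox(value ~ host * factor(generation), data = data,
                         plotit = FALSE, lambda = seq(-1, 2, 0.01))
    lambda <- prof$x[which.max(prof$y)]
  }
  df <- data.frame(tvalue = boxcox_transform(data$value, lambda),
                   cell = factor(paste0(data$host, "_F", data$generation)),
                   replicate = factor(data$replicate),
                   population = factor(data$population))
  # nlminb can stall when a variance component sits on the zero boundary;
  # retry once with optim before giving up
  fit <- tryCatch(
    nlme::lme(tvalue ~ cell, random = ~ 1 | replicate / population,
              data = df, method = "REML"),
    error = function(e) e)
  if (inherits(fit, "error")) {
    fit <- tryCatch(
      nlme::lme(tvalue ~ cell, random = ~ 1 | replicate / population,
                data = df, method = "REML",
                control = nlme::lmeControl(opt = "optim")),
      error = function(e) stop("mixed model failed to converge: ",
                               conditionMessage(e), call. = FALSE))
  }
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(cell = "Tukey"))
  # host contrasts are population-level comparisons: use the population
  # stratum df for the joint t approximation rather than the normal limit,
  # which understates the uncertainty of the variance components
  glt$df <- max(1L, length(unique(df$population)) -
                  length(unique(data$host)))
  quiet_mv <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("abseps|Completion", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  tk <- quiet_mv(summary(glt))
  letters <- quiet_mv(multcomp::cld(glt)$mcletters$Letters)
  cell_means <- tapply(df$tvalue, df$cell, mean)
  structure(list(model = fit, tukey = tk, letters = letters,
                 cell_means = cell_means, lambda = lambda),
            class = "lbgap2_fit")
}

#' @export
print.lbgap2_fit <- function(x, ...) {
  cat("lbgap2_fit: Box-Cox lambda =", x$lambda, "\n")
  cat("cell means (transformed scale):\n")
  print(round(x$cell_means, 3))
  cat("compact letter display:\n")
  print(x$letters)
  invisible(x)
}
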