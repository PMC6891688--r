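#' Deterministic parental venom reference profiles
#'
#' Builds a fixed set of reference bands with intensities for the two parental
#' isofemale lines (ISm and ISy). Band templates cycle through ISm-dominant,
#' ISy-dominant and shared bands so that any number of bands contains a mix of
#' origins; relative migration positions are spread over (0.05, 0.95) and
#' molecular weights decay log-linearly with position, as on a real gel.
#'
#' @param n_bands number of reference bands (>= 2); the study design uses 34.
#' @return A data.frame of class `parental_profiles` with columns `band`,
#'   `position`, `mw` (kDa), `intensity_ISm`, `intensity_ISy`.
#' @examples
#' default_parental_profiles(34)
#' @export
default_parental_profiles <- function(n_bands = 34) {
  if (!is.numeric(n_bands) || length(n_bands) != 1 || n_bands < 2)
    stop("`n_bands` must be a single integer >= 2")
  n_bands <- as.integer(n_bands)
  # templates: (ISm, ISy) intensity pairs; mixture of dominant and shared bands
  templates <- rbind(c(4, 1), c(0, 5), c(3, 3), c(1, 4), c(5, 0), c(2, 2))
  idx <- rep_len(seq_len(nrow(templates)), n_bands)
  position <- seq(0.05, 0.95, length.out = n_bands)
  mw <- exp(log(250) + (log(10) - log(250)) * (position - 0.05) / 0.9)
  out <- data.frame(band = seq_len(n_bands), position = position, mw = mw,
                    intensity_ISm = templates[idx, 1],
                    intensity_ISy = templates[idx, 2])
  class(out) <- c("parental_profiles", "data.frame")
  out
}

#' Ground-truth effect specification for band-intensity simulation
#'
#' Describes how each reference band behaves over the course of the
#' experimental evolution: its baseline mean in F2 hybrids, a linear intensity
#' trend per generation unit on each host (the "selection" signal), replicate
#' random-effect and residual standard deviations, and a block-correlation
#' structure grouping bands into clusters. Bands can also be declared
#' passengers of another band: their intensity is a linear readout of the
#' source band plus independent noise, with total correlation
#' `passenger_rho` — the signature of indirect selection through band overlap
#' or linkage disequilibrium.
#'
#' @param parents a [default_parental_profiles()] table.
#' @param baseline per-band F2 mean; defaults to the mid-parent value
#'   `(intensity_ISm + intensity_ISy) / 2`.
#' @param slope_S,slope_R intensity change per generation unit on the S / R
#'   host (generation enters as `generation - 2`; F2 is the first generation
#'   under selection). Scalar or per-band vector.
#' @param replicate_sd,residual_sd non-negative standard deviations of the
#'   population random effect and the residual noise.
#' @param cluster integer cluster assignment per band; bands sharing a cluster
#'   have residuals correlated at `rho`.
#' @param rho within-cluster residual correlation in \[0, 1).
#' @param passenger_of per-band index of a source band (`NA` = not a
#'   passenger). Passenger bands ignore their own slopes.
#' @param passenger_rho total intensity correlation between a passenger and
#'   its source band.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(parents, baseline = NULL, slope_S = 0, slope_R = 0,
                        replicate_sd = 0.3, residual_sd = 0.5, cluster = NULL,
                        rho = 0, passenger_of = NULL, passenger_rho = 0.8) {
  b <- nrow(parents)
  if (is.null(baseline))
    baseline <- (parents$intensity_ISm + parents$intensity_ISy) / 2
  if (is.null(cluster)) cluster <- seq_len(b)
  if (is.null(passenger_of)) passenger_of <- rep(NA_integer_, b)
  spec <- list(baseline = rep_len(baseline, b),
               slope_S = rep_len(slope_S, b),
               slope_R = rep_len(slope_R, b),
               replicate_sd = rep_len(replicate_sd, b),
               residual_sd = rep_len(residual_sd, b),
               cluster = rep_len(as.integer(cluster), b),
               rho = rho,
               passenger_of = rep_len(as.integer(passenger_of), b),
               passenger_rho = passenger_rho,
               n_bands = b)
  if (any(spec$replicate_sd < 0) || any(spec$residual_sd < 0))
    stop("standard deviations must be non-negative")
  if (rho < 0 || rho >= 1)
    stop("`rho` must lie in [0, 1)")
  if (passenger_rho < -1 || passenger_rho > 1)
    stop("`passenger_rho` must lie in [-1, 1]")
  pass <- which(!is.na(spec$passenger_of))
  if (length(pass) > 0) {
    src <- spec$passenger_of[pass]
    if (any(src < 1 | src > b)) stop("passenger source index out of range")
    if (any(src %in% pass)) stop("a passenger band cannot be a source band")
  }
  class(spec) <- "effect_spec"
  spec
}

#' Default selection scenario for the synthetic study
#'
#' A fixed, deterministic scenario used by the pipeline smoke runs: a handful
#' of mostly ISm-origin bands under positive selection on the susceptible host
#' and counter-selection on the resistant host, one ISy-origin band
#' counter-selected on S, modest replicate and residual noise, and two small
#' residual-correlation clusters. All other bands are neutral truth.
#'
#' @param parents a [default_parental_profiles()] table.
#' @return An `effect_spec`.
#' @export
default_effect_spec <- function(parents) {
  b <- nrow(parents)
  slope_S <- rep(0, b)
  slope_R <- rep(0, b)
  origin <- band_origins(parents)
  ism <- which(origin >= 0.5)
  isy <- which(origin < 0.5)
  up_s <- utils::head(ism, 3)
  slope_S[up_s] <- 0.15
  slope_R[up_s] <- -0.10
  down_s <- utils::head(isy, 2)
  slope_S[down_s] <- -0.10
  cluster <- seq_len(b)
  if (b >= 12) {
    cluster[c(4, 5, 6)] <- 4L
    cluster[c(10, 11, 12)] <- 10L
  }
  effect_spec(parents, slope_S = slope_S, slope_R = slope_R,
              cluster = cluster, rho = if (b >= 12) 0.5 else 0)
}

#' Effect scenario with directly selected and passenger bands
#'
#' The recovery-study scenario: `n_direct` bands carry clear generation
#' trends (a total intensity change of `effect` residual standard deviations
#' over the course of the experiment, F2 to F10) and `n_passenger` bands are
#' passengers of the first direct bands at total correlation `rho`. The
#' remaining bands are neutral. The total-change parameterization keeps the
#' pairwise correlation between direct bands sharing a host trend below the
#' clustering threshold, so each direct band is confounded only with its own
#' passengers; stronger per-generation trends make same-host direct bands
#' mutually collinear in the two-dimensional trend space, where no partial
#' correlation can separate them.
#'
#' @param parents a [default_parental_profiles()] table.
#' @param n_direct number of directly selected bands.
#' @param n_passenger number of passenger bands.
#' @param rho passenger-source total correlation.
#' @param effect total trend magnitude in residual-sd units over the 8
#'   generation units between F2 and F10.
#' @return An `effect_spec`.
#' @export
recovery_effect_spec <- function(parents, n_direct = 5, n_passenger = 3,
                                 rho = 0.8, effect = 1.5) {
  b <- nrow(parents)
  if (b < n_direct + n_passenger)
    stop("need at least ", n_direct + n_passenger, " bands")
  residual_sd <- 0.5
  slope_S <- rep(0, b)
  slope_R <- rep(0, b)
  n_s <- ceiling(n_direct / 2)
  slope_S[seq_len(n_s)] <- effect * residual_sd / 8
  slope_R[seq(n_s + 1, n_direct)] <- -effect * residual_sd / 8
  passenger_of <- rep(NA_integer_, b)
  passenger_of[n_direct + seq_len(n_passenger)] <-
    rep_len(seq_len(n_direct), n_passenger)
  effect_spec(parents, slope_S = slope_S, slope_R = slope_R,
              residual_sd = residual_sd, passenger_of = passenger_of,
              passenger_rho = rho)
}

#' Simulate a band-intensity matrix with known ground truth
#'
#' Draws individual band intensities under the generative model
#' `I(i, b) = max(0, baseline_b + u(population(i), b) +
#' slope_host(i),b * (generation(i) - 2) + eps(i, b))` with per-population
#' random effects `u` and residuals `eps` multivariate normal with block
#' correlation `rho` within clusters. Passenger bands are then overwritten by
#' a calibrated linear readout of their source band. Negative draws are
#' truncated at zero (silver-stain signal cannot be negative).
#'
#' @param design a [design_table()].
#' @param parents a [default_parental_profiles()] table.
#' @param effects an [effect_spec()] dimensioned to `parents`.
#' @param seed optional integer seed.
#' @return A list with elements `matrix` (a raw [band_matrix()]) and `truth`
#'   (data.frame per band: `selected_S`, `selected_R`, `direction_S`,
#'   `direction_R`, `passenger`, `source`).
#' @export
simulate_band_matrix <- function(design, parents, effects, seed = NULL) {
  if (nrow(design) == 0) stop("design is empty")
  if (effects$n_bands != nrow(parents))
    stop("effects are dimensioned for ", effects$n_bands, " bands but parents",
         " has ", nrow(parents))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  b <- effects$n_bands
  g <- design$generation - 2

  core <- which(is.na(effects$passenger_of))
  pass <- which(!is.na(effects$passenger_of))

  slope <- matrix(0, n, b)
  s_rows <- design$host == "S"
  slope[s_rows, ] <- rep(effects$slope_S, each = sum(s_rows))
  slope[!s_rows, ] <- rep(effects$slope_R, each = sum(!s_rows))
  mu <- matrix(effects$baseline, n, b, byrow = TRUE) + slope * g

  # population random effects, independent per band
  pops <- unique(design$population)
  u <- matrix(stats::rnorm(length(pops) * b), length(pops), b) *
    matrix(effects$replicate_sd, length(pops), b, byrow = TRUE)
  rownames(u) <- pops
  mu <- mu + u[design$population, , drop = FALSE]

  # residuals: block-correlated across core bands (correlation factorized
  # first so zero-variance bands stay valid degenerate cases)
  corr <- outer(effects$cluster, effects$cluster, "==") * effects$rho +
    diag(1 - effects$rho, b)
  corr_core <- corr[core, core, drop = FALSE]
  ch <- tryCatch(chol(corr_core),
                 error = function(e) stop("implied residual covariance is ",
                                          "not positive definite", call. = FALSE))
  eps <- matrix(0, n, b)
  eps[, core] <- (matrix(stats::rnorm(n * length(core)), n) %*% ch) *
    rep(effects$residual_sd[core], each = n)
  intensity <- mu + eps

  # passenger bands: calibrated readout of the source band plus noise
  for (p in pass) {
    src <- intensity[, effects$passenger_of[p]]
    src_sd <- stats::sd(src)
    z <- if (src_sd > 0) (src - mean(src)) / src_sd else rep(0, n)
    sd_p <- effects$residual_sd[p]
    intensity[, p] <- effects$baseline[p] +
      effects$passenger_rho * sd_p * z +
      sqrt(1 - effects$passenger_rho^2) * sd_p * stats::rnorm(n)
  }
  intensity <- pmax(intensity, 0)
  colnames(intensity) <- sprintf("band_%02d", seq_len(b))

  truth <- data.frame(band = seq_len(b),
                      selected_S = effects$slope_S != 0 &
                        is.na(effects$passenger_of),
                      selected_R = effects$slope_R != 0 &
                        is.na(effects$passenger_of),
                      direction_S = sign(effects$slope_S),
                      direction_R = sign(effects$slope_R),
                      passenger = !is.na(effects$passenger_of),
                      source = effects$passenger_of)
  list(matrix = band_matrix(intensity, design, normalized = FALSE),
       truth = truth)
}

#' Gel simulation parameters
#'
#' @param n_points sampling-grid size over relative distance \[0, 1\].
#' @param peak_sd Gaussian peak width (relative-distance units).
#' @param baseline_intercept,baseline_slope coefficients of the linear
#'   baseline drift `a + c * x`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param lanes_per_gel individual lanes per simulated gel; one ISm and one
#'   ISy control lane are emitted per gel.
#' @return A list of class `gel_params`.
#' @export
gel_params <- function(n_points = 2000, peak_sd = 0.006,
                       baseline_intercept = 0.2, baseline_slope = 0.3,
                       noise_sd = 0.05, lanes_per_gel = 12) {
  stopifnot(n_points >= 10, peak_sd > 0, noise_sd >= 0, lanes_per_gel >= 1)
  structure(list(n_points = as.integer(n_points), peak_sd = peak_sd,
                 baseline_intercept = baseline_intercept,
                 baseline_slope = baseline_slope, noise_sd = noise_sd,
                 lanes_per_gel = as.integer(lanes_per_gel)),
            class = "gel_params")
}

#' Simulate lane densitometry traces from a band matrix
#'
#' Each individual's lane is a sum of Gaussian peaks (one per reference band,
#' height taken from the band matrix) on a linear baseline with additive
#' noise. Lanes are grouped into gels of `lanes_per_gel` individuals; each gel
#' additionally carries one ISm and one ISy control lane built from the
#' parental reference intensities.
#'
#' @param bm a [band_matrix()] of true heights.
#' @param parents a [default_parental_profiles()] table (peak positions and
#'   control-lane heights).
#' @param gel a [gel_params()] list.
#' @param seed optional integer seed.
#' @return A list of [lane_profile()] objects (individual lanes in design
#'   order, control lanes appended).
#' @export
simulate_lane_profiles <- function(bm, parents, gel = gel_params(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- seq(0, 1, length.out = gel$n_points)
  dx <- x[2] - x[1]
  if (any(diff(sort(parents$position)) < dx))
    warning("some band positions are closer than the grid resolution")
  basis <- exp(-outer(parents$position, x, "-")^2 / (2 * gel$peak_sd^2))
  baseline <- gel$baseline_intercept + gel$baseline_slope * x

  make_lane <- function(heights, id, role) {
    y <- as.numeric(heights %*% basis) + baseline
    if (gel$noise_sd > 0) y <- y + stats::rnorm(length(x), 0, gel$noise_sd)
    # densitometry signal cannot be negative: truncated noise
    lane_profile(id, x, pmax(y, 0), role = role)
  }

  n <- nrow(bm$intensity)
  lanes <- vector("list", n)
  for (i in seq_len(n))
    lanes[[i]] <- make_lane(bm$intensity[i, ], bm$design$individual_id[i],
                            "individual")
  n_gels <- ceiling(n / gel$lanes_per_gel)
  controls <- vector("list", 2 * n_gels)
  for (gid in seq_len(n_gels)) {
    controls[[2 * gid - 1]] <- make_lane(parents$intensity_ISm,
                                         sprintf("gel%02d_ISm", gid),
                                         "ISm_control")
    controls[[2 * gid]] <- make_lane(parents$intensity_ISy,
                                     sprintf("gel%02d_ISy", gid),
                                     "ISy_control")
  }
  c(lanes, controls)
}

#' Configuration of a venom marker locus and its populations
#'
#' Describes a bi-allelic venom marker (alleles `m` from ISm and `y` from
#' ISy) segregating in the replicated haplodiploid populations: population
#' sizes, assayed generations, sample sizes and relative viabilities.
#' The default is neutral (all fitness 1).
#'
#' @param kind `"codominant"` (genotypes observable, as for the serpin marker)
#'   or `"dominant"` (only carriers of `m` distinguishable, as for the RhoGAP
#'   marker).
#' @param n_females,n_males breeding females / males per population and
#'   generation.
#' @param n_replicates number of replicate populations per experiment.
#' @param generations_assayed generations at which females are genotyped.
#' @param assay_sample_size number of females genotyped per assay.
#' @param fitness_female named relative viabilities for female genotypes
#'   `mm`, `my`, `yy`.
#' @param fitness_male named relative viabilities for male hemizygotes
#'   `m`, `y`.
#' @param mating `"monandry"` (each breeding female keeps a single mate drawn
#'   uniformly with replacement among the males) or `"polyandry"` (every
#'   offspring draws its father independently).
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(kind = c("codominant", "dominant"), n_females = 10,
                          n_males = 5, n_replicates = 8,
                          generations_assayed = c(6, 10),
                          assay_sample_size = 10,
                          fitness_female = c(mm = 1, my = 1, yy = 1),
                          fitness_male = c(m = 1, y = 1),
                          mating = c("monandry", "polyandry")) {
  kind <- match.arg(kind)
  mating <- match.arg(mating)
  stopifnot(n_females >= 1, n_males >= 1, n_replicates >= 1,
            assay_sample_size >= 1)
  fitness_female <- fitness_female[c("mm", "my", "yy")]
  fitness_male <- fitness_male[c("m", "y")]
  if (any(is.na(fitness_female)) || any(is.na(fitness_male)))
    stop("fitness vectors must be named (mm, my, yy) and (m, y)")
  if (any(c(fitness_female, fitness_male) < 0) ||
      all(fitness_female == 0) || all(fitness_male == 0))
    stop("fitness values must be >= 0 and not all zero")
  structure(list(kind = kind, n_females = as.integer(n_females),
                 n_males = as.integer(n_males),
                 n_replicates = as.integer(n_replicates),
                 generations_assayed = sort(as.integer(generations_assayed)),
                 assay_sample_size = as.integer(assay_sample_size),
                 fitness_female = fitness_female,
                 fitness_male = fitness_male, mating = mating),
            class = "marker_config")
}

#' Simulate a marker dataset for one replicated experiment
#'
#' Runs the haplodiploid Wright-Fisher update (see [simulate_wf_replicate()])
#' for each replicate population from the F1 state of the ISm female x ISy
#' male cross (all F1 females heterozygous m/y, all F1 males hemizygous m) and
#' draws an independent assay sample of daughters at each assayed generation.
#'
#' @param cfg a [marker_config()].
#' @param n_generations number of generations to simulate (F1 = 1).
#' @param seed optional integer seed.
#' @return A list with `dataset` (a `marker_dataset` data.frame: per replicate
#'   and assayed generation, genotype counts `n_mm`, `n_my`, `n_yy` for
#'   codominant markers or `n_carrier`, `n` for dominant markers) and
#'   `frequencies` (true per-replicate, per-generation allele-y frequencies
#'   `q_f`, `q_m` among breeders).
#' @export
simulate_marker_dataset <- function(cfg, n_generations = 10, seed = NULL) {
  sim <- sim_wf_batch(cfg, n_pop = cfg$n_replicates,
                      n_generations = n_generations, seed = seed)
  counts <- sim$assay_counts         # rows: pop x assayed gen
  dataset <- data.frame(replicate = counts$pop, generation = counts$generation)
  if (cfg$kind == "codominant") {
    dataset$n_mm <- counts$n_mm
    dataset$n_my <- counts$n_my
    dataset$n_yy <- counts$n_yy
  } else {
    dataset$n_carrier <- counts$n_mm + counts$n_my  # carries >= 1 m allele
    dataset$n <- counts$n_mm + counts$n_my + counts$n_yy
  }
  attr(dataset, "kind") <- cfg$kind
  class(dataset) <- c("marker_dataset", "data.frame")
  freqs <- data.frame(replicate = rep(seq_len(cfg$n_replicates),
                                      each = n_generations),
                      generation = rep(seq_len(n_generations),
                                       cfg$n_replicates),
                      q_f = as.vector(sim$q_f), q_m = as.vector(sim$q_m))
  list(dataset = dataset, frequencies = freqs)
}

#' Simulate a continuous-marker (Western blot) dataset
#'
#' Generates corrected Western-blot intensities for a continuous venom marker
#' under the mixed-model structure used downstream: fixed host and generation
#' effects (parameterized as a per-host linear trend in `generation - 2`), a
#' population random intercept and residual noise on the Box-Cox scale,
#' back-transformed to the intensity scale.
#'
#' @param design a [design_table()].
#' @param effects list with elements `mu` (grand mean on the transformed
#'   scale), `host_R` (additive effect of the R host), `slope_S`, `slope_R`
#'   (trend per generation unit on each host).
#' @param sd_population,sd_residual non-negative variance components (as
#'   standard deviations, transformed scale).
#' @param lambda Box-Cox parameter used for the inverse transform.
#' @param seed optional integer seed.
#' @return A data.frame with design columns plus `value` (positive corrected
#'   intensity); the transformed-scale linear predictor is kept in attribute
#'   `truth`.
#' @export
simulate_lbgap2_dataset <- function(design,
                                    effects = list(mu = 2, host_R = 0,
                                                   slope_S = 0, slope_R = 0),
                                    sd_population = 0.2, sd_residual = 0.3,
                                    lambda = 0.23, seed = NULL) {
  stopifnot(sd_population >= 0, sd_residual >= 0)
  if (!is.null(seed)) set.seed(seed)
  g <- design$generation - 2
  eta <- effects$mu + effects$host_R * (design$host == "R") +
    ifelse(design$host == "S", effects$slope_S, effects$slope_R) * g
  pops <- unique(design$population)
  u <- stats::rnorm(length(pops), 0, sd_population)
  names(u) <- pops
  z <- eta + u[design$population] + stats::rnorm(nrow(design), 0, sd_residual)
  out <- as.data.frame(design)
  out$value <- inv_boxcox(z, lambda)
  attr(out, "truth") <- eta
  out
}
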