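# full-precision numeric formatting so that write -> read is bit-identical
fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a band matrix as TSV
#'
#' Tab-separated dialect: columns `individual_id`, `replicate`, `host`,
#' `generation`, then one `band_XX` column per reference band; UTF-8, header
#' row, `.` decimal. Intensities are written with full precision so the
#' round trip is bit-identical.
#'
#' @param x a [band_matrix()].
#' @param path file path.
#' @return `write_band_matrix` returns `path` invisibly; `read_band_matrix`
#'   returns a [band_matrix()].
#' @export
write_band_matrix <- function(x, path) {
  df <- data.frame(individual_id = x$design$individual_id,
                   replicate = x$design$replicate,
                   host = x$design$host,
                   generation = x$design$generation)
  m <- x$intensity
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @param normalized flag recorded on the matrix read back.
#' @rdname write_band_matrix
#' @export
read_band_matrix <- function(path, normalized = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("individual_id", "replicate", "host", "generation")
  for (col in need) {
    if (!col %in% names(df))
      stop("malformed band matrix file: missing column `", col, "`")
  }
  band_cols <- grep("^band_", names(df), value = TRUE)
  if (length(band_cols) == 0)
    stop("malformed band matrix file: no band_XX columns")
  m <- as.matrix(df[band_cols])
  storage.mode(m) <- "double"
  bad <- which(m < 0 | !is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative or non-finite intensity at line ", bad[1, 1] + 1L,
         " (column `", band_cols[bad[1, 2]], "`)")
  design <- df[need]
  design$population <- sprintf("r%02d_%s", design$replicate, design$host)
  class(design) <- c("design_table", "data.frame")
  band_matrix(m, design, normalized = normalized)
}

#' Write / read lane profiles as CSV
#'
#' Comma-separated long format: `lane_id`, `relative_distance`, `intensity`,
#' plus a `role` column (a 3-column file is accepted on read; the role is
#' then inferred from `_ISm` / `_ISy` lane-id suffixes).
#'
#' @param lanes list of [lane_profile()]s.
#' @param path file path.
#' @return `write_lane_profiles` returns `path` invisibly;
#'   `read_lane_profiles` returns a list of [lane_profile()]s.
#' @export
write_lane_profiles <- function(lanes, path) {
  df <- do.call(rbind, lapply(lanes, function(l) {
    data.frame(lane_id = l$lane_id, relative_distance = fmt_num(l$distance),
               intensity = fmt_num(l$intensity), role = l$role)
  }))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lane_profiles
#' @export
read_lane_profiles <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("lane_id", "relative_distance", "intensity")
  for (col in need) {
    if (!col %in% names(df))
      stop("malformed lane profile file: missing column `", col, "`")
  }
  if (!"role" %in% names(df)) {
    df$role <- ifelse(grepl("_ISm$", df$lane_id), "ISm_control",
                      ifelse(grepl("_ISy$", df$lane_id), "ISy_control",
                             "individual"))
  }
  if (any(df$intensity < 0)) {
    stop("negative intensity at line ", which(df$intensity < 0)[1] + 1L)
  }
  lapply(split(df, factor(df$lane_id, levels = unique(df$lane_id))),
         function(d) lane_profile(d$lane_id[1], d$relative_distance,
                                  d$intensity, role = d$role[1]))
}

#' Write / read a marker dataset as TSV
#'
#' Codominant dialect: `replicate`, `generation`, `n_mm`, `n_my`, `n_yy`;
#' dominant dialect: `replicate`, `generation`, `n_carrier`, `n`.
#'
#' @param x a `marker_dataset` data.frame.
#' @param path file path.
#' @return `write_marker_dataset` returns `path` invisibly;
#'   `read_marker_dataset` returns a `marker_dataset`.
#' @export
write_marker_dataset <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_marker_dataset
#' @export
read_marker_dataset <- function(path) {
  df <- utils::read.delim(path, fileEncoding = "UTF-8")
  for (col in c("replicate", "generation")) {
    if (!col %in% names(df))
      stop("malformed marker dataset: missing column `", col, "`")
  }
  if (all(c("n_mm", "n_my", "n_yy") %in% names(df))) {
    kind <- "codominant"
    counts <- df[c("n_mm", "n_my", "n_yy")]
  } else if (all(c("n_carrier", "n") %in% names(df))) {
    kind <- "dominant"
    counts <- df[c("n_carrier", "n")]
    if (any(df$n_carrier > df$n))
      stop("carrier count exceeds sample size at line ",
           which(df$n_carrier > df$n)[1] + 1L)
  } else {
    stop("malformed marker dataset: need n_mm/n_my/n_yy or n_carrier/n")
  }
  if (any(counts < 0))
    stop("negative count at line ",
         which(apply(counts < 0, 1, any))[1] + 1L)
  attr(df, "kind") <- kind
  class(df) <- c("marker_dataset", "data.frame")
  df
}

#' Write a reference-band set as JSON
#'
#' @param refs a [build_reference_set()] table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(refs, path) {
  jsonlite::write_json(as.data.frame(refs), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the band dendrogram in Newick format
#'
#' @param clusters a [upgma_band_clusters()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_band_dendrogram <- function(clusters, path) {
  ape::write.tree(ape::as.phylo(clusters$tree), file = path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the synthetic-to-report pipeline in one
#' serializable list. Any two runs with the same configuration (including the
#' seed) produce byte-identical result tables.
#'
#' @param seed master seed; expanded into independent per-stage seeds so that
#'   stage subsets stay reproducible.
#' @param out_dir output directory for all stage files.
#' @param n_bands number of reference bands.
#' @param design a [design_table()].
#' @param effects an [effect_spec()]; defaults to [default_effect_spec()].
#' @param gel a [gel_params()] list.
#' @param n_perm permutations for the MANOVA and the LDA test.
#' @param n_sim neutral simulations per drift-test null distribution.
#' @param cluster_threshold correlation threshold for band clusters.
#' @param alpha significance level.
#' @param lambda Box-Cox parameter for the continuous marker.
#' @param markers named list of [marker_config()]s to simulate and test.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "extract", "mva", "bands", "drift_test", "lbgap2")`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            out_dir = file.path(tempdir(), "venomevol_run"),
                            n_bands = 34, design = design_table(),
                            effects = NULL, gel = gel_params(),
                            n_perm = 999, n_sim = 2000,
                            cluster_threshold = 0.4, alpha = 0.05,
                            lambda = 0.23,
                            markers = list(
                              lbspn = marker_config("codominant"),
                              lbgap = marker_config("dominant")),
                            stages = c("simulate", "extract", "mva", "bands",
                                       "drift_test", "lbgap2")) {
  parents <- default_parental_profiles(n_bands)
  if (is.null(effects)) effects <- default_effect_spec(parents)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_bands = as.integer(n_bands), design = design,
                 parents = parents, effects = effects, gel = gel,
                 n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
                 cluster_threshold = cluster_threshold, alpha = alpha,
                 lambda = lambda, markers = markers, stages = stages),
            class = "pipeline_config")
}

# deterministic per-stage substream of the master seed (kept below 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101, extract = 211, mva = 307, bands = 401,
               drift_test = 503, lbgap2 = 601)
  (as.integer(seed) * 7919L + offsets[[stage]] * 104729L) %% 2147483647L
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order. Every stage reads only the
#' serialized outputs of earlier stages from `config$out_dir` and writes its
#' own result files there, so any stage can be re-run in isolation from the
#' files alone. A failing stage is recorded in the report and all downstream
#' stages are skipped.
#'
#' @param config a [pipeline_config()].
#' @param stages stages to run (default: those in the config).
#' @return A list of class `run_report`: per-stage status and timing, result
#'   file paths, package version, configuration hash and collected warnings.
#' @export
run_pipeline <- function(config, stages = config$stages) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  report <- list(stages = data.frame(stage = character(0),
                                     status = character(0),
                                     seconds = numeric(0)),
                 files = list(),
                 version = as.character(utils::packageVersion("venomevol")),
                 config_hash = rlang::hash(config),
                 warnings = character(0))
  failed <- FALSE

  stage_fns <- list(
    simulate = function() {
      seed <- stage_seed(config$seed, "simulate")
      sim <- simulate_band_matrix(config$design, config$parents,
                                  config$effects, seed = seed)
      lanes <- simulate_lane_profiles(sim$matrix, config$parents, config$gel,
                                      seed = seed + 1L)
      files <- c(
        truth_matrix = write_band_matrix(sim$matrix, out("truth_matrix.tsv")),
        lanes = write_lane_profiles(lanes, out("lane_profiles.csv")))
      jsonlite::write_json(sim$truth, out("truth_report.json"), digits = NA,
                           pretty = TRUE)
      files["truth_report"] <- out("truth_report.json")
      for (nm in names(config$markers)) {
        md <- simulate_marker_dataset(config$markers[[nm]],
                                      seed = seed + 2L + match(nm, names(config$markers)))
        files[paste0("marker_", nm)] <-
          write_marker_dataset(md$dataset, out(paste0("marker_", nm, ".tsv")))
      }
      lb <- simulate_lbgap2_dataset(config$design, lambda = config$lambda,
                                    seed = seed + 99L)
      utils::write.table(data.frame(lb[c("individual_id", "replicate", "host",
                                         "generation", "population")],
                                    value = fmt_num(lb$value)),
                         out("lbgap2.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files["lbgap2"] <- out("lbgap2.tsv")
      files
    },
    extract = function() {
      lanes <- read_lane_profiles(out("lane_profiles.csv"))
      design <- read_band_matrix(out("truth_matrix.tsv"))$design
      ext <- extract_band_matrix(lanes, design)
      files <- c(
        raw = write_band_matrix(ext$raw, out("band_matrix_raw.tsv")),
        normalized = write_band_matrix(ext$normalized,
                                       out("band_matrix_normalized.tsv")),
        reference = write_reference_set(ext$reference,
                                        out("reference_bands.json")))
      utils::write.table(data.frame(band = ext$reference$band,
                                    ISm = fmt_num(ext$control_intensities$ISm),
                                    ISy = fmt_num(ext$control_intensities$ISy),
                                    origin = fmt_num(ext$origin)),
                         out("band_origins.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files["origins"] <- out("band_origins.tsv")
      files
    },
    mva = function() {
      seed <- stage_seed(config$seed, "mva")
      bm <- read_band_matrix(out("band_matrix_normalized.tsv"),
                             normalized = TRUE)
      tab <- permutational_manova(bm, n_perm = config$n_perm, seed = seed)
      utils::write.table(data.frame(term = rownames(tab), tab),
                         out("manova_table.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      centered <- replicate_center(bm)
      groups <- factor(paste0(bm$design$host, "_F", bm$design$generation))
      lda <- discriminant_analysis(centered, groups)
      lda <- orient_axes(lda, bm$design)
      pt <- lda_permutation_test(centered, groups,
                                 strata = bm$design$replicate,
                                 n_perm = config$n_perm, seed = seed + 1L)
      lda$p_value <- pt$p_value
      utils::write.table(data.frame(band = rownames(lda$loadings),
                                    apply(lda$loadings, 2, fmt_num)),
                         out("lda_loadings.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(data.frame(individual_id = bm$design$individual_id,
                                    apply(lda$scores, 2, fmt_num)),
                         out("lda_scores.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(list(eigenvalues = lda$eigenvalues,
                                statistic = pt$statistic,
                                p_value = pt$p_value,
                                flipped = lda$flipped),
                           out("lda_summary.json"), digits = NA, pretty = TRUE,
                           auto_unbox = TRUE)
      c(manova = out("manova_table.tsv"), loadings = out("lda_loadings.tsv"),
        scores = out("lda_scores.tsv"), lda_summary = out("lda_summary.json"))
    },
    bands = function() {
      bm <- read_band_matrix(out("band_matrix_normalized.tsv"),
                             normalized = TRUE)
      sc <- utils::read.delim(out("lda_scores.tsv"))
      scores <- as.matrix(sc[, -1])
      initial <- axis_correlations(bm, scores, alpha = config$alpha)
      clusters <- upgma_band_clusters(bm, threshold = config$cluster_threshold)
      final <- partial_axis_correlations(bm, clusters, scores, initial,
                                         alpha = config$alpha)
      origins <- utils::read.delim(out("band_origins.tsv"))
      lda_p <- jsonlite::read_json(out("lda_summary.json"))$p_value
      evol <- classify_band_evolution(final, origins$origin,
                                      discrimination_p = lda_p,
                                      alpha = config$alpha)
      trade <- axis_tradeoff(final)
      utils::write.table(initial, out("correlations_initial.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(final, out("correlations_final.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(evol, out("band_evolution.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_band_dendrogram(clusters, out("band_dendrogram.nwk"))
      jsonlite::write_json(list(rho = trade$rho, p_value = trade$p_value),
                           out("axis_tradeoff.json"), digits = NA,
                           auto_unbox = TRUE)
      c(initial = out("correlations_initial.tsv"),
        final = out("correlations_final.tsv"),
        evolution = out("band_evolution.tsv"),
        dendrogram = out("band_dendrogram.nwk"),
        tradeoff = out("axis_tradeoff.json"))
    },
    drift_test = function() {
      seed <- stage_seed(config$seed, "drift_test")
      files <- character(0)
      for (nm in names(config$markers)) {
        obs <- read_marker_dataset(out(paste0("marker_", nm, ".tsv")))
        res <- drift_test(obs, config$markers[[nm]], n_sim = config$n_sim,
                          seed = seed + match(nm, names(config$markers)))
        path <- out(paste0("drift_test_", nm, ".json"))
        jsonlite::write_json(list(marker = nm, kind = res$kind,
                                  statistic = res$statistic, tail = res$tail,
                                  p_value = res$p_value, n_sim = res$n_sim,
                                  expected = as.list(res$expected),
                                  expected_deterministic =
                                    as.list(res$expected_deterministic)),
                             path, digits = NA, auto_unbox = TRUE,
                             pretty = TRUE)
        files[paste0("drift_", nm)] <- path
      }
      files
    },
    lbgap2 = function() {
      lb <- utils::read.delim(out("lbgap2.tsv"))
      fit <- lbgap2_mixed_model(lb, lambda = config$lambda)
      tk <- fit$tukey
      utils::write.table(data.frame(contrast = rownames(tk$linfct),
                                    estimate = tk$test$coefficients,
                                    se = tk$test$sigma,
                                    z = tk$test$tstat,
                                    p_adj = tk$test$pvalues),
                         out("lbgap2_tukey.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      jsonlite::write_json(list(lambda = fit$lambda,
                                letters = as.list(fit$letters),
                                cell_means = as.list(fit$cell_means)),
                           out("lbgap2_summary.json"), digits = NA,
                           auto_unbox = TRUE, pretty = TRUE)
      c(lbgap2_tukey = out("lbgap2_tukey.tsv"),
        lbgap2_summary = out("lbgap2_summary.json"))
    })

  for (st in stages) {
    if (failed) {
      report$stages <- rbind(report$stages,
                             data.frame(stage = st, status = "skipped",
                                        seconds = NA_real_))
      next
    }
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(stage_fns[[st]](), error = function(e) e),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(st, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed <- TRUE
      report$stages <- rbind(report$stages,
                             data.frame(stage = st, status = paste0(
                               "failed: ", conditionMessage(res)),
                               seconds = secs))
    } else {
      report$files <- c(report$files, as.list(res))
      report$stages <- rbind(report$stages,
                             data.frame(stage = st, status = "ok",
                                        seconds = secs))
    }
  }
  if (length(report$files) > 0)
    stopifnot(all(file.exists(unlist(report$files))))
  jsonlite::write_json(list(stages = report$stages,
                            files = report$files,
                            version = report$version,
                            config_hash = report$config_hash,
                            warnings = report$warnings),
                       out("run_report.json"), digits = NA, pretty = TRUE,
                       auto_unbox = TRUE)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("venomevol run_report (version ", x$version, ")\n", sep = "")
  print(x$stages, row.names = FALSE)
  invisible(x)
}
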