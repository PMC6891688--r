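spearman_test <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Spearman correlations of band intensities with the discriminant axes
#'
#' For every band and each of the first two (oriented) discriminant axes,
#' computes the Spearman rank correlation (midranks for ties, t-approximation
#' p-value) between band intensity and axis scores, with Bonferroni control
#' over the whole family of tests (2 x number of bands by default).
#' Constant bands have undefined correlation and are flagged non-significant.
#'
#' @param x the (normalized) [band_matrix()] or plain matrix.
#' @param scores score matrix from an oriented [discriminant_analysis()];
#'   columns 1-2 are used.
#' @param family Bonferroni family size; default = number of tests performed.
#' @param alpha significance level applied to adjusted p-values.
#' @return A data.frame of class `band_correlations` with columns `band`,
#'   `axis`, `rho`, `p`, `p_adj`, `significant`, `stage` (`"initial"`),
#'   `cluster` (`NA` until clustering).
#' @export
axis_correlations <- function(x, scores, family = NULL, alpha = 0.05) {
  m <- bm_intensity(x)
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(m))
    stop("scores must be row-aligned with the band matrix")
  n_axes <- min(2, ncol(scores))
  b <- ncol(m)
  if (is.null(family)) family <- n_axes * b
  out <- expand.grid(band = seq_len(b), axis = seq_len(n_axes))
  res <- t(mapply(function(bb, ax) spearman_test(m[, bb], scores[, ax]),
                  out$band, out$axis))
  out$rho <- res[, "rho"]
  out$p <- res[, "p"]
  out$p_adj <- pmin(1, out$p * family)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$stage <- "initial"
  out$cluster <- NA_integer_
  attr(out, "family") <- family
  attr(out, "alpha") <- alpha
  class(out) <- c("band_correlations", "data.frame")
  out
}

#' UPGMA clustering of bands by absolute correlation
#'
#' Groups bands by average-linkage (UPGMA) hierarchical clustering on the
#' distance `1 - |Pearson correlation of intensities|`, then cuts the tree at
#' height `1 - threshold` so that clusters hold bands correlated (in absolute
#' value) at least at the threshold. Constant bands are assigned distance 1
#' to all others (with a warning) and end up as singletons.
#'
#' @param x the [band_matrix()] or plain matrix.
#' @param threshold correlation threshold defining clusters (default 0.4,
#'   a conservative choice).
#' @return A list of class `band_clusters`: `cluster` (named integer
#'   assignment), `tree` (the `hclust` object), `threshold`, `cut_height`.
#' @export
upgma_band_clusters <- function(x, threshold = 0.4) {
  m <- bm_intensity(x)
  if (ncol(m) < 2) stop("need at least 2 bands to cluster")
  cc <- suppressWarnings(stats::cor(m))
  if (any(is.na(cc))) {
    warning("constant band(s): correlation undefined, distance set to 1")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  d <- stats::as.dist(1 - abs(cc))
  tree <- stats::hclust(d, method = "average")
  cut_height <- 1 - threshold
  cluster <- stats::cutree(tree, h = cut_height)
  names(cluster) <- colnames(m)
  structure(list(cluster = cluster, tree = tree, threshold = threshold,
                 cut_height = cut_height),
            class = "band_clusters")
}

#' Partial correlations within band clusters
#'
#' Disentangles direct from indirect selection: within every cluster
#' containing at least two bands initially significant on the same axis, each
#' band is regressed (ordinary least squares) on all other bands of its
#' cluster and the residual is Spearman-correlated with each discriminant
#' axis. Bonferroni correction is applied over the partial tests actually
#' performed. Bands in unanalyzed clusters and singletons carry their
#' initial-stage result forward, so the returned table is the final,
#' per-band x axis correlation table.
#'
#' @param x the [band_matrix()] or plain matrix.
#' @param clusters a [upgma_band_clusters()] result.
#' @param scores the oriented axis scores (columns 1-2 used).
#' @param initial the initial-stage [axis_correlations()] table.
#' @param alpha significance level.
#' @return A `band_correlations` data.frame in which rows from analyzed
#'   clusters have `stage == "partial"` and the rest keep their initial
#'   values; the `cluster` column is filled for all bands.
#' @export
partial_axis_correlations <- function(x, clusters, scores, initial,
                                      alpha = 0.05) {
  m <- bm_intensity(x)
  scores <- as.matrix(scores)
  cl <- clusters$cluster
  b <- ncol(m)
  if (length(cl) != b) stop("cluster assignment does not match the matrix")
  n_axes <- min(2, ncol(scores))

  # gate: clusters with >= 2 bands initially significant on the same axis
  analyzed <- vapply(unique(cl), function(id) {
    members <- which(cl == id)
    if (length(members) < 2) return(FALSE)
    any(vapply(seq_len(n_axes), function(ax) {
      sum(initial$significant[initial$band %in% members &
                                initial$axis == ax]) >= 2
    }, logical(1)))
  }, logical(1))
  analyzed_ids <- unique(cl)[analyzed]
  analyzed_bands <- which(cl %in% analyzed_ids)

  out <- initial
  out$cluster <- cl[out$band]
  if (length(analyzed_bands) > 0) {
    if (length(analyzed_bands) > nrow(m) - 2)
      stop("cluster larger than n - 2 individuals; partial regression rank ",
           "deficient")
    family <- length(analyzed_bands) * n_axes
    for (bb in analyzed_bands) {
      others <- setdiff(which(cl == cl[bb]), bb)
      res <- stats::lm.fit(cbind(1, m[, others, drop = FALSE]),
                           m[, bb])$residuals
      # collinear bands leave a numerically zero residual: correlation
      # undefined, band cannot remain
      if (stats::sd(res) < 1e-10 * max(stats::sd(m[, bb]), 1)) res[] <- 0
      for (ax in seq_len(n_axes)) {
        row <- which(out$band == bb & out$axis == ax)
        st <- spearman_test(res, scores[, ax])
        out$rho[row] <- st["rho"]
        out$p[row] <- st["p"]
        out$p_adj[row] <- min(1, st["p"] * family)
        out$significant[row] <- !is.na(st["p"]) && st["p"] * family < alpha
        out$stage[row] <- "partial"
      }
    }
    attr(out, "partial_family") <- family
  }
  attr(out, "analyzed_clusters") <- analyzed_ids
  class(out) <- c("band_correlations", "data.frame")
  out
}

#' Classify the direction and origin of band evolution
#'
#' Summarizes the final correlation table into the per-band evolution table:
#' direction of intensity change on the S host (sign of the final axis-1
#' correlation if significant), on the R host (axis 2), the parental origin
#' index and side, and whether the band is selected (significant on at least
#' one axis).
#'
#' Band-axis correlations are only meaningful when the groups are actually
#' discriminated: the axes are linear combinations of the bands, so under a
#' global null every band correlates with the noise directions the analysis
#' happens to pick. Supplying the overall discrimination p-value (from
#' [lda_permutation_test()]) gates the classification: when it is not
#' significant at `alpha`, no band is called selected.
#'
#' @param final the final [partial_axis_correlations()] (or initial) table.
#' @param origin per-band origin indices in \[0, 1\] (see
#'   [band_origin_index()]), or a `parental_profiles` table.
#' @param discrimination_p optional p-value of the overall discrimination;
#'   `NA` skips the gate.
#' @param alpha significance level for the gate.
#' @return A data.frame of class `band_evolution`: `band`, `cluster`,
#'   `rho_S`, `p_adj_S`, `rho_R`, `p_adj_R`, `origin`, `origin_side`,
#'   `direction_S`, `direction_R`, `selected`.
#' @export
classify_band_evolution <- function(final, origin, discrimination_p = NA,
                                    alpha = 0.05) {
  if (inherits(origin, "parental_profiles")) origin <- band_origins(origin)
  gate_open <- is.na(discrimination_p) || discrimination_p < alpha
  bands <- sort(unique(final$band))
  if (length(origin) != length(bands))
    stop("`origin` must provide one value per band")
  pick <- function(col, ax) {
    final[[col]][match(paste(bands, ax), paste(final$band, final$axis))]
  }
  dir_of <- function(rho, sig) {
    ifelse(!sig | is.na(rho), "none", ifelse(rho > 0, "up", "down"))
  }
  sig_s <- pick("significant", 1) & gate_open
  sig_r <- pick("significant", 2) & gate_open
  out <- data.frame(band = bands,
                    cluster = final$cluster[match(bands, final$band)],
                    rho_S = pick("rho", 1), p_adj_S = pick("p_adj", 1),
                    rho_R = pick("rho", 2), p_adj_R = pick("p_adj", 2),
                    origin = origin,
                    origin_side = ifelse(origin >= 0.5, "ISm", "ISy"),
                    direction_S = dir_of(pick("rho", 1), sig_s),
                    direction_R = dir_of(pick("rho", 2), sig_r),
                    selected = sig_s | sig_r)
  class(out) <- c("band_evolution", "data.frame")
  out
}

#' Trade-off between the axis correlations of the bands
#'
#' Relates the bands' correlations to the two discriminant axes: the Spearman
#' correlation between the two columns of the final correlation table (a
#' negative value means bands gaining intensity on one host lose it on the
#' other) and the least-squares regression of the axis-1 correlations on the
#' axis-2 correlations.
#'
#' @param final a final `band_correlations` table.
#' @return A list with `rho`, `p_value` and the `lm` fit (`regression`).
#' @export
axis_tradeoff <- function(final) {
  bands <- sort(unique(final$band))
  r1 <- final$rho[match(paste(bands, 1), paste(final$band, final$axis))]
  r2 <- final$rho[match(paste(bands, 2), paste(final$band, final$axis))]
  keep <- !is.na(r1) & !is.na(r2)
  st <- spearman_test(r1[keep], r2[keep])
  list(rho = unname(st["rho"]), p_value = unname(st["p"]),
       regression = stats::lm(r1[keep] ~ r2[keep]))
}
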