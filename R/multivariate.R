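# build the model-matrix block for one term; components of "a:b" interactions
# are column-wise products of the component blocks
term_block <- function(term, design) {
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    blocks <- lapply(parts, term_block, design = design)
    out <- blocks[[1]]
    for (bl in blocks[-1]) {
      out <- do.call(cbind, lapply(seq_len(ncol(bl)), function(j) out * bl[, j]))
    }
    return(out)
  }
  v <- design[[term]]
  if (is.null(v)) stop("unknown model term '", term, "'")
  if (is.numeric(v)) {
    matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, term))
  } else {
    stats::model.matrix(~ 0 + f, data.frame(f = factor(v)))
  }
}

# random permutation of 1..n restricted to strata blocks
strata_permutation <- function(n, strata) {
  p <- seq_len(n)
  if (is.null(strata)) return(sample.int(n))
  for (idx in split(seq_len(n), strata)) {
    p[idx] <- idx[sample.int(length(idx))]
  }
  p
}

#' Distance-based permutational MANOVA with restricted permutations
#'
#' Partitions the total sum of squares of the pairwise Euclidean distance
#' matrix among the venom compositions into sequential (Type-I) contributions
#' of the model terms, in the order given. Internally the squared distance
#' matrix is Gower-centered into the inner-product matrix
#' `G = -1/2 J D^2 J` and the sum of squares of term k is
#' `trace((H_k - H_(k-1)) G)` for the nested hat matrices of the cumulative
#' model. Pseudo-F statistics are tested by permuting individuals, restricted
#' to the given strata (by default the replicates, so individuals exchange
#' freely across hosts and generations within a replicate but never across
#' replicates). p-values use the add-one convention
#' `(1 + #\{F* >= F\}) / (n_perm + 1)`.
#'
#' @param x a [band_matrix()] (or plain matrix with a `design` supplied).
#' @param terms ordered character vector of terms; any design column name,
#'   `generation` entering as a continuous covariate (2, 6, 10), and `:`
#'   interactions, e.g. `c("generation", "host", "generation:host",
#'   "population")`.
#' @param design design table; defaults to `x$design`.
#' @param n_perm number of random permutations (>= 99 recommended).
#' @param strata labels restricting the permutations; defaults to the
#'   replicate. `NA` disables restriction.
#' @param seed optional integer seed for the permutations.
#' @param permutations optional integer matrix of explicit permutations (one
#'   row each, typically an exhaustive enumeration). When supplied, the
#'   p-value is the plain proportion of enumerated statistics at least as
#'   large as the observed one and `n_perm`/`strata`/`seed` are ignored.
#' @return A data.frame of class `manova_table` with rows for each term plus
#'   `Residuals` and `Total`, and columns `Df`, `SumsOfSqs`, `F`, `R2`,
#'   `p_value`.
#' @export
permutational_manova <- function(x, terms = c("generation", "host",
                                              "generation:host", "population"),
                                 design = NULL, n_perm = 999, strata = NULL,
                                 seed = NULL, permutations = NULL) {
  if (is.null(design)) {
    if (!inherits(x, "band_matrix")) stop("supply `design` for a plain matrix")
    design <- x$design
  }
  m <- bm_intensity(x)
  n <- nrow(m)
  if (is.null(strata) && !is.null(design$replicate)) strata <- design$replicate
  if (length(strata) == 1 && is.na(strata)) strata <- NULL

  d2 <- as.matrix(stats::dist(m))^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% d2 %*% j
  ss_total <- sum(diag(g))

  # nested hat matrices of the cumulative model, intercept first
  xmat <- matrix(1, n, 1)
  qr0 <- qr(xmat)
  hats <- list()
  dfs <- integer(length(terms))
  rank_prev <- qr0$rank
  h_prev <- tcrossprod(qr.Q(qr0)[, seq_len(qr0$rank), drop = FALSE])
  for (k in seq_along(terms)) {
    xmat <- cbind(xmat, term_block(terms[k], design))
    qrk <- qr(xmat)
    dfs[k] <- qrk$rank - rank_prev
    if (dfs[k] == 0)
      stop("term '", terms[k], "' is aliased with the preceding terms (",
           paste(terms[seq_len(k - 1)], collapse = ", "), ")")
    h_k <- tcrossprod(qr.Q(qrk)[, seq_len(qrk$rank), drop = FALSE])
    hats[[k]] <- h_k - h_prev
    h_prev <- h_k
    rank_prev <- qrk$rank
  }
  h_res <- diag(n) - h_prev
  df_res <- n - rank_prev

  stat_fun <- function(gm) {
    ss <- vapply(hats, function(h) sum(h * gm), numeric(1))
    ss_res <- sum(h_res * gm)
    (ss / dfs) / (ss_res / df_res)
  }
  f_obs <- stat_fun(g)
  ss_obs <- vapply(hats, function(h) sum(h * g), numeric(1))
  ss_res <- sum(h_res * g)

  if (!is.null(permutations)) {
    permutations <- as.matrix(permutations)
    f_perm <- t(apply(permutations, 1, function(p) stat_fun(g[p, p])))
    if (length(terms) == 1) f_perm <- t(f_perm)
    p_val <- colMeans(sweep(f_perm, 2, f_obs - 1e-12, ">="))
    n_used <- nrow(permutations)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- numeric(length(terms))
    for (b in seq_len(n_perm)) {
      p <- strata_permutation(n, strata)
      count <- count + (stat_fun(g[p, p]) >= f_obs - 1e-12)
    }
    p_val <- (1 + count) / (n_perm + 1)
    n_used <- n_perm
  }

  out <- data.frame(Df = c(dfs, df_res, n - 1),
                    SumsOfSqs = c(ss_obs, ss_res, ss_total),
                    F = c(f_obs, NA, NA),
                    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
                    p_value = c(p_val, NA, NA),
                    row.names = c(terms, "Residuals", "Total"))
  attr(out, "n_perm") <- n_used
  attr(out, "strata") <- if (is.null(strata)) "none" else "supplied"
  class(out) <- c("manova_table", "data.frame")
  out
}

#' Center a band matrix within labels
#'
#' Subtracts the per-label mean of every band, removing between-label
#' variation (used to remove the replicate effect before discriminant
#' analysis, which has no error stratum for it).
#'
#' @param x a [band_matrix()] or plain matrix.
#' @param labels centering labels, one per individual; defaults to the
#'   replicate.
#' @return Object of the same type, centered (band_matrix values are shifted
#'   intensities and may be negative, so a plain matrix is returned together
#'   with the design in attribute `design`).
#' @export
replicate_center <- function(x, labels = NULL) {
  m <- bm_intensity(x)
  if (is.null(labels)) {
    if (!inherits(x, "band_matrix")) stop("supply `labels` for a plain matrix")
    labels <- x$design$replicate
  }
  if (length(labels) != nrow(m)) stop("one label per individual is required")
  if (any(table(labels) == 1))
    warning("labels with a single individual are centered to exact zeros")
  labels <- as.character(labels)
  means <- rowsum(m, labels) / as.vector(table(labels)[sort(unique(labels))])
  out <- m - means[labels, , drop = FALSE]
  if (inherits(x, "band_matrix")) attr(out, "design") <- x$design
  out
}

#' Linear discriminant analysis of venom composition groups
#'
#' Solves the generalized eigenproblem of the between-group versus pooled
#' within-group sums-of-squares-and-cross-products matrices of the (centered)
#' band matrix, yielding `min(n_groups - 1, n_bands)` discriminant axes
#' ordered by decreasing eigenvalue. The within-group matrix is regularized
#' by a small ridge `eps * I` (default `1e-8 * trace / n_bands`) to guard
#' against numerically singular pooled covariance.
#'
#' @param x centered matrix from [replicate_center()] (or a band_matrix /
#'   matrix).
#' @param groups factor of group memberships (host x generation), each level
#'   with at least 2 individuals.
#' @param ridge ridge constant added to the within-group SSCP diagonal; `0`
#'   disables regularization (an error advises a ridge if the matrix is then
#'   singular), `NULL` uses the default.
#' @return A list of class `discriminant_result`: `loadings` (bands x axes),
#'   `scores` (individuals x axes, `scores = centered data %*% loadings`),
#'   `eigenvalues`, `centroids` (groups x axes), `groups`, `center` (column
#'   means removed before projection), `p_value` (filled by
#'   [lda_permutation_test()]), `flipped` (filled by [orient_axes()]).
#' @export
discriminant_analysis <- function(x, groups, ridge = NULL) {
  m <- bm_intensity(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 individuals")
  n <- nrow(m); b <- ncol(m)
  center <- colMeans(m)
  mc <- sweep(m, 2, center)
  gm <- rowsum(mc, groups) / as.vector(table(groups))
  w <- crossprod(mc - gm[groups, , drop = FALSE])      # within-group SSCP
  bet <- crossprod(gm * sqrt(as.vector(table(groups)))) # between-group SSCP
  eps <- if (is.null(ridge)) 1e-8 * sum(diag(w)) / b else ridge
  wr <- w + diag(eps, b)
  u <- tryCatch(chol(wr), error = function(e)
    stop("within-group covariance is singular; supply a positive `ridge`",
         call. = FALSE))
  uinv <- backsolve(u, diag(b))
  es <- eigen(crossprod(uinv, bet %*% uinv), symmetric = TRUE)
  n_axes <- min(nlevels(groups) - 1, b)
  loadings <- uinv %*% es$vectors[, seq_len(n_axes), drop = FALSE]
  colnames(loadings) <- paste0("axis_", seq_len(n_axes))
  rownames(loadings) <- colnames(m)
  scores <- mc %*% loadings
  centroids <- rowsum(scores, groups) / as.vector(table(groups))
  structure(list(loadings = loadings, scores = scores,
                 eigenvalues = es$values[seq_len(n_axes)],
                 centroids = centroids, groups = groups, center = center,
                 ridge = eps, p_value = NA_real_,
                 flipped = rep(FALSE, n_axes)),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf("discriminant_result: %d axes over %d bands, %d groups\n",
              ncol(x$loadings), nrow(x$loadings), nlevels(x$groups)))
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  if (!is.na(x$p_value)) cat("permutation p =", format(x$p_value), "\n")
  invisible(x)
}

#' Orient discriminant axes by the generation trends
#'
#' Eigenvector signs are arbitrary; this flips axes 1 and 2 so that axis-1
#' scores of S-host individuals increase with generation ("venom evolution on
#' the S host") and axis-2 scores of R-host individuals increase with
#' generation ("venom evolution on the R host"). Loadings, scores and
#' centroids are negated consistently; a zero regression slope leaves the
#' axis unchanged and is flagged.
#'
#' @param result a [discriminant_analysis()] result.
#' @param design the [design_table()] aligned with the scores.
#' @return The oriented `discriminant_result`, with `flipped` recording which
#'   axes were negated and `degenerate` flagging zero-slope axes.
#' @export
orient_axes <- function(result, design) {
  if (ncol(result$scores) < 2) stop("axes 1 and 2 are required for orientation")
  degenerate <- logical(2)
  for (ax in 1:2) {
    host <- if (ax == 1) "S" else "R"
    rows <- design$host == host
    gg <- design$generation[rows]
    slope <- stats::cov(result$scores[rows, ax], gg) / stats::var(gg)
    if (slope == 0) {
      degenerate[ax] <- TRUE
    } else if (slope < 0) {
      result$loadings[, ax] <- -result$loadings[, ax]
      result$scores[, ax] <- -result$scores[, ax]
      result$centroids[, ax] <- -result$centroids[, ax]
      result$flipped[ax] <- !result$flipped[ax]
    }
  }
  result$degenerate <- degenerate
  result
}

#' Permutation test of the overall discrimination
#'
#' Tests the between-group / total inertia ratio of the centered band matrix
#' by permuting group labels, restricted to strata (the replicates). The
#' statistic lies in \[0, 1\]; the p-value uses the add-one convention.
#'
#' @param x centered matrix (see [replicate_center()]).
#' @param groups factor of group memberships.
#' @param strata permutation strata labels (`NULL` = free permutation).
#' @param n_perm number of permutations; fewer than 99 triggers a warning
#'   about coarse p resolution.
#' @param seed optional integer seed.
#' @return A list with `statistic`, `p_value`, `n_perm`.
#' @export
lda_permutation_test <- function(x, groups, strata = NULL, n_perm = 999,
                                 seed = NULL) {
  if (n_perm < 99) warning("fewer than 99 permutations gives coarse p-values")
  m <- bm_intensity(x)
  groups <- factor(groups)
  if (!is.null(seed)) set.seed(seed)
  mc <- sweep(m, 2, colMeans(m))
  total <- sum(mc^2)
  inertia <- function(grp) {
    gm <- rowsum(mc, grp)
    sum(gm^2 / as.vector(table(grp)))
  }
  obs <- inertia(groups) / total
  n <- nrow(m)
  count <- 0
  for (b in seq_len(n_perm)) {
    p <- strata_permutation(n, strata)
    count <- count + (inertia(groups[p]) / total >= obs - 1e-12)
  }
  list(statistic = obs, p_value = (1 + count) / (n_perm + 1), n_perm = n_perm)
}
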