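# running min/max over a centered window, edges treated as partial windows
run_extreme <- function(x, k, fun_pad, fun_p) {
  n <- length(x)
  pad_l <- (k - 1) %/% 2
  xp <- c(rep(fun_pad, pad_l), x, rep(fun_pad, k - 1 - pad_l))
  do.call(fun_p, as.data.frame(stats::embed(xp, k)))
}

#' Remove the baseline of a lane profile by morphological opening
#'
#' Estimates the slowly varying background of a densitometry trace as the
#' morphological opening (rolling minimum followed by rolling maximum, window
#' `window` in relative-distance units) and subtracts it. Peaks narrower than
#' the window are preserved; any smooth drift wider than the window is
#' removed. The transform (a "white top-hat") is idempotent and its output is
#' non-negative.
#'
#' @param profile a [lane_profile()].
#' @param window opening window width, relative-distance units, in (0, 1);
#'   must be at least one grid step.
#' @return The background-removed [lane_profile()].
#' @export
remove_background <- function(profile, window = 0.05) {
  if (!is.numeric(window) || window <= 0 || window >= 1)
    stop("`window` must lie in (0, 1)")
  dx <- min(diff(profile$distance))
  if (window < dx)
    stop("`window` (", window, ") is smaller than the grid spacing (",
         signif(dx, 3), ")")
  k <- max(2L, as.integer(round(window / dx)))
  eroded <- run_extreme(profile$intensity, k, Inf, pmin)
  opened <- run_extreme(eroded, k, -Inf, pmax)
  out <- profile
  out$intensity <- pmax(profile$intensity - opened, 0)
  out
}

#' Detect peaks in a background-removed lane profile
#'
#' Finds local maxima and keeps those whose topographic prominence (apex
#' height above the higher of the two bounding saddles) reaches
#' `min_prominence`. Peak height is the profile value at the apex.
#'
#' @param profile a background-removed [lane_profile()].
#' @param min_prominence minimum topographic prominence, intensity units.
#' @return A data.frame with columns `position`, `height`, `prominence`,
#'   sorted by position; zero rows if no peak qualifies.
#' @export
detect_peaks <- function(profile, min_prominence = 0.5) {
  y <- profile$intensity
  n <- length(y)
  if (n < 3)
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  left <- c(Inf, y[-n])
  right <- c(y[-1], Inf)
  apex <- which(y > left & y >= right)
  apex <- apex[apex > 1 & apex < n]
  if (length(apex) == 0)
    return(data.frame(position = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(apex, function(i) {
    h <- y[i]
    higher_l <- which(y[seq_len(i - 1)] > h)
    base_l <- if (length(higher_l) > 0) {
      min(y[(max(higher_l) + 1):i])
    } else min(y[1:i])
    right_idx <- seq(i + 1, n)
    higher_r <- right_idx[y[right_idx] > h]
    base_r <- if (length(higher_r) > 0) {
      min(y[i:(min(higher_r) - 1)])
    } else min(y[i:n])
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  out <- data.frame(position = profile$distance[apex[keep]],
                    height = y[apex[keep]], prominence = prom[keep])
  out[order(out$position), , drop = FALSE]
}

#' Build the reference-band set from parental control lanes
#'
#' Detects peaks in the ISm and ISy control lanes (after background removal)
#' and takes the union across lanes, merging peaks closer than `delta`
#' (merged position = mean of the merged peaks). Band ids are assigned
#' top-to-bottom.
#'
#' @param controls list of control [lane_profile()]s (roles `ISm_control` /
#'   `ISy_control`); at least one of each.
#' @param delta merge / matching tolerance, relative-distance units.
#' @param window background-removal window passed to [remove_background()].
#' @param min_prominence peak threshold passed to [detect_peaks()].
#' @return A data.frame of class `reference_bands` with columns `band`,
#'   `position`, `tolerance`, `mw` (NA unless calibrated).
#' @export
build_reference_set <- function(controls, delta = 0.01, window = 0.05,
                                min_prominence = 0.5) {
  roles <- vapply(controls, function(l) l$role, character(1))
  if (!any(roles == "ISm_control") || !any(roles == "ISy_control"))
    stop("need at least one ISm control and one ISy control lane")
  positions <- unlist(lapply(controls, function(l) {
    detect_peaks(remove_background(l, window), min_prominence)$position
  }))
  if (length(positions) == 0)
    stop("no peaks detected in any control lane; cannot build a reference set")
  positions <- sort(positions)
  grp <- cumsum(c(1, diff(positions) >= delta))
  merged <- as.numeric(tapply(positions, grp, mean))
  if (any(diff(merged) <= delta))
    warning("adjacent reference bands are closer than the matching tolerance")
  out <- data.frame(band = seq_along(merged), position = merged,
                    tolerance = delta, mw = NA_real_)
  class(out) <- c("reference_bands", "data.frame")
  out
}

#' Match detected peaks to the reference bands of one lane
#'
#' Assigns each detected peak to at most one reference band (greedy by
#' increasing peak-to-band distance, ties broken toward the lower band id)
#' within the matching tolerance. A matched band takes the height of its
#' peak; an unmatched band falls back to the background-removed profile value
#' at the reference position, so the resulting vector is always complete.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param refs a [build_reference_set()] table.
#' @param profile the background-removed [lane_profile()] the peaks came from
#'   (fallback values for unmatched bands).
#' @return Named numeric vector of per-band heights (length `nrow(refs)`).
#' @export
match_reference_bands <- function(peaks, refs, profile) {
  heights <- stats::approx(profile$distance, profile$intensity,
                           xout = refs$position, rule = 2)$y
  heights <- pmax(heights, 0)
  if (nrow(peaks) > 0) {
    cand <- expand.grid(peak = seq_len(nrow(peaks)), band = seq_len(nrow(refs)))
    cand$dist <- abs(peaks$position[cand$peak] - refs$position[cand$band])
    cand <- cand[cand$dist <= refs$tolerance[cand$band], , drop = FALSE]
    cand <- cand[order(cand$dist, cand$band), , drop = FALSE]
    used_peak <- logical(nrow(peaks))
    used_band <- logical(nrow(refs))
    for (i in seq_len(nrow(cand))) {
      p <- cand$peak[i]; b <- cand$band[i]
      if (!used_peak[p] && !used_band[b]) {
        heights[b] <- peaks$height[p]
        used_peak[p] <- TRUE
        used_band[b] <- TRUE
      }
    }
  }
  names(heights) <- sprintf("band_%02d", refs$band)
  heights
}

#' Quantile normalization across lanes
#'
#' Classic quantile normalization of the band-intensity matrix across lanes
#' (rows): the k-th order statistic of every lane is replaced by the mean of
#' the k-th order statistics over all lanes, so every lane ends with the same
#' sorted intensity multiset while within-lane ranks are preserved. Tied
#' values within a lane receive the mean of the order-statistic means they
#' jointly occupy. All-zero lanes are excluded from the reference
#' distribution and left as zeros (with a warning).
#'
#' @param x a [band_matrix()] or plain matrix, individuals in rows.
#' @return Object of the same type, normalized.
#' @export
quantile_normalize <- function(x) {
  m <- bm_intensity(x)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("quantile normalization needs at least 2 individuals and 2 bands")
  zero_rows <- rowSums(m != 0) == 0
  if (any(zero_rows))
    warning(sum(zero_rows), " all-zero lane(s) left unnormalized")
  ref <- m[!zero_rows, , drop = FALSE]
  if (nrow(ref) == 0) stop("all lanes are zero; nothing to normalize")
  ord_means <- colMeans(t(apply(ref, 1, sort)))
  out <- m
  for (i in which(!zero_rows)) {
    v <- ord_means[rank(m[i, ], ties.method = "first")]
    out[i, ] <- stats::ave(v, match(m[i, ], m[i, ]), FUN = mean)
  }
  if (inherits(x, "band_matrix")) {
    band_matrix(out, x$design, normalized = TRUE)
  } else {
    out
  }
}

#' Extract the band-intensity matrix from lane profiles
#'
#' End-to-end lane processing: background removal and peak detection on every
#' lane, reference-band construction from the parental control lanes,
#' nearest-reference matching of each individual lane, and joint quantile
#' normalization over all individual lanes. The raw (pre-normalization)
#' matrix is kept for uses that require unnormalized intensities, such as the
#' Western-blot correction denominator.
#'
#' @param lanes list of [lane_profile()]s: one `individual` lane per design
#'   row (lane_id = individual_id) plus ISm / ISy control lanes.
#' @param design a [design_table()].
#' @param window background-removal window.
#' @param min_prominence peak-calling threshold.
#' @param delta reference matching tolerance.
#' @return A list of class `band_extraction`: `normalized` and `raw`
#'   [band_matrix()]s, `reference` (the reference-band table),
#'   `control_intensities` (mean per-band heights in the ISm and ISy control
#'   lanes) and `origin` (per-band origin index, NA where both controls are
#'   zero).
#' @export
extract_band_matrix <- function(lanes, design, window = 0.05,
                                min_prominence = 0.5, delta = 0.01) {
  roles <- vapply(lanes, function(l) l$role, character(1))
  ids <- vapply(lanes, function(l) l$lane_id, character(1))
  indiv <- lanes[roles == "individual"]
  indiv_ids <- ids[roles == "individual"]
  missing_lane <- setdiff(design$individual_id, indiv_ids)
  extra_lane <- setdiff(indiv_ids, design$individual_id)
  if (length(missing_lane) > 0 || length(extra_lane) > 0)
    stop("design/lane mismatch; missing lanes: ",
         paste(utils::head(missing_lane, 5), collapse = ", "),
         if (length(extra_lane) > 0) paste0("; unexpected lanes: ",
           paste(utils::head(extra_lane, 5), collapse = ", ")))
  controls <- lanes[roles %in% c("ISm_control", "ISy_control")]
  refs <- build_reference_set(controls, delta = delta, window = window,
                              min_prominence = min_prominence)

  lane_heights <- function(lane) {
    bg <- remove_background(lane, window)
    match_reference_bands(detect_peaks(bg, min_prominence), refs, bg)
  }
  raw <- t(vapply(indiv, lane_heights, numeric(nrow(refs))))
  raw <- raw[match(design$individual_id, indiv_ids), , drop = FALSE]
  raw_bm <- band_matrix(raw, design, normalized = FALSE)

  ctrl <- t(vapply(controls, lane_heights, numeric(nrow(refs))))
  ctrl_role <- vapply(controls, function(l) l$role, character(1))
  ism <- colMeans(ctrl[ctrl_role == "ISm_control", , drop = FALSE])
  isy <- colMeans(ctrl[ctrl_role == "ISy_control", , drop = FALSE])
  tot <- ism + isy
  origin <- ifelse(tot > 0, ism / tot, NA_real_)

  structure(list(normalized = quantile_normalize(raw_bm), raw = raw_bm,
                 reference = refs,
                 control_intensities = data.frame(band = refs$band, ISm = ism,
                                                  ISy = isy),
                 origin = origin),
            class = "band_extraction")
}

#' Band origin index
#'
#' Proximity of a reference band to the parental lines: ISm intensity divided
#' by the sum of its ISm and ISy intensities. 1 means the band is present in
#' ISm venom and absent from ISy; 0 the opposite.
#'
#' @param intensity_ISm,intensity_ISy non-negative parental band intensities
#'   (vectorized).
#' @return Values in \[0, 1\].
#' @export
band_origin_index <- function(intensity_ISm, intensity_ISy) {
  if (any(intensity_ISm < 0) || any(intensity_ISy < 0))
    stop("intensities must be non-negative")
  tot <- intensity_ISm + intensity_ISy
  if (any(tot <= 0))
    stop("origin index undefined where both parental intensities are zero")
  intensity_ISm / tot
}

#' Per-band origin indices of a parental profile table
#'
#' @param parents a [default_parental_profiles()] table.
#' @return Numeric vector of origin indices (see [band_origin_index()]).
#' @export
band_origins <- function(parents) {
  band_origin_index(parents$intensity_ISm, parents$intensity_ISy)
}
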