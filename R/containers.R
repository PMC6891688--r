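#' Experimental design table
#'
#' Builds the table of individual wasps sampled for venom analysis: replicated
#' selection lines kept on a resistant (R) or susceptible (S) host strain and
#' assayed at several generations. Each (replicate, host) pair is one
#' experimental population. The default reproduces the study layout of 8
#' replicates x 2 hosts x 3 generations x 10 females, with a single reduced
#' F2 cell of 4 females on the S host, for 474 individuals in total.
#'
#' @param n_replicates number of replicates (selection lines per host).
#' @param hosts host strain labels; `"R"` (resistant) and `"S"` (susceptible).
#' @param generations generations at which venom is assayed.
#' @param n_per_cell number of females per (replicate, host, generation) cell.
#' @param reduced_cell optional list (`replicate`, `host`, `generation`, `n`)
#'   overriding the size of one cell; `NULL` for a balanced design.
#' @return A data.frame of class `design_table` with columns `individual_id`,
#'   `replicate`, `host`, `generation` and `population` (derived from
#'   replicate and host).
#' @examples
#' d <- design_table()
#' nrow(d) # 474
#' @export
design_table <- function(n_replicates = 8, hosts = c("R", "S"),
                         generations = c(2, 6, 10), n_per_cell = 10,
                         reduced_cell = list(replicate = 1, host = "S",
                                             generation = 2, n = 4)) {
  stopifnot(n_replicates >= 1, length(hosts) >= 1, n_per_cell >= 1)
  cells <- expand.grid(generation = generations, host = hosts,
                       replicate = seq_len(n_replicates),
                       stringsAsFactors = FALSE)
  cells <- cells[, c("replicate", "host", "generation")]
  cells$n <- n_per_cell
  if (!is.null(reduced_cell)) {
    hit <- cells$replicate == reduced_cell$replicate &
      cells$host == reduced_cell$host &
      cells$generation == reduced_cell$generation
    if (!any(hit)) stop("`reduced_cell` does not match any design cell")
    if (reduced_cell$n < 1) stop("every design cell needs at least 1 individual")
    cells$n[hit] <- reduced_cell$n
  }
  design <- cells[rep(seq_len(nrow(cells)), cells$n),
                  c("replicate", "host", "generation")]
  rownames(design) <- NULL
  design$indiv <- stats::ave(design$replicate,
                             design$replicate, design$host, design$generation,
                             FUN = seq_along)
  design$individual_id <- sprintf("r%02d%s_F%02d_%02d", design$replicate,
                                  design$host, design$generation, design$indiv)
  design$population <- sprintf("r%02d_%s", design$replicate, design$host)
  design <- design[, c("individual_id", "replicate", "host", "generation",
                       "population")]
  class(design) <- c("design_table", "data.frame")
  design
}

#' Band-intensity matrix with design metadata
#'
#' The central trait container: one row per individual wasp, one column per
#' reference protein band, holding non-negative densitometry intensities
#' ("height" of each band), plus the design metadata describing each row.
#'
#' @param intensity numeric matrix (individuals x bands), non-negative and
#'   finite. Columns are named `band_01`, `band_02`, ... if unnamed.
#' @param design a [design_table()] (or compatible data.frame) with one row
#'   per matrix row, in the same order.
#' @param normalized logical flag: has quantile normalization been applied?
#' @return An object of class `band_matrix`: a list with elements
#'   `intensity`, `design`, `normalized`.
#' @export
band_matrix <- function(intensity, design, normalized = FALSE) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (!is.data.frame(design)) stop("`design` must be a data.frame")
  need <- c("individual_id", "replicate", "host", "generation", "population")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(intensity) != nrow(design))
    stop("intensity has ", nrow(intensity), " rows but design has ",
         nrow(design))
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (is.null(colnames(intensity)))
    colnames(intensity) <- sprintf("band_%02d", seq_len(ncol(intensity)))
  rownames(intensity) <- design$individual_id
  structure(list(intensity = intensity, design = design,
                 normalized = isTRUE(normalized)),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d individuals x %d bands (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              if (x$normalized) "quantile-normalized" else "raw"))
  cat(sprintf("  replicates: %d | hosts: %s | generations: %s\n",
              length(unique(x$design$replicate)),
              paste(sort(unique(x$design$host)), collapse = "/"),
              paste(sort(unique(x$design$generation)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$intensity)

# row subset that keeps intensity and design aligned
bm_subset <- function(x, i) {
  band_matrix(x$intensity[i, , drop = FALSE], x$design[i, , drop = FALSE],
              normalized = x$normalized)
}

# resolve a band_matrix or plain matrix argument to an intensity matrix
bm_intensity <- function(x) {
  if (inherits(x, "band_matrix")) x$intensity else as.matrix(x)
}

#' Lane densitometry profile
#'
#' One gel lane as a 1D intensity trace over relative migration distance
#' (0 = top of the gel, 1 = bottom).
#'
#' @param lane_id identifier; for individual lanes this is the individual id.
#' @param distance strictly increasing relative migration distances in
#'   \[0, 1\].
#' @param intensity finite intensities (arbitrary densitometry units).
#' @param role one of `"individual"`, `"ISm_control"`, `"ISy_control"`,
#'   `"ladder"`.
#' @return An object of class `lane_profile`.
#' @export
lane_profile <- function(lane_id, distance, intensity,
                         role = c("individual", "ISm_control", "ISy_control",
                                  "ladder")) {
  role <- match.arg(role)
  distance <- as.numeric(distance)
  intensity <- as.numeric(intensity)
  if (length(distance) != length(intensity))
    stop("distance and intensity lengths differ")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (any(diff(distance) <= 0))
    stop("relative distance must be strictly increasing")
  if (min(distance) < 0 || max(distance) > 1)
    stop("relative distance must lie in [0, 1]")
  structure(list(lane_id = as.character(lane_id), distance = distance,
                 intensity = intensity, role = role),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("lane_profile '%s' (%s): %d samples on [%.3f, %.3f]\n",
              x$lane_id, x$role, length(x$distance), min(x$distance),
              max(x$distance)))
  invisible(x)
}
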