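# shared fixtures, built in code

# a lane made of Gaussian peaks on an optional linear baseline
gaussian_lane <- function(positions, heights, sigma = 0.01, n = 1000,
                          a = 0, c = 0, noise_sd = 0, role = "individual",
                          lane_id = "lane") {
  x <- seq(0, 1, length.out = n)
  y <- a + c * x
  for (i in seq_along(positions))
    y <- y + heights[i] * exp(-(x - positions[i])^2 / (2 * sigma^2))
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  lane_profile(lane_id, x, y, role = role)
}

# small balanced design for fast tests
small_design <- function(n_replicates = 2, n_per_cell = 3) {
  design_table(n_replicates = n_replicates, n_per_cell = n_per_cell,
               reduced_cell = NULL)
}

# construct an n x k matrix whose sample correlation matrix is exactly C
matrix_with_correlation <- function(n, C, seed = 1) {
  set.seed(seed)
  k <- ncol(C)
  z <- matrix(rnorm(n * k), n, k)
  z <- scale(z, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z))
  x <- q %*% chol(C)
  scale(x, center = TRUE, scale = FALSE)
}

# all permutations of 1..n (n small), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0
  for (i in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(i, rows), sub + (sub >= i))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# host x generation grouping factor of a design
hg_groups <- function(design) {
  factor(paste0(design$host, "_F", design$generation))
}
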