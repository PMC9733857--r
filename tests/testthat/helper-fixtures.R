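# Small fixtures and independent oracles shared across the suite.

# quick grid from a matrix (30 m cells unless said otherwise)
g30 <- function(m, cell = 30) eco_grid(as.matrix(m), cell_size = cell)

# one-class land-use map: every cell the given secondary code
uniform_landuse <- function(nr, nc, code = 21, cell = 30) {
  eco_landuse(matrix(code, nr, nc), cell_size = cell)
}

# Brute-force nearest-source Euclidean distance (centre to centre):
# the oracle distance_field() must reproduce on small grids.
brute_distance <- function(src, cell) {
  nr <- nrow(src); nc <- ncol(src)
  pts <- which(src, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    out[r, c] <- cell * sqrt(min((pts[, 1] - r)^2 + (pts[, 2] - c)^2))
  }
  out
}

# Total within-class sum of squared deviations of a partition of sorted x
# given the last index of each class but the final one.
partition_ssd <- function(x_sorted, last_idx) {
  bounds <- c(0L, last_idx, length(x_sorted))
  tot <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    seg <- x_sorted[(bounds[i] + 1L):bounds[i + 1L]]
    tot <- tot + sum((seg - mean(seg))^2)
  }
  tot
}

# Exhaustive Fisher-Jenks optimum: minimal SSD over every placement of
# k - 1 breaks in a sorted vector (feasible for n <= 20).
jenks_exhaustive_ssd <- function(x, k) {
  s <- sort(x)
  n <- length(s)
  combs <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(combs))) {
    ssd <- partition_ssd(s, combs[, j])
    if (ssd < best) best <- ssd
  }
  best
}

# Step-by-step scalar evaluation of the entropy-weight chain for a small
# normalised matrix, written independently of the package internals.
entropy_weights_oracle <- function(p) {
  n <- nrow(p); m <- ncol(p)
  H <- numeric(m)
  for (i in seq_len(m)) {
    f <- p[, i] / sum(p[, i])
    f <- f[f > 0]
    H[i] <- -sum(f * log(f)) / log(n)
  }
  (1 - H) / (m - sum(H))
}
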