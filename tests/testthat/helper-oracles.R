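# Independent oracles used to cross-check the implementation.

# Winding-number point-in-polygon test, evaluated for every pixel center
# of an nx-by-ny grid (0-based integer coordinates). Sums signed angles
# around each vertex pair; |winding| > 0.5 turns => inside. Independent of
# the package's even-odd ray-cast rasterizer.
winding_inside <- function(poly, nx, ny) {
  px <- as.vector(matrix(rep(0:(nx - 1), ny), nx, ny))
  py <- as.vector(matrix(rep(0:(ny - 1), each = nx), nx, ny))
  total <- numeric(length(px))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1] - px; ay <- poly[i, 2] - py
    bx <- poly[j, 1] - px; by <- poly[j, 2] - py
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  matrix(abs(total) > pi, nx, ny)
}

# Brute-force per-pixel survival mask (value >= threshold keeps a pixel).
brute_mask <- function(values, threshold) {
  out <- matrix(NA, nrow(values), ncol(values))
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      out[i, j] <- !(values[i, j] < threshold)
    }
  }
  out
}

# Brute-force masked regional mean via an explicit sum/count loop.
brute_region_mean <- function(values, mask, labels, code) {
  s <- 0; n <- 0L
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      if (labels[i, j] == code && mask[i, j]) {
        s <- s + values[i, j]
        n <- n + 1L
      }
    }
  }
  list(mean = s / n, n = n)
}
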