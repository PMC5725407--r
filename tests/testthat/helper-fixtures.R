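# Small fixtures built in code.

# an axis-aligned rectangle polygon with half-pixel-offset corners, so
# pixel centers x0..x1 / y0..y1 rasterize exactly
rect_poly <- function(x0, x1, y0, y1) {
  cbind(x = c(x0 - 0.5, x1 + 0.5, x1 + 0.5, x0 - 0.5),
        y = c(y0 - 0.5, y0 - 0.5, y1 + 0.5, y1 + 0.5))
}

# three disjoint rectangles on a small slice
tiny_boundaries <- function() {
  boundary_config(frontal = rect_poly(1, 4, 1, 3),
                  parietal = rect_poly(1, 4, 10, 12),
                  sensorimotor = rect_poly(1, 4, 6, 8))
}

# slice with chosen constant intensities painted into the tiny regions
tiny_slice <- function(fl = 200, pl = 150, smc = 180, bg = 0,
                       nx = 8, ny = 14, bit_depth = 8L) {
  v <- matrix(bg, nx, ny)
  v[2:5, 2:4] <- fl
  v[2:5, 11:13] <- pl
  v[2:5, 7:9] <- smc
  slice_grid(v, bit_depth = bit_depth, slice_index = 0L)
}

# a small random sparse volume for round-trip fuzzing
random_volume <- function(dims = c(5, 6, 7), n = 20, bit_depth = 15L) {
  coords <- unique(cbind(sample(0:(dims[1] - 1), n, TRUE),
                         sample(0:(dims[2] - 1), n, TRUE),
                         sample(0:(dims[3] - 1), n, TRUE)))
  arr <- array(0, dim = dims)
  arr[coords + 1] <- sample.int(2^bit_depth - 1, nrow(coords), TRUE)
  voxel_volume(arr, bit_depth = bit_depth)
}
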