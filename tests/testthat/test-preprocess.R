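test_that("slice extraction counts ordinally from the top", {
  arr <- array(0, c(4, 5, 6))
  for (z in 1:6) arr[, , z] <- z * 10
  v <- voxel_volume(arr, bit_depth = 8)
  expect_true(all(extract_slice(v, 1)$values == 10))
  expect_true(all(extract_slice(v, 6)$values == 60))
  expect_equal(extract_slice(v, 3)$slice_index, 2L)
  expect_error(extract_slice(v, 7), "out of range")
  expect_error(extract_slice(v, 0), "out of range")
})

test_that("the 30th slice of the standard geometry sits 58-60 mm deep", {
  v <- voxel_volume(array(0, c(86, 100, 86)))
  sl <- extract_slice(v, 30)
  expect_equal(sl$dims, c(86L, 100L))
  depth_window <- c(sl$slice_index, sl$slice_index + 1) * v$spacing_mm[3]
  expect_equal(depth_window, c(58, 60))
})

test_that("the masking threshold is the stated fraction of the bit-depth maximum", {
  expect_identical(mask_threshold(0.45, 15), 14745.15)
  expect_equal(mask_threshold(0.45, 8), 114.75)
  expect_equal(mask_threshold(0.5, 1), 0.5)
  expect_error(mask_threshold(0, 15), "between 0 and 1")
  expect_error(mask_threshold(1, 15), "between 0 and 1")

  # linear in (2^bits - 1), strictly increasing in fraction and depth
  expect_equal(mask_threshold(0.45, 16) / (2^16 - 1),
               mask_threshold(0.45, 4) / (2^4 - 1))
  fr <- seq(0.1, 0.9, by = 0.2)
  expect_true(all(diff(vapply(fr, mask_threshold, 1, bit_depth = 12)) > 0))
  expect_true(all(diff(vapply(8:16, function(b)
    mask_threshold(0.45, b), 1)) > 0))
})

test_that("masking keeps values at or above threshold and is idempotent", {
  zero <- slice_grid(matrix(0, 5, 5), bit_depth = 8)
  expect_false(any(apply_mask(zero, 10)$mask))

  const <- slice_grid(matrix(42, 5, 5), bit_depth = 8)
  expect_true(all(apply_mask(const, 42)$mask))  # 42 is not below 42

  set.seed(3)
  for (rep in 1:10) {
    v <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
    sl <- slice_grid(v, bit_depth = 8)
    thr <- runif(1, 0, 255)
    m1 <- apply_mask(sl, thr)
    expect_identical(m1$mask, brute_mask(v, thr))
    expect_identical(m1$values, v)
    expect_identical(apply_mask(m1, thr)$mask, m1$mask)
  }
})

test_that("rectangle segmentation yields closed-form label areas", {
  sl <- slice_grid(matrix(0, 20, 30), bit_depth = 8)
  b <- boundary_config(frontal = rect_poly(2, 6, 2, 5),
                       parietal = rect_poly(2, 6, 20, 27),
                       sensorimotor = rect_poly(10, 15, 10, 14))
  lab <- unclass(segment_lobes(sl, b))
  expect_equal(sum(lab == 1L), 5 * 4)
  expect_equal(sum(lab == 2L), 5 * 8)
  expect_equal(sum(lab == 3L), 6 * 5)
  expect_equal(sum(lab == 0L), 600 - 20 - 40 - 30)
})

test_that("the half-open edge rule assigns shared boundaries to one side only", {
  sl <- slice_grid(matrix(0, 12, 12), bit_depth = 8)
  # two rectangles sharing the vertical line x = 5.5 exactly
  b <- boundary_config(
    frontal = cbind(c(1.5, 5.5, 5.5, 1.5), c(1.5, 1.5, 8.5, 8.5)),
    parietal = cbind(c(5.5, 9.5, 9.5, 5.5), c(1.5, 1.5, 8.5, 8.5)),
    sensorimotor = rect_poly(1, 9, 10, 11))
  lab <- unclass(segment_lobes(sl, b))
  expect_equal(sum(lab == 1L), 4 * 7)   # x in {2..5}
  expect_equal(sum(lab == 2L), 4 * 7)   # x in {6..9}
  # no pixel lost or duplicated along the shared edge
  expect_equal(sum(lab %in% 1:2), 8 * 7)
})

test_that("segmentation matches a winding-number oracle on random triangles", {
  set.seed(21)
  nx <- 40; ny <- 30
  sl <- slice_grid(matrix(0, nx, ny), bit_depth = 8)
  done <- 0
  while (done < 8) {
    # continuous vertices keep pixel centers off the edges
    tri <- function(cx, cy) cbind(cx + runif(3, -6, 6) + 0.25,
                                  cy + runif(3, -6, 6) + 0.25)
    polys <- list(frontal = tri(8, 8), parietal = tri(30, 8),
                  sensorimotor = tri(19, 22))
    oracle <- lapply(polys, winding_inside, nx = nx, ny = ny)
    if (any(vapply(oracle, sum, 1) == 0)) next  # degenerate draw
    b <- boundary_config(polys$frontal, polys$parietal, polys$sensorimotor)
    lab <- unclass(segment_lobes(sl, b))
    expect_identical(lab == 1L, oracle$frontal)
    expect_identical(lab == 2L, oracle$parietal)
    expect_identical(lab == 3L, oracle$sensorimotor)
    done <- done + 1
  }
})

test_that("label counts are invariant under common integer translation", {
  sl <- slice_grid(matrix(0, 30, 30), bit_depth = 8)
  base <- list(frontal = rect_poly(2, 6, 2, 5) ,
               parietal = cbind(c(3.2, 12.7, 7.1), c(12.3, 13.9, 20.2)),
               sensorimotor = rect_poly(16, 20, 3, 8))
  shift <- function(p, dx, dy) cbind(p[, 1] + dx, p[, 2] + dy)
  lab0 <- unclass(segment_lobes(sl, do.call(boundary_config, base)))
  lab1 <- unclass(segment_lobes(sl, do.call(boundary_config,
    lapply(base, shift, dx = 4, dy = 7))))
  expect_equal(tabulate(lab0 + 1L, 4L), tabulate(lab1 + 1L, 4L))
})

test_that("overlapping polygons and out-of-bounds points are rejected", {
  sl <- slice_grid(matrix(0, 12, 12), bit_depth = 8)
  b <- boundary_config(frontal = rect_poly(1, 6, 1, 6),
                       parietal = rect_poly(4, 9, 4, 9),  # overlaps frontal
                       sensorimotor = rect_poly(1, 3, 9, 11))
  expect_error(segment_lobes(sl, b), "overlap on 9 pixel")

  b2 <- boundary_config(frontal = rect_poly(1, 20, 1, 6),
                        parietal = rect_poly(4, 9, 8, 9),
                        sensorimotor = rect_poly(1, 3, 10, 11))
  expect_error(segment_lobes(sl, b2), "outside slice dims")
})
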