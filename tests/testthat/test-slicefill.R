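disc_slice <- function(n, r, centre = c(0, 0)) {
  ii <- outer(seq_len(n) - (n + 1) / 2 - centre[1], rep(1, n))
  jj <- outer(rep(1, n), seq_len(n) - (n + 1) / 2 - centre[2])
  (sqrt(ii^2 + jj^2) <= r) * 1
}

# interleave the given annotated slices with empty slices to fill
stack_of <- function(slices, kind) {
  nk <- 2L * length(slices) - 1L
  arr <- array(0, c(dim(slices[[1]]), nk))
  ann <- seq(1L, nk, by = 2L)
  for (k in seq_along(slices)) arr[, , ann[k]] <- slices[[k]]
  sparse_slice_stack(voxel_grid(arr, spacing = c(1, 1, 2.5)), ann, kind)
}

test_that("sparse stacks reject wide gaps and off-slice payloads", {
  arr <- array(0, c(4, 4, 5))
  expect_error(sparse_slice_stack(voxel_grid(arr), c(1, 5), "contour"),
               "gaps")
  arr2 <- arr; arr2[1, 1, 2] <- 1
  expect_error(sparse_slice_stack(voxel_grid(arr2), c(1, 3, 5), "contour"),
               "zero outside annotated")
  arr3 <- arr; arr3[1, 1, 1] <- 0.4
  expect_error(sparse_slice_stack(voxel_grid(arr3), c(1, 3, 5), "contour"),
               "binary")
})

test_that("contour interpolation returns geometrically intermediate regions", {
  # identical neighbours reproduce the region exactly
  d <- disc_slice(21, 6)
  same <- interpolate_contours(stack_of(list(d, d), "contour"))
  expect_equal(same$values[, , 2], d)
  # concentric discs radius 5 and 9: filled area strictly between,
  # centre of mass preserved
  a <- disc_slice(25, 5); b <- disc_slice(25, 9)
  out <- interpolate_contours(stack_of(list(a, b), "contour"))
  mid <- out$values[, , 2]
  expect_true(all(mid %in% c(0, 1)))
  expect_gt(sum(mid), sum(a))
  expect_lt(sum(mid), sum(b))
  cm <- function(m) c(sum(row(m) * m), sum(col(m) * m)) / sum(m)
  expect_equal(cm(mid), cm(b), tolerance = 0.05)
  # annotated slices are untouched
  expect_equal(out$values[, , 1], a)
  expect_equal(out$values[, , 3], b)
  # one empty neighbour: strict subset of the non-empty one
  out2 <- interpolate_contours(stack_of(list(b, b * 0), "contour"))
  mid2 <- out2$values[, , 2]
  expect_true(all(mid2 <= b))
  expect_lt(sum(mid2), sum(b))
  # both empty stays empty
  out3 <- interpolate_contours(stack_of(list(a * 0, a * 0), "contour"))
  expect_equal(sum(out3$values[, , 2]), 0)
})

test_that("density interpolation equals the elementwise-mean oracle", {
  set.seed(11)
  a <- matrix(runif(64, 0, 300), 8, 8)
  b <- matrix(runif(64, 0, 300), 8, 8)
  out <- interpolate_density(stack_of(list(a, b), "density"))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) oracle[i, j] <- (a[i, j] + b[i, j]) / 2
  expect_equal(out$values[, , 2], oracle)
  expect_true(all(out$values[, , 2] >= pmin(a, b) - 1e-12))
  expect_true(all(out$values[, , 2] <= pmax(a, b) + 1e-12))
  # worked midpoint: neighbours 100 and 200 -> 150
  c1 <- matrix(100, 4, 4); c2 <- matrix(200, 4, 4)
  expect_equal(interpolate_density(stack_of(list(c1, c2),
                                            "density"))$values[2, 2, 2], 150)
  # identical neighbours reproduce the slice
  out2 <- interpolate_density(stack_of(list(a, a), "density"))
  expect_equal(out2$values[, , 2], a)
  arrn <- array(0, c(4, 4, 3)); arrn[1, 1, 1] <- -5
  expect_error(sparse_slice_stack(voxel_grid(arrn), c(1, 3), "density"),
               "non-negative")
})

test_that("volumetric conversion is the elementwise power and is monotone", {
  expect_equal(to_volumetric(voxel_grid(array(4, c(2, 2, 2))))$values[1], 8)
  expect_equal(to_volumetric(voxel_grid(array(0, c(2, 2, 2))))$values[1], 0)
  expect_equal(to_volumetric(voxel_grid(array(1, c(2, 2, 2))))$values[1], 1)
  set.seed(3)
  g <- voxel_grid(array(runif(27, 0, 500), c(3, 3, 3)))
  out <- to_volumetric(g, 1.5)
  oracle <- array(0, c(3, 3, 3))
  for (q in seq_along(g$values)) oracle[q] <- g$values[q]^1.5
  expect_equal(out$values, oracle)
  expect_equal(order(out$values), order(g$values))
  expect_equal(to_volumetric(g, 1)$values, g$values)
  gneg <- voxel_grid(array(-1, c(2, 2, 2)))
  expect_error(to_volumetric(gneg), "non-negative")
})

test_that("probabilistic lesion interpolation applies the 0.5 weighting rules", {
  sq <- function(n, on) { m <- matrix(0, n, n); if (on) m[3:5, 3:5] <- 1; m }
  # same grade on both flanks -> 1 on the filled slice
  both <- interpolate_lesions(list(A = stack_of(list(sq(8, TRUE), sq(8, TRUE)),
                                                "lesion_grade")))
  expect_equal(both$A$values[4, 4, 2], 1)
  # one flank only -> 0.5 at covered in-plane positions
  one <- interpolate_lesions(list(A = stack_of(list(sq(8, TRUE), sq(8, FALSE)),
                                               "lesion_grade")))
  expect_equal(one$A$values[4, 4, 2], 0.5)
  expect_equal(one$A$values[1, 1, 2], 0)
  # different grades on the two flanks -> 0.5 in each grade's image
  two <- interpolate_lesions(list(
    A = stack_of(list(sq(8, TRUE), sq(8, FALSE)), "lesion_grade"),
    B = stack_of(list(sq(8, FALSE), sq(8, TRUE)), "lesion_grade")))
  expect_equal(two$A$values[4, 4, 2], 0.5)
  expect_equal(two$B$values[4, 4, 2], 0.5)
  # annotated slices unchanged; all values within [0, 1]
  expect_equal(two$A$values[, , 1], sq(8, TRUE))
  for (m in two) expect_true(all(m$values >= 0 & m$values <= 1))
  # a single annotated voxel cannot carry two grades
  expect_error(interpolate_lesions(list(
    A = stack_of(list(sq(8, TRUE), sq(8, FALSE)), "lesion_grade"),
    B = stack_of(list(sq(8, TRUE), sq(8, FALSE)), "lesion_grade"))),
    "one grade per annotated lesion voxel")
})

test_that("fill_patient produces a consistent filled dataset", {
  spec <- phantom_spec(n_patients = 1, rng_seed = 5)
  p <- generate_cohort(spec)[[1]]
  f <- fill_patient(p)
  expect_true(f$density_volumetric)
  s <- f$annotated_slices
  # annotated slices preserved exactly for every payload
  expect_equal(f$density$values[, , s], p$density$values[, , s]^1.5)
  expect_equal(f$pz_mask$values[, , s], p$pz_mask$values[, , s])
  # validity marks exactly the annotated slab
  slab <- seq(s[1], s[length(s)])
  expect_true(all(f$validity_mask$values[, , slab] == 1))
  expect_true(all(f$validity_mask$values[, , -slab] == 0))
  # filled PZ stays inside the gland
  expect_true(all(f$pz_mask$values <= f$prostate_mask$values))
})
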