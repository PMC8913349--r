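test_that("principal-axis alignment centres and diagonalises an ellipsoid", {
  m <- ellipsoid_mask(c(12, 8, 10), 41, 1, centre = c(4, -3, 5))
  res <- principal_axis_align(m)
  expect_equal(res$alignment$rotation, diag(3), tolerance = 0.05)
  expect_lt(max(abs(mask_centroid(res$aligned))), 0.6)
  # rotated ellipsoid: transformed second moments diagonal (moment oracle)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  mr <- ellipsoid_mask(c(12, 8, 10), 41, 1, rotation = R)
  resr <- principal_axis_align(mr)
  w <- which(resr$aligned$values != 0, arr.ind = TRUE)
  pts <- prostatlas:::index_to_world(resr$aligned, w)
  cov <- crossprod(sweep(pts, 2, colMeans(pts), "-")) / nrow(pts)
  offdiag <- max(abs(cov[upper.tri(cov)]))
  expect_lt(offdiag, 0.01 * max(diag(cov)))
})

test_that("spherical (degenerate) moments still give a proper rotation", {
  s <- sphere_mask(8, 25)
  res <- principal_axis_align(s)
  A <- res$alignment$rotation
  expect_equal(crossprod(A), diag(3), tolerance = 1e-9)
  expect_equal(det(A), 1, tolerance = 1e-9)
  expect_lt(max(abs(mask_centroid(res$aligned))), 0.6)
  expect_error(principal_axis_align(grid_like(s, s$values * 0)), "empty")
})

test_that("principal-axis alignment is idempotent", {
  th <- 20 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  m <- ellipsoid_mask(c(12, 8, 10), 41, 1, centre = c(3, 1, -2), rotation = R)
  once <- principal_axis_align(m)
  twice <- principal_axis_align(once$aligned)
  expect_equal(twice$alignment$rotation, diag(3), tolerance = 0.03)
  expect_lt(max(abs(twice$alignment$translation)), 0.6)
})

test_that("consensus volume implements the half-or-more rule", {
  base <- sphere_mask(6, 17)
  expect_equal(consensus_volume(list(base, base, base))$values, base$values)
  # 4 masks, a voxel covered by exactly 2 is included at fraction 0.5
  g <- centred_grid(5)
  m1 <- grid_like(g, array(0, c(5, 5, 5))); m1$values[3, 3, 3] <- 1
  m2 <- m1
  m0 <- grid_like(g, array(0, c(5, 5, 5)))
  cons <- consensus_volume(list(m1, m2, m0, m0), fraction = 0.5)
  expect_equal(cons$values[3, 3, 3], 1)
  # 5 random masks equal the brute-force counting oracle at >= ceil(2.5) = 3
  set.seed(21)
  masks <- lapply(1:5, function(i)
    grid_like(g, array(rbinom(125, 1, 0.5), c(5, 5, 5))))
  cons5 <- consensus_volume(masks, 0.5)
  counts <- array(0, c(5, 5, 5))
  for (m in masks) counts <- counts + m$values
  expect_equal(cons5$values, (counts >= 3) * 1)
  # permutation invariance and monotonicity in added coverage
  expect_equal(consensus_volume(rev(masks), 0.5)$values, cons5$values)
  plus <- consensus_volume(c(masks, list(grid_like(g, array(1, c(5, 5, 5))))),
                           fraction = 3 / 6)
  expect_true(all(plus$values >= cons5$values))
  expect_error(consensus_volume(list(m1, centred_grid(7))), "aligned")
})

test_that("urethra tube is a cylinder of the requested radius around a line", {
  g <- centred_grid(31, 1)
  line <- cbind(0, 0, seq(-12, 12, length.out = 7))
  tube <- urethra_tube(line, radius = 3, template = g)
  w <- which(tube$values != 0, arr.ind = TRUE)
  pts <- prostatlas:::index_to_world(tube, w)
  axial <- abs(pts[, 3]) <= 10
  rad <- sqrt(pts[axial, 1]^2 + pts[axial, 2]^2)
  expect_lt(max(rad), 3 + sqrt(3) / 2 + 1e-9)
  expect_gt(max(rad), 2)
  # monotone in radius: smaller tube nested in larger
  t1 <- urethra_tube(line, 1, g); t2 <- urethra_tube(line, 2, g)
  expect_true(all(t1$values <= t2$values))
  expect_error(urethra_tube(matrix(1, 3, 3), 1.5, g), "degenerate")
})

test_that("default tube radius follows the 1.5 mm configuration", {
  g <- centred_grid(c(41, 41, 21), 0.5)
  line <- cbind(0, 0, seq(-4, 4, length.out = 5))
  tube <- urethra_tube(line, template = g)   # default radius
  w <- which(tube$values != 0, arr.ind = TRUE)
  pts <- prostatlas:::index_to_world(tube, w)
  rad <- sqrt(pts[abs(pts[, 3]) <= 3, 1]^2 + pts[abs(pts[, 3]) <= 3, 2]^2)
  expect_lt(max(rad), 1.5 + sqrt(3) * 0.25 + 1e-9)
  expect_equal(pipeline_config()$urethra_radius, 1.5)
})

test_that("reference construction reproduces simple cohorts", {
  # identical patients: reference congruent to the common gland
  spec <- phantom_spec(n_patients = 3, radii_jitter = 0, rotation_deg = 0,
                       gland_radii = c(16, 13, 15), in_plane_spacing = 1.5,
                       apex_base_margin = 4, rng_seed = 2)
  cohort <- lapply(generate_cohort(spec), fill_patient)
  cfg <- pipeline_config(iso_spacing = 1.5,
                         demons = list(iterations = c(15L, 10L, 5L)))
  ref <- build_reference(cohort, cfg, deformable = FALSE)
  vol_ref <- sum(ref$prostate$values) * prod(ref$grid$spacing)
  vol_pat <- sum(cohort[[1]]$prostate_mask$values) *
    prod(cohort[[1]]$prostate_mask$spacing)
  expect_lt(abs(vol_ref - vol_pat) / vol_pat, 0.05)
  expect_true(all(ref$pz$values <= ref$prostate$values))
  expect_gt(sum(ref$urethra$values), 0)
  # deterministic given cohort and config
  ref2 <- build_reference(cohort, cfg, deformable = FALSE)
  expect_identical(ref2$prostate$values, ref$prostate$values)
})

test_that("consensus of nested spheres matches the median-coverage radius", {
  radii <- c(8, 9, 10, 11, 12)
  masks <- lapply(radii, sphere_mask, n = 33, spacing = 1)
  cons <- consensus_volume(masks, 0.5)
  # counting oracle: voxel included iff covered by >= 3 spheres, i.e. r <= 10
  expect_equal(cons$values, sphere_mask(10, 33, 1)$values)
})
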