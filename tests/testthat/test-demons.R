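# Deformable-registration behaviour on geometric phantoms.  Working grids
# are kept at 48-64 voxels per side so each registration runs in seconds.

test_that("registering a shape to itself leaves the grid still", {
  s <- sphere_mask(10, 33, 1)
  d <- distance_preserving_register(s, s)
  mag <- sqrt(d$d[, , , 1]^2 + d$d[, , , 2]^2 + d$d[, , , 3]^2)
  expect_lt(max(mag), 0.1)
})

test_that("the ND = 0.5 shell of a growing sphere maps onto the fixed mid-shell", {
  mov <- sphere_mask(8, 48, 1)
  fix <- sphere_mask(12, 48, 1)
  d <- suppressWarnings(distance_preserving_register(mov, fix))
  ndm <- normalised_distance_map(mov)$values
  ndf <- normalised_distance_map(fix)$values
  sel <- which(abs(ndf$values - 0.5) <= 0.02)
  pts <- grid_points(fix)[sel, , drop = FALSE]
  pts <- pts + prostatlas:::sample_displacement(d, pts)
  at <- prostatlas:::cpp_sample3(as.vector(ndm$values), dim(ndm$values),
                                 prostatlas:::world_to_index(ndm, pts) - 1,
                                 TRUE, TRUE, -1)
  expect_gte(mean(at >= 0.4 & at <= 0.6), 0.95)
})

test_that("boundary match reaches Dice 0.97 on study-sized smooth shapes", {
  mov <- sphere_mask(16, 64, 1)
  fix <- ellipsoid_mask(c(24, 20, 22), 64, 1)
  d <- suppressWarnings(distance_preserving_register(mov, fix))
  expect_gte(dice(warp_mask(mov, d, fix), fix), 0.97)
  expect_gte(nd_preservation(mov, fix, d), 0.95)
})

test_that("displacement fields keep a positive Jacobian determinant in-gland", {
  mov <- sphere_mask(16, 48, 1)
  fix <- ellipsoid_mask(c(20, 16, 18), 48, 1)
  d <- suppressWarnings(distance_preserving_register(mov, fix))
  jac <- jacobian_determinant(d)
  ing <- fix$values == 1
  expect_gte(mean(jac[ing] > 0), 0.999)
})

test_that("mismatched or anisotropic grids are rejected", {
  a <- sphere_mask(5, 17, 1)
  expect_error(distance_preserving_register(a, sphere_mask(5, 19, 1)),
               "aligned")
  aniso <- fill_mask(centred_grid(c(17, 17, 9), c(1, 1, 2.5)),
                     function(p) sqrt(rowSums(p^2)) <= 5)
  expect_error(distance_preserving_register(aniso, aniso), "isotropic")
})

test_that("identity chains and value bounds hold through compose_and_apply", {
  set.seed(2)
  ref <- sphere_mask(10, 25, 1.5)
  data <- grid_like(ref, array(runif(25^3), c(25, 25, 25)))
  chain <- transform_chain()
  out <- compose_and_apply(chain, data, ref, mode = "linear", missing = NA)
  expect_equal(out$values, data$values, tolerance = 1e-12)
  # probabilistic map through a genuine deformable chain stays in [0, 1]
  mov <- sphere_mask(9, 25, 1.5)
  d <- suppressWarnings(distance_preserving_register(mov, ref,
    config = pipeline_config(demons = list(iterations = c(10L, 5L, 5L)))))
  chain2 <- transform_chain(similarity_identity(), list(d))
  prob <- grid_like(ref, array(runif(25^3), c(25, 25, 25)))
  out2 <- compose_and_apply(chain2, prob, ref, mode = "linear", missing = 0)
  expect_gte(min(out2$values), 0)
  expect_lte(max(out2$values), 1)
})

test_that("warped density is missing exactly where warped validity is zero", {
  spec <- phantom_spec(n_patients = 2, gland_radii = c(16, 13, 15),
                       in_plane_spacing = 1.5, apex_base_margin = 4,
                       rng_seed = 31)
  cohort <- lapply(generate_cohort(spec), fill_patient)
  cfg <- pipeline_config(iso_spacing = 1.5,
                         demons = list(iterations = c(15L, 10L, 5L)))
  ref <- build_reference(cohort, cfg, deformable = FALSE)
  chain <- register_patient(cohort[[1]], ref, cfg, pz_stage = FALSE)
  w <- map_patient_to_reference(cohort[[1]], chain, ref)
  expect_identical(is.na(w$density$values), w$validity$values == 0)
  for (m in w$lesion_maps)
    expect_true(all(m$values >= 0 & m$values <= 1))
})

test_that("the full transform chain reproduces the reference gland on phantoms", {
  spec <- phantom_spec(n_patients = 3, gland_radii = c(18, 15, 16),
                       in_plane_spacing = 1.2, apex_base_margin = 4,
                       rng_seed = 13)
  cohort <- lapply(generate_cohort(spec), fill_patient)
  cfg <- pipeline_config(iso_spacing = 1.2,
                         demons = list(iterations = c(30L, 20L, 10L)))
  ref <- build_reference(cohort, cfg, deformable = TRUE)
  for (p in cohort[1:2]) {
    chain <- register_patient(p, ref, cfg)
    warped <- compose_and_apply(chain, p$prostate_mask, ref$prostate,
                                mode = "nearest", missing = 0)
    expect_gte(dice(warped, ref$prostate), 0.95)
  }
})
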