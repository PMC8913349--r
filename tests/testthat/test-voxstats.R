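const_grid <- function(val, n = 4) voxel_grid(array(val, c(n, n, n)))

test_that("sampling frequency counts valid patients per voxel", {
  masks <- lapply(1:5, function(i) const_grid(1))
  n <- sampling_frequency(masks)
  expect_true(all(n$values == 5))
  masks[[1]]$values[1, 1, 1] <- 0
  n2 <- sampling_frequency(masks)
  expect_equal(n2$values[1, 1, 1], 4)
  expect_error(sampling_frequency(list()), "empty")
  expect_error(sampling_frequency(list(const_grid(1, 4), const_grid(1, 5))),
               "aligned")
})

test_that("sampling tapers towards apex and base in the phantom geometry", {
  spec <- phantom_spec(n_patients = 6, gland_radii = c(16, 13, 15),
                       in_plane_spacing = 1.5, apex_base_margin = 4,
                       rng_seed = 19, radii_jitter = 0.15)
  cohort <- lapply(generate_cohort(spec), fill_patient)
  n <- sampling_frequency(lapply(lapply(cohort, patient_record),
                                 `[[`, "validity"))
  prof <- apply(n$values, 3, max)
  mid <- which.max(prof)
  expect_true(all(diff(prof[1:mid]) >= 0))
  expect_true(all(diff(prof[mid:length(prof)]) <= 0))
  expect_equal(max(prof), 6)
  expect_equal(prof[1], 0)
})

test_that("tumour probability model reproduces the binomial moments", {
  # 10 patients, weight 1 everywhere: p = 1, sigma2 = 0, cv = 0
  maps <- lapply(1:10, function(i) list(G = const_grid(1)))
  nmap <- const_grid(10)
  m <- tumour_probability(maps, nmap)
  expect_true(all(m$p$values == 1))
  expect_true(all(m$sigma2$values == 0))
  expect_true(all(m$cv$values == 0))
  # n = 63 with total weight 25.2: p = 0.4, cv = sqrt(0.6 / 25.2)
  maps2 <- lapply(1:63, function(i) list(G = const_grid(0.4)))
  m2 <- tumour_probability(maps2, const_grid(63))
  expect_equal(m2$p$values[1], 0.4, tolerance = 1e-12)
  expect_equal(m2$cv$values[1], sqrt(0.6 / 25.2), tolerance = 1e-12)
  expect_equal(m2$cv$values[1], 0.1543, tolerance = 1e-4)
  # p = 0 flags cv undefined
  m0 <- tumour_probability(lapply(1:5, function(i) list(G = const_grid(0))),
                           const_grid(5))
  expect_true(all(is.na(m0$cv$values)))
  expect_error(tumour_probability(list(list(G = const_grid(1.4))),
                                  const_grid(1)), "outside")
})

test_that("sigma2 equals n p (1-p) and lognormal cv its closed form, voxelwise", {
  set.seed(33)
  npat <- 12
  maps <- lapply(1:npat, function(i)
    list(G = voxel_grid(array(runif(64), c(4, 4, 4)))))
  nmap <- const_grid(npat)
  m <- tumour_probability(maps, nmap)
  recomputed <- nmap$values * m$p$values * (1 - m$p$values)
  expect_equal(m$sigma2$values, recomputed)
  dens <- lapply(1:npat, function(i)
    voxel_grid(array(rlnorm(64, 5, 0.4), c(4, 4, 4))))
  dl <- fit_density_model(dens, "lognormal")
  expect_equal(dl$cv$values, sqrt(exp(dl$sigma2$values) - 1))
})

test_that("density fits use the maximum-likelihood (1/n) forms", {
  # all samples equal c: normal (c, 0); lognormal (log c, 0)
  dens <- lapply(1:6, function(i) const_grid(50))
  dn <- fit_density_model(dens, "normal")
  dl <- fit_density_model(dens, "lognormal")
  expect_equal(max(abs(dn$mu$values - 50)), 0, tolerance = 1e-12)
  expect_equal(max(abs(dn$sigma2$values)), 0, tolerance = 1e-12)
  expect_equal(max(abs(dl$mu$values - log(50))), 0, tolerance = 1e-12)
  expect_equal(max(abs(dl$sigma2$values)), 0, tolerance = 1e-12)
  # samples {e^1, e^3}: lognormal mu = 2, sigma2 = 1 (not the 1/(n-1) form 2)
  dens2 <- list(const_grid(exp(1)), const_grid(exp(3)),
                const_grid(exp(1)), const_grid(exp(3)))
  dl2 <- fit_density_model(dens2, "lognormal")
  expect_equal(dl2$mu$values[1], 2)
  expect_equal(dl2$sigma2$values[1], 1)
  # under the minimum sample count the voxel is flagged unfit
  short <- list(const_grid(10), const_grid(12))
  expect_true(all(is.na(fit_density_model(short, "normal")$mu$values)))
  # zero densities are excluded from the lognormal fit with count adjusted
  withz <- list(const_grid(exp(1)), const_grid(exp(3)), const_grid(0),
                const_grid(exp(2)))
  dlz <- fit_density_model(withz, "lognormal")
  expect_equal(dlz$n$values[1], 3)
  expect_equal(dlz$mu$values[1], 2)
})

test_that("Scott's-rule KDE has the stated bandwidth and normalisation", {
  # engineered sample with sd exactly 2 and n = 32: h = 2 * 32^(-1/5) = 1
  v <- rep(c(-1, 1), 16)
  x <- 10 + v / sd(v) * 2
  k <- kde_estimate(x)
  expect_equal(k$bandwidth, 1, tolerance = 1e-12)
  expect_equal(prostatlas:::trapz(k$grid, k$density), 1, tolerance = 1e-3)
  # consistency: large standard-normal sample centres near 0
  set.seed(12)
  k2 <- kde_estimate(rnorm(1e4))
  expect_lt(abs(prostatlas:::trapz(k2$grid, k2$grid * k2$density)), 0.05)
  # two samples {0, 10}: mixture of two equal kernels, symmetric about 5
  k3 <- kde_estimate(c(0, 10))
  xs <- seq(0, 10, by = 0.25)
  expect_equal(k3$fun(xs), rev(k3$fun(10 - rev(xs))), tolerance = 1e-12)
  expect_equal(k3$fun(0), k3$fun(10), tolerance = 1e-12)
  expect_error(kde_estimate(rep(3, 10)), "distinct")
})

test_that("KL divergence is exact on closed forms and non-negative", {
  g <- seq(-8, 9, length.out = 2001)
  f <- dnorm(g, 0, 1)
  expect_lt(abs(kl_divergence(f, f, g)), 1e-6)
  d <- kl_divergence(f, dnorm(g, 1, 1), g)
  expect_lt(abs(d - 1 / (2 * log(2))) / (1 / (2 * log(2))), 0.01)
  # Gibbs inequality up to quadrature across random density pairs
  set.seed(8)
  for (i in 1:10) {
    e <- dnorm(g, runif(1, -2, 2), runif(1, 0.5, 2))
    m <- dnorm(g, runif(1, -2, 2), runif(1, 0.5, 2)) +
      0.3 * dnorm(g, runif(1, -2, 2), runif(1, 0.5, 2))
    expect_gte(kl_divergence(e, m, g), -1e-6)
  }
  expect_warning(kl_divergence(dnorm(g, 6, 0.3), dnorm(g, -6, 0.05), g),
                 "underflows")
})

test_that("model comparison shares one evaluated mask across both reports", {
  spec <- phantom_spec(n_patients = 12, gland_radii = c(14, 12, 13),
                       in_plane_spacing = 1.8, apex_base_margin = 4,
                       lesion_rate = 0, radii_jitter = 0, rotation_deg = 0,
                       rng_seed = 41)
  recs <- lapply(lapply(generate_cohort(spec), fill_patient), patient_record)
  dens <- lapply(recs, `[[`, "density")
  dn <- fit_density_model(dens, "normal")
  dl <- fit_density_model(dens, "lognormal")
  fit <- suppressWarnings(evaluate_models(dens, dn, dl, max_voxels = 300))
  expect_identical(fit$normal$evaluated_mask$values,
                   fit$lognormal$evaluated_mask$values)
  expect_true(all(fit$normal$dkl_values >= -1e-6))
  expect_true(all(fit$lognormal$dkl_values >= -1e-6))
  s <- fit$normal$summary
  expect_equal(s$mean_dkl, mean(fit$normal$dkl_values))
  expect_equal(s$n_voxels, sum(fit$normal$evaluated_mask$values))
})
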