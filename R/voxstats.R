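# Voxel-level statistical models: sampling frequency, the binomial/normal
# tumour-probability model with its closed-form coefficient of variation,
# maximum-likelihood normal and log-normal cell-density models, and
# KDE-based Kullback-Leibler model comparison.

#' Per-voxel sampling frequency
#'
#' Counts, at every reference voxel, how many patients contribute valid
#' (histology-sampled) data.  Aggregated statistics are normalised by this
#' map, which in the study geometry peaks in the mid-gland and tapers
#' towards apex and base.
#'
#' @param validity_masks list of aligned binary \code{voxel_grid}s, one per
#'   patient.
#' @return an integer-valued \code{voxel_grid}.
#' @export
sampling_frequency <- function(validity_masks) {
  if (length(validity_masks) == 0) stop("empty cohort")
  for (m in validity_masks) assert_binary(m, "validity mask")
  do.call(assert_aligned, c(validity_masks, list(what = "validity masks")))
  grid_like(validity_masks[[1]],
            Reduce(`+`, lapply(validity_masks, function(m) m$values)))
}

#' Voxelwise tumour-probability model
#'
#' Models the frequency of tumour occurrence at each voxel as binomial
#' B(n(x), p(x)), approximated by a normal with mu = n p and
#' sigma^2 = n p (1 - p).  Each patient contributes an any-grade weight
#' min(1, sum of per-grade probabilistic labels) in [0, 1]; p is the sum
#' of weights divided by the sampling frequency.  The coefficient of
#' variation has the closed form sqrt((1 - p) / (n p)), undefined (NA)
#' where p = 0 or n = 0.
#'
#' @param warped_lesion_maps list (one per patient) of named lists
#'   (grade -> \code{voxel_grid} on the reference grid, values in [0, 1]).
#' @param n_map sampling-frequency \code{voxel_grid} from
#'   \code{\link{sampling_frequency}}.
#' @param validity_masks optional per-patient validity masks used to zero
#'   weights outside each patient's sampled region.
#' @return a \code{tumour_probability_model}: list of \code{voxel_grid}s
#'   \code{n}, \code{p}, \code{mu}, \code{sigma2}, \code{rate_var}
#'   (p(1-p)/n), \code{cv}, and \code{p_grade} (per-grade probabilities).
#' @export
tumour_probability <- function(warped_lesion_maps, n_map,
                               validity_masks = NULL) {
  dims <- dim(n_map$values)
  wsum <- array(0, dims)
  grades <- unique(unlist(lapply(warped_lesion_maps, names)))
  gsum <- stats::setNames(lapply(grades, function(g) array(0, dims)), grades)
  for (i in seq_along(warped_lesion_maps)) {
    maps <- warped_lesion_maps[[i]]
    w <- array(0, dims)
    for (g in names(maps)) {
      assert_aligned(n_map, maps[[g]], what = "lesion maps and n map")
      v <- maps[[g]]$values
      if (any(v < 0 | v > 1, na.rm = TRUE))
        stop("lesion weights outside [0, 1]")
      v[is.na(v)] <- 0
      if (!is.null(validity_masks)) v <- v * validity_masks[[i]]$values
      gsum[[g]] <- gsum[[g]] + v
      w <- w + v
    }
    wsum <- wsum + pmin(1, w)
  }
  n <- n_map$values
  p <- ifelse(n > 0, wsum / n, NA_real_)
  p <- pmin(1, p)
  mu <- n * p
  sigma2 <- n * p * (1 - p)
  rate_var <- ifelse(n > 0, p * (1 - p) / n, NA_real_)
  cv <- ifelse(!is.na(p) & p > 0 & n > 0, sqrt((1 - p) / (n * p)), NA_real_)
  structure(list(n = n_map,
                 p = grid_like(n_map, p),
                 mu = grid_like(n_map, mu),
                 sigma2 = grid_like(n_map, sigma2),
                 rate_var = grid_like(n_map, rate_var),
                 cv = grid_like(n_map, cv),
                 p_grade = lapply(gsum, function(s)
                   grid_like(n_map, ifelse(n > 0, pmin(1, s / n), NA_real_)))),
            class = "tumour_probability_model")
}

#' @export
print.tumour_probability_model <- function(x, ...) {
  p <- x$p$values
  cat(sprintf("<tumour_probability_model> n max %d; p range [%.3g, %.3g] over %d sampled voxels\n",
              max(x$n$values), min(p, na.rm = TRUE), max(p, na.rm = TRUE),
              sum(!is.na(p))))
  invisible(x)
}

#' Voxelwise cell-density model
#'
#' Fits, per voxel, either a normal model to the cell-density samples or a
#' normal model to their logarithms (the log-normal model), using the
#' maximum-likelihood (1/n) forms for mean and variance.  Zero densities
#' have no logarithm and are excluded from the log-normal fit at that
#' voxel with the sample count adjusted (or floored, per the config).
#' Voxels with fewer than \code{config$min_samples_fit} valid samples are
#' flagged unfit (NA).
#'
#' @param warped_density_maps list of \code{voxel_grid}s (cells/mm^3, NA
#'   where a patient has no valid data).
#' @param kind \code{"normal"} or \code{"lognormal"}.
#' @param config a \code{pipeline_config}.
#' @return a \code{cell_density_model}: list with \code{kind} and
#'   \code{voxel_grid}s \code{mu}, \code{sigma2}, \code{n}, \code{cv}
#'   (normal: sqrt(sigma2)/mu; log-normal: the n-free closed form
#'   sqrt(exp(sigma2) - 1)).
#' @export
fit_density_model <- function(warped_density_maps,
                              kind = c("normal", "lognormal"),
                              config = pipeline_config()) {
  kind <- match.arg(kind)
  if (length(warped_density_maps) == 0) stop("empty cohort")
  do.call(assert_aligned, c(warped_density_maps, list(what = "density maps")))
  dims <- dim(warped_density_maps[[1]]$values)
  s1 <- array(0, dims); s2 <- array(0, dims); cnt <- array(0, dims)
  for (g in warped_density_maps) {
    v <- g$values
    if (any(v < 0, na.rm = TRUE)) stop("negative density values")
    if (kind == "lognormal") {
      if (config$lognormal_zero == "floor") v[v == 0] <- config$zero_floor
      v <- ifelse(!is.na(v) & v > 0, log(v), NA_real_)
    }
    ok <- !is.na(v)
    v[!ok] <- 0
    s1 <- s1 + v
    s2 <- s2 + v^2
    cnt <- cnt + ok
  }
  fit <- cnt >= config$min_samples_fit
  mu <- ifelse(fit, s1 / cnt, NA_real_)
  sigma2 <- ifelse(fit, pmax(0, s2 / cnt - mu^2), NA_real_)
  cv <- if (kind == "normal")
    ifelse(fit & mu > 0, sqrt(sigma2) / mu, NA_real_)
  else
    ifelse(fit, sqrt(exp(sigma2) - 1), NA_real_)
  ref <- warped_density_maps[[1]]
  structure(list(kind = kind,
                 mu = grid_like(ref, mu),
                 sigma2 = grid_like(ref, sigma2),
                 n = grid_like(ref, cnt),
                 cv = grid_like(ref, cv)),
            class = "cell_density_model")
}

#' @export
print.cell_density_model <- function(x, ...) {
  cat(sprintf("<cell_density_model> kind '%s'; %d fitted voxels\n",
              x$kind, sum(!is.na(x$mu$values))))
  invisible(x)
}

#' Gaussian kernel density estimate with Scott's-rule bandwidth
#'
#' One-dimensional Gaussian KDE with bandwidth h = s * n^(-1/5) (Scott's
#' rule; s the sample standard deviation).  The returned object evaluates
#' on a fixed grid spanning [min - 4h, max + 4h] (overridable) with 512
#' points; on that grid the estimate integrates to 1 within 0.1%.
#'
#' @param samples numeric vector with at least two distinct values.
#' @param n_grid number of evaluation points.
#' @param from,to optional evaluation range overrides (the model
#'   comparison restricts the range to positive densities).
#' @return a \code{kde_estimate}: list with \code{grid}, \code{density},
#'   \code{bandwidth} and a vectorised evaluator \code{fun}.
#' @export
kde_estimate <- function(samples, n_grid = 512L, from = NULL, to = NULL) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 2 || stats::sd(samples) == 0)
    stop("KDE requires at least two distinct samples (degenerate bandwidth)")
  h <- stats::sd(samples) * length(samples)^(-1 / 5)
  lo <- from %||% (min(samples) - 4 * h)
  hi <- to %||% (max(samples) + 4 * h)
  dens <- stats::density(samples, bw = h, kernel = "gaussian",
                         from = lo, to = hi, n = n_grid)
  f <- function(x) {
    rowMeans(stats::dnorm(outer(x, samples, "-"), sd = h))
  }
  structure(list(grid = dens$x, density = dens$y, bandwidth = h, fun = f,
                 n = length(samples)),
            class = "kde_estimate")
}

#' @export
print.kde_estimate <- function(x, ...) {
  cat(sprintf("<kde_estimate> n = %d, bandwidth %.4g, grid [%.4g, %.4g]\n",
              x$n, x$bandwidth, min(x$grid), max(x$grid)))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Kullback-Leibler divergence between two densities on a grid
#'
#' Numerically integrates empirical * log2(empirical / model) by the
#' trapezoid rule after renormalising both densities on the grid, giving
#' the information lost (in bits) when the model approximates the
#' empirical distribution.  The model density is floored at 1e-30 inside
#' the integrand; if the model is effectively zero where the empirical
#' density carries mass, the capped contribution triggers a warning.
#'
#' @param empirical,model numeric density values on \code{grid}, or
#'   functions to evaluate there (e.g. a \code{kde_estimate}'s \code{fun}).
#' @param grid increasing numeric evaluation grid.
#' @return KL divergence in bits (non-negative up to quadrature tolerance).
#' @export
kl_divergence <- function(empirical, model, grid) {
  ev <- function(f) if (is.function(f)) f(grid) else as.numeric(f)
  e <- ev(empirical); m <- ev(model)
  if (length(e) != length(grid) || length(m) != length(grid))
    stop("densities and grid must have equal length")
  e <- e / trapz(grid, e)
  zm <- trapz(grid, m)
  if (zm <= 0) stop("model density has no mass on the evaluation grid")
  m <- m / zm
  floorv <- 1e-30
  capped <- e > 1e-8 & m < floorv
  if (any(capped))
    warning(sprintf("model density underflows where the empirical density is positive at %d grid points; contributions capped",
                    sum(capped)))
  integrand <- ifelse(e > 0, e * (log2(e) - log2(pmax(m, floorv))), 0)
  trapz(grid, integrand)
}

#' Compare normal and log-normal cell-density models per voxel
#'
#' At every voxel with at least \code{config$min_samples_kl} valid samples
#' (and a non-degenerate spread), builds the Gaussian KDE of the samples
#' and computes the KL divergence from it to the fitted normal and fitted
#' log-normal densities, both renormalised on the KDE grid.  Both reports
#' share one evaluated mask.
#'
#' @param warped_density_maps list of \code{voxel_grid}s (cells/mm^3, NA
#'   where invalid).
#' @param normal_model,lognormal_model fitted \code{cell_density_model}s.
#' @param config a \code{pipeline_config}.
#' @param max_voxels optionally cap the number of evaluated voxels by
#'   seeded subsampling (useful for large grids).
#' @param subsample_seed seed used when \code{max_voxels} is finite.
#' @return list of two \code{model_fit_report}s (\code{normal},
#'   \code{lognormal}), each with \code{dkl_map}, \code{summary}
#'   (data.frame: mean, sd, n_voxels), \code{evaluated_mask} and the raw
#'   \code{dkl_values}; plus \code{winner} (+1 where the log-normal model
#'   loses less information, -1 where the normal does).
#' @export
evaluate_models <- function(warped_density_maps, normal_model,
                            lognormal_model, config = pipeline_config(),
                            max_voxels = Inf, subsample_seed = 1L) {
  dims <- dim(warped_density_maps[[1]]$values)
  ref <- warped_density_maps[[1]]
  nvox <- prod(dims)
  samp <- vapply(warped_density_maps, function(g) as.vector(g$values),
                 numeric(nvox))
  cnt <- rowSums(!is.na(samp))
  ok <- cnt >= config$min_samples_kl &
    !is.na(as.vector(normal_model$sigma2$values)) &
    !is.na(as.vector(lognormal_model$sigma2$values)) &
    as.vector(normal_model$sigma2$values) > 0 &
    as.vector(lognormal_model$sigma2$values) > 0
  idx <- which(ok)
  if (length(idx) == 0) stop("no evaluable voxels for model comparison")
  if (is.finite(max_voxels) && length(idx) > max_voxels) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(subsample_seed)
    idx <- sort(sample(idx, max_voxels))
  }
  mun <- as.vector(normal_model$mu$values)
  s2n <- as.vector(normal_model$sigma2$values)
  mul <- as.vector(lognormal_model$mu$values)
  s2l <- as.vector(lognormal_model$sigma2$values)
  dn <- rep(NA_real_, nvox); dl <- rep(NA_real_, nvox)
  for (q in idx) {
    x <- samp[q, ]
    x <- x[!is.na(x)]
    if (stats::sd(x) == 0) next
    # cell densities are positive: keep the evaluation grid strictly above
    # zero so the log-normal model density is positive everywhere on it
    h <- stats::sd(x) * length(x)^(-1 / 5)
    kde <- kde_estimate(x, from = max(min(x) - 4 * h, min(x) * 1e-3))
    g <- kde$grid
    dn[q] <- kl_divergence(kde$density,
                           stats::dnorm(g, mun[q], sqrt(s2n[q])), g)
    dl[q] <- kl_divergence(kde$density,
                           stats::dlnorm(g, mul[q], sqrt(s2l[q])), g)
  }
  eval_mask <- grid_like(ref, array(as.numeric(!is.na(dn)), dims))
  report <- function(d, kind) {
    v <- d[!is.na(d)]
    structure(list(kind = kind,
                   dkl_map = grid_like(ref, array(d, dims)),
                   summary = data.frame(model = kind, mean_dkl = mean(v),
                                        sd_dkl = stats::sd(v),
                                        n_voxels = length(v)),
                   evaluated_mask = eval_mask,
                   dkl_values = v),
              class = "model_fit_report")
  }
  winner <- array(NA_real_, dims)
  sel <- !is.na(dn)
  winner[sel] <- sign(dn[sel] - dl[sel])
  list(normal = report(dn, "normal"),
       lognormal = report(dl, "lognormal"),
       winner = grid_like(ref, winner))
}

#' @export
print.model_fit_report <- function(x, ...) {
  cat(sprintf("<model_fit_report> %s: D_KL %.4g +/- %.4g bits over %d voxels\n",
              x$kind, x$summary$mean_dkl, x$summary$sd_dkl,
              x$summary$n_voxels))
  invisible(x)
}

#' Present a patient already in reference space as an atlas record
#'
#' The degenerate (identity-chain) counterpart of
#' \code{\link{map_patient_to_reference}}, for cohorts generated directly on
#' a common grid (e.g. jitter-free phantoms used for parameter-recovery
#' studies).  With \code{slices = "annotated"} only the annotated slices
#' count as sampled and the density map is used as-is, so per-voxel samples
#' are actual draws rather than interpolated values.
#'
#' @param patient a \code{patient_dataset} (filled for
#'   \code{slices = "filled"}).
#' @param slices \code{"filled"} (validity slab, interpolated slices count
#'   as sampled) or \code{"annotated"}.
#' @return list with \code{lesion_maps}, \code{density} (NA where invalid)
#'   and \code{validity}, as consumed by \code{\link{build_atlas}}.
#' @export
patient_record <- function(patient, slices = c("filled", "annotated")) {
  slices <- match.arg(slices)
  if (slices == "filled") {
    if (is.null(patient$validity_mask))
      stop("patient has no validity mask; run fill_patient first")
    validity <- patient$validity_mask
  } else {
    v <- array(0, dim(patient$prostate_mask$values))
    v[, , patient$annotated_slices] <- 1
    validity <- grid_like(patient$prostate_mask, v)
  }
  density <- grid_like(patient$density,
                       ifelse(validity$values == 0, NA,
                              patient$density$values))
  list(lesion_maps = patient$lesion_maps, density = density,
       validity = validity)
}

#' Build the voxelised statistical atlas from warped cohort data
#'
#' @param warped list of per-patient records from
#'   \code{\link{map_patient_to_reference}} (or equivalent: fields
#'   \code{lesion_maps}, \code{density}, \code{validity}).
#' @param config a \code{pipeline_config}.
#' @param compare_models run the KDE/KL model comparison.
#' @param max_voxels passed to \code{\link{evaluate_models}}.
#' @return a \code{voxel_atlas}: list with \code{n}, \code{tumour},
#'   \code{density_normal}, \code{density_lognormal} and (optionally)
#'   \code{model_fit}.
#' @export
build_atlas <- function(warped, config = pipeline_config(),
                        compare_models = TRUE, max_voxels = Inf) {
  n_map <- sampling_frequency(lapply(warped, `[[`, "validity"))
  tumour <- tumour_probability(lapply(warped, `[[`, "lesion_maps"), n_map,
                               validity_masks = lapply(warped, `[[`, "validity"))
  dens <- lapply(warped, `[[`, "density")
  dn <- fit_density_model(dens, "normal", config)
  dl <- fit_density_model(dens, "lognormal", config)
  fit <- if (compare_models)
    evaluate_models(dens, dn, dl, config, max_voxels = max_voxels)
  structure(list(n = n_map, tumour = tumour, density_normal = dn,
                 density_lognormal = dl, model_fit = fit, config = config),
            class = "voxel_atlas")
}

#' @export
print.voxel_atlas <- function(x, ...) {
  cat(sprintf("<voxel_atlas> %d patients max per voxel\n", max(x$n$values)))
  print(x$tumour)
  if (!is.null(x$model_fit)) {
    print(x$model_fit$normal)
    print(x$model_fit$lognormal)
  }
  invisible(x)
}

#' Export atlas maps and summaries to a directory
#'
#' Writes the per-voxel maps as NIfTI volumes, the model-comparison
#' summary as CSV and the D_KL histogram data as CSV.
#'
#' @param atlas a \code{voxel_atlas}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wi <- function(g, name) write_image(g, file.path(dir, paste0(name, ".nii.gz")))
  wi(atlas$n, "sampling_frequency")
  wi(atlas$tumour$p, "tumour_probability")
  wi(atlas$tumour$sigma2, "tumour_sigma2")
  wi(atlas$tumour$cv, "tumour_cv")
  for (m in c("density_normal", "density_lognormal")) {
    wi(atlas[[m]]$mu, paste0(m, "_mu"))
    wi(atlas[[m]]$sigma2, paste0(m, "_sigma2"))
    wi(atlas[[m]]$cv, paste0(m, "_cv"))
  }
  if (!is.null(atlas$model_fit)) {
    wi(atlas$model_fit$normal$dkl_map, "dkl_normal")
    wi(atlas$model_fit$lognormal$dkl_map, "dkl_lognormal")
    utils::write.csv(rbind(atlas$model_fit$normal$summary,
                           atlas$model_fit$lognormal$summary),
                     file.path(dir, "model_fit_summary.csv"),
                     row.names = FALSE)
    hist_df <- rbind(
      data.frame(model = "normal", dkl = atlas$model_fit$normal$dkl_values),
      data.frame(model = "lognormal",
                 dkl = atlas$model_fit$lognormal$dkl_values))
    utils::write.csv(hist_df, file.path(dir, "dkl_histogram.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
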