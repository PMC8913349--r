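# Reference geometry: principal-moment alignment of cohort glands, the
# half-or-more consensus volume, and the spline urethra tube.

# Second-moment (covariance) matrix of voxel-centre positions inside a mask.
mask_moments <- function(mask) {
  w <- as.vector(mask$values)
  if (sum(w) == 0) stop("mask is empty")
  pts <- grid_points(mask)
  c0 <- colSums(pts * w) / sum(w)
  pc <- sweep(pts[w != 0, , drop = FALSE], 2, c0, "-")
  list(centroid = c0, cov = crossprod(pc) / sum(w))
}

# All 24 signed permutation matrices with determinant +1.
signed_perms_plus <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms)
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
      m <- matrix(0, 3, 3)
      m[cbind(1:3, p)] <- c(s1, s2, s3)
      if (abs(det(m) - 1) < 1e-9) out[[length(out) + 1]] <- m
    }
  out
}

# Rotation (rows = axes) that diagonalises `cov`, chosen among the signed
# permutations of its eigenvectors as the one nearest the imaging axes
# (maximal trace), so no axis is flipped and near-degenerate moments pick
# the assignment closest to the initial orientation.
principal_rotation <- function(cov) {
  e <- eigen(cov, symmetric = TRUE)
  V <- e$vectors                  # columns: principal axes
  if (det(V) < 0) V[, 3] <- -V[, 3]
  best <- NULL; best_tr <- -Inf
  for (P in signed_perms_plus()) {
    A <- P %*% t(V)               # candidate rotation, rows orthonormal
    tr <- sum(diag(A))
    if (tr > best_tr) { best_tr <- tr; best <- A }
  }
  best
}

#' Align a mask to its principal moments
#'
#' Translates the mask centroid to the origin and rotates so the principal
#' moments of the binary volume lie along the coordinate axes.  The
#' rotation is initialised from the imaging axes: among all assignments of
#' principal axes to coordinate axes with determinant +1, the one nearest
#' the initial orientation is chosen, so no axis is flipped.
#'
#' @param mask non-empty binary \code{voxel_grid}.
#' @param target optional \code{voxel_grid} geometry for the aligned output;
#'   by default a centred grid with the mask's smallest spacing, sized to
#'   contain the rotated gland.
#' @return list with \code{alignment} (fields \code{rotation},
#'   \code{translation}, \code{centre}: the map is
#'   \code{y = rotation \%*\% (x - centre)}) and \code{aligned}, the mask
#'   resampled (nearest) on the centred grid.
#' @export
principal_axis_align <- function(mask, target = NULL) {
  assert_binary(mask)
  mm <- mask_moments(mask)
  A <- principal_rotation(mm$cov)
  if (is.null(target)) {
    sp <- rep(min(mask$spacing), 3)
    w <- which(mask$values != 0, arr.ind = TRUE)
    pts <- index_to_world(mask, w)
    ali <- sweep(pts, 2, mm$centroid, "-") %*% t(A)
    half <- max(abs(ali)) + 2 * sp[1]
    n <- 2L * as.integer(ceiling(half / sp[1])) + 1L
    target <- voxel_grid(array(0, c(n, n, n)), spacing = sp,
                         origin = -(n - 1) / 2 * sp)
  }
  # sample the mask at x = centre + A^T y for each aligned voxel centre y
  pts <- grid_points(target) %*% A
  pts <- sweep(pts, 2, mm$centroid, "+")
  vals <- cpp_sample3(as.vector(mask$values), dim(mask$values),
                      world_to_index(mask, pts) - 1,
                      linear = FALSE, clamp = FALSE, fill = 0)
  list(alignment = list(rotation = A,
                        translation = as.vector(-A %*% mm$centroid),
                        centre = mm$centroid),
       aligned = grid_like(target, array(vals, dim(target$values))))
}

#' Consensus volume of aligned binary masks
#'
#' A voxel belongs to the consensus iff it is covered by at least
#' \code{fraction} of the masks; exact attainment counts as inside
#' ("half or more" with the default fraction 0.5).
#'
#' @param masks list of two or more aligned binary \code{voxel_grid}s.
#' @param fraction required coverage fraction in (0, 1].
#' @return a binary \code{voxel_grid}.
#' @export
consensus_volume <- function(masks, fraction = 0.5) {
  if (length(masks) < 2) stop("consensus requires at least two masks")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  for (m in masks) assert_binary(m)
  do.call(assert_aligned, c(masks, list(what = "consensus masks")))
  counts <- Reduce(`+`, lapply(masks, function(m) m$values))
  thr <- fraction * length(masks)
  grid_like(masks[[1]], (counts >= thr - 1e-9) * 1)
}

#' Binary tube around a spline through centreline points
#'
#' Fits an interpolating cubic spline (chord-length parameterised) through
#' the centreline points, rasterises it densely onto the template grid and
#' thresholds the Euclidean distance to the rasterised curve, giving a
#' connected tube of the requested radius (the study default is 1.5 mm).
#'
#' @param centreline n x 3 matrix of mm points (n >= 3) ordered along the
#'   curve.
#' @param radius tube radius, mm.
#' @param template \code{voxel_grid} defining the output geometry.
#' @return a binary \code{voxel_grid}.
#' @export
urethra_tube <- function(centreline, radius = 1.5, template) {
  centreline <- as.matrix(centreline)
  if (nrow(centreline) < 3) stop("centreline needs at least 3 points")
  if (radius <= 0) stop("radius must be positive")
  seg <- sqrt(rowSums(diff(centreline)^2))
  if (any(seg < 1e-9) || sum(seg) < 1e-6)
    stop("degenerate centreline: coincident points")
  t0 <- c(0, cumsum(seg))
  step <- min(template$spacing) / 4
  tt <- seq(0, t0[length(t0)], by = step)
  pts <- sapply(1:3, function(a)
    stats::spline(t0, centreline[, a], xout = tt, method = "natural")$y)
  idx <- round(world_to_index(template, pts))
  d <- dim(template$values)
  keep <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) stop("centreline lies outside the template grid")
  seedv <- array(0L, d)
  seedv[idx] <- 1L
  dist <- sqrt(cpp_edt_sq(as.integer(seedv), d, template$spacing))
  grid_like(template, array((dist <= radius) * 1, d))
}

#' Build the cohort reference geometry
#'
#' The reference prostate is the consensus of the principal-moment-aligned
#' cohort prostate masks on a common centred grid.  The reference
#' peripheral zone is the consensus of each patient's PZ after the
#' whole-gland registration stage (anisotropic similarity plus, optionally,
#' the distance-preserving deformable stage), intersected with the
#' reference prostate.  The reference urethra is a spline tube through the
#' per-slice centroids of the mean warped urethra mask.
#'
#' @param cohort list of \code{patient_dataset}s (filled, see
#'   \code{\link{fill_patient}}).
#' @param config a \code{pipeline_config}.
#' @param deformable run the deformable whole-gland stage before combining
#'   PZ masks (TRUE, the full procedure) or use the similarity stage only.
#' @return a \code{reference_geometry}: list with \code{prostate},
#'   \code{pz}, \code{urethra} (binary \code{voxel_grid}s on the reference
#'   grid), per-patient \code{alignments} and the \code{config} used.
#' @export
build_reference <- function(cohort, config = pipeline_config(),
                            deformable = TRUE) {
  if (length(cohort) == 0) stop("cohort is empty")
  sp <- rep(config$iso_spacing, 3)
  aligns <- lapply(cohort, function(p) {
    mm <- mask_moments(p$prostate_mask)
    list(rotation = principal_rotation(mm$cov), centre = mm$centroid)
  })
  half <- 0
  for (i in seq_along(cohort)) {
    m <- cohort[[i]]$prostate_mask
    w <- which(m$values != 0, arr.ind = TRUE)
    pts <- sweep(index_to_world(m, w), 2, aligns[[i]]$centre, "-") %*%
      t(aligns[[i]]$rotation)
    half <- max(half, max(abs(pts)))
  }
  n <- 2L * as.integer(ceiling((half + 3 * sp[1]) / sp[1])) + 1L
  refgrid <- voxel_grid(array(0, c(n, n, n)), spacing = sp,
                        origin = -(n - 1) / 2 * sp)
  aligned <- lapply(seq_along(cohort), function(i)
    principal_axis_align(cohort[[i]]$prostate_mask, target = refgrid)$aligned)
  prostate <- consensus_volume(aligned, config$consensus_fraction)
  if (sum(prostate$values) == 0)
    stop("empty consensus prostate: pathological cohort")

  # whole-gland stage per patient, then combine PZ and urethra
  pz_w <- vector("list", length(cohort))
  ur_mean <- array(0, dim(refgrid$values))
  chains <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    sim <- similarity_register(p$prostate_mask, prostate)
    fields <- list()
    if (deformable) {
      mov <- apply_chain_to_grid(transform_chain(sim), p$prostate_mask,
                                 prostate, mode = "nearest", fill = 0)
      fields <- list(distance_preserving_register(mov, prostate,
                                                  config = config))
    }
    chains[[i]] <- transform_chain(sim, fields)
    pz_w[[i]] <- apply_chain_to_grid(chains[[i]], p$pz_mask, prostate,
                                     mode = "nearest", fill = 0)
    urw <- apply_chain_to_grid(chains[[i]], p$urethra_mask, prostate,
                               mode = "nearest", fill = 0)
    ur_mean <- ur_mean + urw$values / length(cohort)
  }
  pz <- consensus_volume(pz_w, config$consensus_fraction)
  pz <- grid_like(pz, pz$values * prostate$values)
  if (sum(pz$values) == 0)
    stop("empty consensus PZ: pathological cohort")

  urethra <- reference_urethra_from_mean(ur_mean, refgrid, config)
  structure(list(prostate = prostate, pz = pz, urethra = urethra,
                 grid = refgrid, alignments = aligns, chains = chains,
                 config = config),
            class = "reference_geometry")
}

# Per-slice centroids of a mean urethra occupancy map -> spline tube.
reference_urethra_from_mean <- function(ur_mean, refgrid, config) {
  d <- dim(ur_mean)
  pts <- NULL
  for (k in seq_len(d[3])) {
    sl <- ur_mean[, , k]
    if (sum(sl) < 1e-6) next
    ci <- sum(row(sl) * sl) / sum(sl)
    cj <- sum(col(sl) * sl) / sum(sl)
    pts <- rbind(pts, c(ci, cj, k))
  }
  if (is.null(pts) || nrow(pts) < 3)
    stop("too few urethra slices to fit a centreline")
  world <- index_to_world(refgrid, pts)
  urethra_tube(world, radius = config$urethra_radius, template = refgrid)
}

#' Write / read a reference geometry directory
#'
#' Volumes (\code{reference_prostate}, \code{reference_pz},
#' \code{reference_urethra}) plus a JSON file recording the cohort size,
#' consensus fraction and per-patient rigid alignments.
#'
#' @param reference a \code{reference_geometry}.
#' @param dir directory path.
#' @return \code{write_reference}: \code{dir} invisibly;
#'   \code{read_reference}: a \code{reference_geometry} (without the
#'   per-patient transform chains).
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(reference$prostate, file.path(dir, "reference_prostate.nii.gz"))
  write_image(reference$pz, file.path(dir, "reference_pz.nii.gz"))
  write_image(reference$urethra, file.path(dir, "reference_urethra.nii.gz"))
  meta <- list(
    n_patients = length(reference$alignments),
    consensus_fraction = reference$config$consensus_fraction,
    iso_spacing = reference$config$iso_spacing,
    alignments = lapply(reference$alignments, function(a)
      list(rotation = as.vector(a$rotation), centre = a$centre)))
  jsonlite::write_json(meta, file.path(dir, "reference.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "reference.json"),
                              simplifyVector = TRUE)
  prostate <- read_image(file.path(dir, "reference_prostate.nii.gz"))
  structure(list(
    prostate = prostate,
    pz = read_image(file.path(dir, "reference_pz.nii.gz")),
    urethra = read_image(file.path(dir, "reference_urethra.nii.gz")),
    grid = grid_like(prostate, prostate$values * 0),
    alignments = lapply(seq_len(meta$n_patients), function(i)
      list(rotation = matrix(meta$alignments$rotation[[i]], 3, 3),
           centre = meta$alignments$centre[[i]])),
    chains = NULL,
    config = pipeline_config(iso_spacing = meta$iso_spacing,
                             consensus_fraction = meta$consensus_fraction)),
    class = "reference_geometry")
}

#' @export
print.reference_geometry <- function(x, ...) {
  cat(sprintf("<reference_geometry> %s-voxel grid at %.3g mm; prostate %d, PZ %d, urethra %d voxels\n",
              paste(dim(x$grid$values), collapse = "x"), x$grid$spacing[1],
              sum(x$prostate$values), sum(x$pz$values), sum(x$urethra$values)))
  invisible(x)
}
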