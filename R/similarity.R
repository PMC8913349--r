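# Anisotropic similarity transform: per-axis scaling about the moving
# centroid (along the moving principal axes), then rotation, then
# translation.  Forward map (moving -> fixed space):
#   y = R %*% (V diag(s) V^T) %*% (x - centre) + centre + translation

new_similarity3 <- function(centre, axes, scales, rotation, translation) {
  structure(list(centre = centre, axes = axes, scales = scales,
                 rotation = rotation, translation = translation),
            class = "similarity3")
}

#' Identity similarity transform
#' @return a \code{similarity3}.
#' @export
similarity_identity <- function() {
  new_similarity3(c(0, 0, 0), diag(3), c(1, 1, 1), diag(3), c(0, 0, 0))
}

#' @export
print.similarity3 <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<similarity3> scales (%s), rotation %.2f deg, translation (%s) mm\n",
              paste(signif(x$scales, 4), collapse = ", "), ang,
              paste(signif(x$translation, 3), collapse = ", ")))
  invisible(x)
}

similarity_forward_points <- function(tr, pts) {
  S <- tr$axes %*% diag(tr$scales) %*% t(tr$axes)
  out <- sweep(pts, 2, tr$centre, "-") %*% t(tr$rotation %*% S)
  sweep(out, 2, tr$centre + tr$translation, "+")
}

similarity_inverse_points <- function(tr, pts) {
  Sinv <- tr$axes %*% diag(1 / tr$scales) %*% t(tr$axes)
  out <- sweep(pts, 2, tr$centre + tr$translation, "-") %*%
    t(Sinv %*% t(tr$rotation))
  sweep(out, 2, tr$centre, "+")
}

#' Anisotropic similarity registration of two binary masks
#'
#' Computes translation, rotation and per-axis scales aligning the moving
#' mask to the fixed mask by moment matching: centroids give the
#' translation, principal axes (sign-matched to the imaging axes) give the
#' rotation, and the ratios of second moments along matched axes give the
#' scales.  Optionally the nine parameters are refined by minimising the
#' mean squared difference of the two normalised distance maps.  If the
#' moment-matched transform worsens the Dice overlap it is replaced by the
#' identity.
#'
#' @param moving_mask,fixed_mask non-empty binary \code{voxel_grid}s.
#' @param refine logical; run Nelder-Mead refinement of the moment-matched
#'   initialisation.
#' @return a \code{similarity3} mapping moving to fixed space.
#' @export
similarity_register <- function(moving_mask, fixed_mask, refine = FALSE) {
  assert_binary(moving_mask, "moving_mask")
  assert_binary(fixed_mask, "fixed_mask")
  mm <- mask_moments(moving_mask)
  mf <- mask_moments(fixed_mask)
  Am <- principal_rotation(mm$cov)   # rows = moving axes
  Af <- principal_rotation(mf$cov)
  var_m <- diag(Am %*% mm$cov %*% t(Am))
  var_f <- diag(Af %*% mf$cov %*% t(Af))
  scales <- sqrt(var_f / var_m)
  tr <- new_similarity3(centre = mm$centroid, axes = t(Am), scales = scales,
                        rotation = t(Af) %*% Am,
                        translation = mf$centroid - mm$centroid)
  if (refine) tr <- refine_similarity(tr, moving_mask, fixed_mask)
  # guard: never return a transform worse than no transform at all
  warped <- warp_mask_by_similarity(moving_mask, tr, fixed_mask)
  plain <- resample_to_grid(moving_mask, fixed_mask, mode = "nearest")
  if (dice(warped, fixed_mask) < dice(plain, fixed_mask) - 0.005) {
    warning("moment-matched similarity transform rejected (Dice decreased); using identity")
    tr <- similarity_identity()
  }
  tr
}

warp_mask_by_similarity <- function(mask, tr, target) {
  pts <- similarity_inverse_points(tr, grid_points(target))
  vals <- cpp_sample3(as.vector(mask$values), dim(mask$values),
                      world_to_index(mask, pts) - 1,
                      linear = FALSE, clamp = FALSE, fill = 0)
  grid_like(target, array(vals, dim(target$values)))
}

refine_similarity <- function(tr, moving_mask, fixed_mask) {
  ndm <- normalised_distance_map(moving_mask)$values
  ndf <- normalised_distance_map(fixed_mask)$values
  pts <- grid_points(fixed_mask)
  keep <- abs(as.vector(ndf$values)) < 0.999
  pts <- pts[keep, , drop = FALSE]
  target <- as.vector(ndf$values)[keep]
  rot_xyz <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  cost <- function(par) {
    tt <- tr
    tt$translation <- tr$translation + par[1:3]
    tt$rotation <- rot_xyz(par[4:6]) %*% tr$rotation
    tt$scales <- tr$scales * exp(par[7:9])
    p <- similarity_inverse_points(tt, pts)
    v <- cpp_sample3(as.vector(ndm$values), dim(ndm$values),
                     world_to_index(ndm, p) - 1,
                     linear = TRUE, clamp = TRUE, fill = -1)
    mean((v - target)^2)
  }
  opt <- stats::optim(rep(0, 9), cost, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-6))
  tr$translation <- tr$translation + opt$par[1:3]
  tr$rotation <- rot_xyz(opt$par[4:6]) %*% tr$rotation
  tr$scales <- tr$scales * exp(opt$par[7:9])
  tr
}
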