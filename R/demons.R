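# Distance-preserving deformable registration: log-domain symmetric-forces
# demons driven by the normalised distance maps of two binary shapes.
# Matching equal normalised-distance shells (rather than just the boundary)
# is what preserves each point's relative distance to the volume boundary.

new_displacement_field <- function(d, spacing, origin, direction = diag(3)) {
  structure(list(d = d, spacing = spacing, origin = origin,
                 direction = direction),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$d[, , , 1]^2 + x$d[, , , 2]^2 + x$d[, , , 3]^2)
  cat(sprintf("<displacement_field> %s voxels at %.3g mm; |d| max %.3g mm, mean %.3g mm\n",
              paste(dim(x$d)[1:3], collapse = "x"), x$spacing[1],
              max(mag), mean(mag)))
  invisible(x)
}

# Sample the mm displacement at arbitrary mm points (n x 3), edge-clamped.
sample_displacement <- function(field, pts) {
  dims <- dim(field$d)[1:3]
  g <- voxel_grid(array(0, dims), field$spacing, field$origin, field$direction)
  idx <- world_to_index(g, pts) - 1
  vapply(1:3, function(a)
    cpp_sample3(as.vector(field$d[, , , a]), dims, idx,
                linear = TRUE, clamp = TRUE, fill = 0),
    numeric(nrow(pts)))
}

#' Jacobian determinant of a displacement field
#'
#' Determinant of the Jacobian of the mapping x + d(x), computed by central
#' differences; positive values indicate a locally orientation-preserving
#' (fold-free) deformation.
#'
#' @param field a \code{displacement_field}.
#' @return a 3D array of determinants.
#' @export
jacobian_determinant <- function(field) {
  dims <- dim(field$d)[1:3]
  J11 <- J12 <- J13 <- J21 <- J22 <- J23 <- J31 <- J32 <- J33 <- NULL
  for (a in 1:3) {
    g <- cpp_grad3(as.vector(field$d[, , , a]), dims, field$spacing)
    assign(paste0("J", a, "1"), array(g[[1]], dims))
    assign(paste0("J", a, "2"), array(g[[2]], dims))
    assign(paste0("J", a, "3"), array(g[[3]], dims))
  }
  (1 + J11) * ((1 + J22) * (1 + J33) - J23 * J32) -
    J12 * (J21 * (1 + J33) - J23 * J31) +
    J13 * (J21 * J32 - (1 + J22) * J31)
}

# Build one pyramid level of an image: Gaussian pre-smoothing at half the
# decimation factor, then linear resampling onto the level grid.
pyramid_level <- function(grid, factor, level_grid) {
  vals <- grid$values
  if (factor > 1)
    vals <- array(cpp_gauss3(as.vector(vals), dim(vals), rep(factor / 2, 3)),
                  dim(vals))
  resample_to_grid(grid_like(grid, vals), level_grid, mode = "linear",
                   fill = -1)
}

make_level_grid <- function(grid, factor) {
  d <- dim(grid$values)
  nd <- pmax(2L, as.integer(floor((d - 1) / factor)) + 1L)
  voxel_grid(array(0, nd), spacing = grid$spacing * factor,
             origin = grid$origin, direction = grid$direction)
}

#' Distance-preserving deformable registration
#'
#' Registers two binary shapes with a log-domain, symmetric-forces
#' demons algorithm driven by their normalised distance maps, so that
#' points at equal relative depth correspond: the update at each voxel is
#' the classic demons force computed from both images' gradients, smoothed
#' (fluid-like), accumulated into a stationary velocity field that is
#' itself smoothed (diffusion-like) and exponentiated by scaling and
#' squaring into a diffeomorphic displacement.  With
#' \code{signal = "mask"} the binary masks themselves drive the
#' registration (a boundary-only control with no interior signal).
#'
#' If \code{pin_boundary_of} is given, velocity updates are multiplied by a
#' smooth weight that is zero within one voxel of that mask's boundary and
#' ramps to one over \code{pin_band} voxels, so a later registration stage
#' cannot distort the boundary match achieved by an earlier one.
#'
#' @param moving_mask,fixed_mask aligned binary \code{voxel_grid}s on an
#'   isotropic grid.
#' @param pin_boundary_of optional binary \code{voxel_grid} whose boundary
#'   must not move.
#' @param config a \code{pipeline_config} (demons parameters are read from
#'   \code{config$demons}).
#' @param signal \code{"distance"} (normalised distance maps, the default)
#'   or \code{"mask"}.
#' @return a \code{displacement_field} d (mm) on the fixed grid such that
#'   resampling \code{moving(x + d(x))} aligns the moving shape with the
#'   fixed one.
#' @export
distance_preserving_register <- function(moving_mask, fixed_mask,
                                         pin_boundary_of = NULL,
                                         config = pipeline_config(),
                                         signal = c("distance", "mask")) {
  signal <- match.arg(signal)
  assert_aligned(moving_mask, fixed_mask, what = "registration masks")
  if (diff(range(moving_mask$spacing)) > 1e-3 * min(moving_mask$spacing))
    stop("deformable registration requires an isotropic grid; resample first")
  assert_binary(moving_mask, "moving_mask")
  assert_binary(fixed_mask, "fixed_mask")
  if (!is.null(pin_boundary_of))
    assert_aligned(moving_mask, pin_boundary_of, what = "pin mask and images")

  Fimg <- if (signal == "distance")
    normalised_distance_map(fixed_mask)$values else
      grid_like(fixed_mask, fixed_mask$values * 2 - 1)
  Mimg <- if (signal == "distance")
    normalised_distance_map(moving_mask)$values else
      grid_like(moving_mask, moving_mask$values * 2 - 1)

  pin_w <- NULL
  if (!is.null(pin_boundary_of)) {
    nd <- normalised_distance_map(pin_boundary_of)
    bdist <- abs(nd$values$values) * nd$max_depth     # mm to pin boundary
    sp0 <- moving_mask$spacing[1]
    band <- config$demons$pin_band
    pin_w <- grid_like(moving_mask,
                       array(pmin(1, pmax(0, (bdist / sp0 - 1) / band)),
                             dim(moving_mask$values)))
  }

  dp <- config$demons
  factors <- 2^((dp$levels - 1):0)
  v <- NULL
  prev_grid <- NULL
  for (li in seq_along(factors)) {
    f <- factors[li]
    lg <- make_level_grid(Fimg, f)
    Fl <- pyramid_level(Fimg, f, lg)$values
    Ml <- pyramid_level(Mimg, f, lg)$values
    wl <- if (!is.null(pin_w))
      pmin(1, pmax(0, resample_to_grid(pin_w, lg, "linear", fill = 1)$values))
    dims <- dim(Fl)
    if (is.null(v)) {
      v <- list(array(0, dims), array(0, dims), array(0, dims))
    } else {
      scale <- prev_grid$spacing[1] / lg$spacing[1]
      v <- lapply(v, function(comp)
        resample_to_grid(grid_like(prev_grid, comp), lg, "linear",
                         fill = 0)$values * scale)
    }
    v <- demons_level(Fl, Ml, v, dims, wl,
                      iters = dp$iterations[li],
                      sigma_update = dp$sigma_update,
                      sigma_total = dp$sigma_total)
    prev_grid <- lg
  }
  dvox <- exp_velocity(v, dim(Fimg$values))
  d <- array(0, c(dim(Fimg$values), 3))
  for (a in 1:3) d[, , , a] <- dvox[[a]] * Fimg$spacing[a]
  new_displacement_field(d, Fimg$spacing, Fimg$origin, Fimg$direction)
}

exp_velocity <- function(v, dims) {
  mx <- max(abs(unlist(lapply(v, range))))
  nsteps <- max(2L, min(10L, as.integer(ceiling(log2(max(mx, 1e-9) / 0.25)))))
  r <- cpp_exp_field(as.vector(v[[1]]), as.vector(v[[2]]), as.vector(v[[3]]),
                     dims, nsteps)
  lapply(r, array, dim = dims)
}

demons_level <- function(Fl, Ml, v, dims, wl, iters, sigma_update,
                         sigma_total) {
  gF <- cpp_grad3(as.vector(Fl), dims, c(1, 1, 1))
  best <- Inf; best_v <- v; best_iter <- 0L
  for (it in seq_len(iters)) {
    d <- exp_velocity(v, dims)
    Mw <- array(cpp_warp3(as.vector(Ml), dims, as.vector(d[[1]]),
                          as.vector(d[[2]]), as.vector(d[[3]]),
                          linear = TRUE, clamp = TRUE, fill = -1), dims)
    diffv <- Fl - Mw
    gM <- cpp_grad3(as.vector(Mw), dims, c(1, 1, 1))
    gx <- (gF[[1]] + gM[[1]]) / 2
    gy <- (gF[[2]] + gM[[2]]) / 2
    gz <- (gF[[3]] + gM[[3]]) / 2
    dv <- as.vector(diffv)
    den <- gx^2 + gy^2 + gz^2 + dv^2
    sel <- den > 1e-12
    step <- ifelse(sel, dv / den, 0)
    ux <- array(step * gx, dims); uy <- array(step * gy, dims)
    uz <- array(step * gz, dims)
    nrm <- sqrt(ux^2 + uy^2 + uz^2)
    cap <- array(pmin(1, 2 / pmax(nrm, 1e-12)), dims)
    ux <- ux * cap; uy <- uy * cap; uz <- uz * cap
    if (sigma_update > 0) {
      ux <- array(cpp_gauss3(as.vector(ux), dims, rep(sigma_update, 3)), dims)
      uy <- array(cpp_gauss3(as.vector(uy), dims, rep(sigma_update, 3)), dims)
      uz <- array(cpp_gauss3(as.vector(uz), dims, rep(sigma_update, 3)), dims)
    }
    if (!is.null(wl)) { ux <- ux * wl; uy <- uy * wl; uz <- uz * wl }
    v <- list(v[[1]] + ux, v[[2]] + uy, v[[3]] + uz)
    if (sigma_total > 0)
      v <- lapply(v, function(comp)
        array(cpp_gauss3(as.vector(comp), dims, rep(sigma_total, 3)), dims))
    if (!is.null(wl)) v <- lapply(v, function(comp) comp * wl)
    mse <- mean(diffv^2)
    if (mse < best * (1 - 1e-4)) {
      best <- mse; best_v <- v; best_iter <- it
    } else if (it - best_iter >= 10L) {
      if (mse > 1.2 * best + 1e-6) {
        warning("demons update norm stopped decreasing; returning best-so-far field")
        v <- best_v
      }
      break
    }
  }
  v
}
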