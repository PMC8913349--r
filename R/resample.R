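#' Resample a grid onto the geometry of another grid
#'
#' Values are sampled at the target voxel centres; positions outside the
#' source extent receive \code{fill}.  Nearest-neighbour mode preserves
#' binary masks, linear mode keeps values inside the convex hull of the
#' source values.
#'
#' @param grid source \code{voxel_grid}.
#' @param target \code{voxel_grid} (its values are ignored) defining the
#'   output geometry.
#' @param mode \code{"nearest"} or \code{"linear"}.
#' @param fill value assigned outside the source extent.
#' @return a \code{voxel_grid} on the target geometry.
#' @export
resample_to_grid <- function(grid, target, mode = c("linear", "nearest"),
                             fill = 0) {
  mode <- match.arg(mode)
  coords <- world_to_index(grid, grid_points(target)) - 1
  vals <- cpp_sample3(as.vector(grid$values), dim(grid$values), coords,
                      linear = mode == "linear", clamp = FALSE, fill = fill)
  grid_like(target, array(vals, dim(target$values)))
}

#' Resample a grid to isotropic spacing
#'
#' The physical extent (first to last voxel centre) is preserved to within
#' one voxel; the origin is unchanged.  Use \code{mode = "nearest"} for
#' binary masks and \code{mode = "linear"} for density or probabilistic
#' maps (the study resolution for atlas construction is 0.8 mm isotropic).
#'
#' @param grid source \code{voxel_grid}.
#' @param spacing target isotropic voxel size, mm (default 0.8).
#' @param mode interpolation mode.
#' @param fill value assigned outside the source extent.
#' @return a \code{voxel_grid} with \code{spacing} on all axes.
#' @export
resample_isotropic <- function(grid, spacing = 0.8,
                               mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("spacing must be a single positive value (mm)")
  d <- dim(grid$values)
  extent <- (d - 1) * grid$spacing
  # floor keeps the new extent inside the old one, so border voxels never
  # sample outside the source
  nd <- pmax(1L, as.integer(floor(extent / spacing + 1e-9)) + 1L)
  target <- voxel_grid(array(0, nd), spacing = rep(spacing, 3),
                       origin = grid$origin, direction = grid$direction)
  resample_to_grid(grid, target, mode = mode, fill = fill)
}
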