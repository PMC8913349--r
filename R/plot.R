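#' Display an axial slice of a voxel grid
#'
#' Base-graphics heatmap of slice \code{k} with physical (mm) axes, with
#' optional mask contours overlaid.
#'
#' @param grid a \code{voxel_grid}.
#' @param k axial slice index (default: middle slice).
#' @param masks optional named list of binary \code{voxel_grid}s drawn as
#'   contours.
#' @param col colour palette.
#' @param ... passed to \code{graphics::image}.
#' @return invisibly, the slice matrix.
#' @export
plot_slice <- function(grid, k = NULL, masks = NULL,
                       col = grDevices::hcl.colors(64, "viridis"), ...) {
  d <- dim(grid$values)
  if (is.null(k)) k <- (d[3] + 1) %/% 2
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  sl <- grid$values[, , k]
  graphics::image(xs, ys, sl, col = col, xlab = "x (mm)", ylab = "y (mm)",
                  useRaster = TRUE, ...)
  if (!is.null(masks))
    for (i in seq_along(masks))
      graphics::contour(xs, ys, masks[[i]]$values[, , k], levels = 0.5,
                        add = TRUE, drawlabels = FALSE, col = "white",
                        lty = i)
  invisible(sl)
}
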