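#' Normalised distance map of a binary mask
#'
#' Signed Euclidean distance to the mask boundary, positive inside,
#' divided by the maximal interior depth so the deepest point carries 1 and
#' the boundary 0 (within one voxel); exterior values are divided by the
#' same factor and clipped at -1.  Equal values then define corresponding
#' "shells" across shapes of different size, which is what makes the map a
#' suitable registration signal for preserving relative boundary distance.
#'
#' @param mask non-empty, non-full binary \code{voxel_grid}.
#' @return a \code{normalised_distance_map}: list with \code{values}
#'   (\code{voxel_grid} in [-1, 1]), \code{max_depth} (mm) and
#'   \code{source_mask}.
#' @export
normalised_distance_map <- function(mask) {
  assert_binary(mask)
  m <- mask$values
  if (sum(m) == 0) stop("mask is empty: no boundary to measure from")
  if (all(m == 1)) stop("mask fills the grid: no boundary to measure from")
  d <- dim(m)
  # half-voxel offset places the zero level on the mask interface rather
  # than at the first voxel centre on the other side
  half <- 0.5 * min(mask$spacing)
  depth <- sqrt(cpp_edt_sq(as.integer(m == 0), d, mask$spacing)) - half
  dist_out <- sqrt(cpp_edt_sq(as.integer(m != 0), d, mask$spacing)) - half
  dmax <- max(depth[as.vector(m) != 0])
  nd <- ifelse(as.vector(m) != 0, depth / dmax, pmax(-1, -dist_out / dmax))
  structure(list(values = grid_like(mask, array(nd, d)),
                 max_depth = dmax, source_mask = mask),
            class = "normalised_distance_map")
}

#' @export
print.normalised_distance_map <- function(x, ...) {
  cat(sprintf("<normalised_distance_map> max interior depth %.3g mm\n",
              x$max_depth))
  invisible(x)
}
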