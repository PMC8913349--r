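#' Create a voxel grid
#'
#' The universal spatial carrier of the package: a 3D scalar field together
#' with the metadata needed to place every voxel in physical (mm) space.
#' Voxel \code{(i, j, k)} (1-based, R convention) has its centre at
#' \code{origin + direction \%*\% (spacing * (c(i, j, k) - 1))}.  Axial slices
#' are indexed along the third axis, so slice \code{k} sits at
#' \code{z = origin[3] + (k - 1) * spacing[3]} when \code{direction} is the
#' identity.
#'
#' @param values numeric 3D array.
#' @param spacing per-axis voxel size in mm (strictly positive, length 3).
#' @param origin physical position of the centre of voxel (1,1,1), mm.
#' @param direction 3x3 orthonormal direction matrix with determinant +1.
#' @return an object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("voxel_grid values must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6 ||
      abs(det(direction) - 1) > 1e-6)
    stop("direction must be a 3x3 orthonormal matrix with determinant +1")
  structure(list(values = values, spacing = spacing, origin = origin,
                 direction = direction),
            class = "voxel_grid")
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' @export
as.array.voxel_grid <- function(x, ...) x$values

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin  (%s) mm\n", paste(signif(x$origin, 4), collapse = ", ")))
  if (max(abs(x$direction - diag(3))) > 1e-9)
    cat("  direction: non-identity\n")
  rng <- range(x$values)
  cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Replace the values of a grid, keeping its geometry
#'
#' @param grid a \code{voxel_grid} providing spacing/origin/direction.
#' @param values replacement array with the same dimensions.
#' @return a \code{voxel_grid}.
#' @export
grid_like <- function(grid, values) {
  if (is.null(dim(values)) && length(values) == length(grid$values))
    dim(values) <- dim(grid$values)   # pmin/pmax and friends drop dims
  values <- as.array(values)
  if (!all(dim(values) == dim(grid$values)))
    stop("replacement values must match the grid dimensions")
  voxel_grid(values, grid$spacing, grid$origin, grid$direction)
}

#' Test whether two grids share the same sampling geometry
#'
#' Two grids are aligned iff shape, spacing, origin and direction all agree
#' (metadata within a small absolute tolerance).  Voxelwise aggregation is
#' only defined between aligned grids.
#'
#' @param a,b \code{voxel_grid} objects.
#' @param tol metadata tolerance in mm.
#' @return logical.
#' @export
grids_aligned <- function(a, b, tol = 1e-4) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

assert_aligned <- function(..., what = "grids") {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!grids_aligned(gs[[1]], gs[[i]]))
      stop(sprintf("%s are not aligned (shape/spacing/origin/direction mismatch)",
                   what))
  invisible(TRUE)
}

is_binary_grid <- function(grid) {
  all(grid$values %in% c(0, 1))
}

assert_binary <- function(grid, what = "mask") {
  if (!is_binary_grid(grid))
    stop(sprintf("%s must be binary ({0,1} values)", what))
  invisible(TRUE)
}

#' Physical coordinates of every voxel centre
#'
#' @param grid a \code{voxel_grid}.
#' @return an n-voxel x 3 matrix of mm coordinates, in array (column-major)
#'   order.
#' @export
grid_points <- function(grid) {
  d <- dim(grid$values)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  sweep(idx %*% (t(grid$direction) * grid$spacing), 2, grid$origin, "+")
}

# world (mm) -> continuous 1-based voxel index
world_to_index <- function(grid, pts) {
  pts <- sweep(pts, 2, grid$origin, "-") %*% grid$direction
  sweep(pts, 2, grid$spacing, "/") + 1
}

index_to_world <- function(grid, idx) {
  sweep((idx - 1) %*% (t(grid$direction) * grid$spacing), 2, grid$origin, "+")
}

#' Dice overlap coefficient between two binary grids
#'
#' @param a,b aligned binary \code{voxel_grid}s.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  assert_aligned(a, b)
  sa <- sum(a$values); sb <- sum(b$values)
  if (sa + sb == 0) return(1)
  2 * sum(a$values * b$values) / (sa + sb)
}

#' Centroid of a binary mask in physical coordinates
#'
#' @param mask binary \code{voxel_grid}.
#' @return length-3 mm coordinates of the mean voxel-centre position.
#' @export
mask_centroid <- function(mask) {
  w <- as.vector(mask$values)
  if (sum(w) == 0) stop("mask is empty")
  colSums(grid_points(mask) * w) / sum(w)
}
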