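#' Sparse axial slice stack
#'
#' Wraps a grid whose payload (contour, density or graded lesion) is defined
#' only on a set of annotated axial slices, with unannotated slices in
#' between to be filled.  Gaps of exactly one slice between consecutive
#' annotated slices match the study geometry (5 mm sectioning on 2.5 mm
#' slices); wider gaps are rejected rather than extrapolated.
#'
#' @param grid a \code{voxel_grid}; values must be zero outside the
#'   annotated slices.
#' @param annotated_slices strictly increasing 1-based slice indices.
#' @param payload_kind \code{"contour"}, \code{"density"} or
#'   \code{"lesion_grade"}.
#' @return a \code{sparse_slice_stack}.
#' @export
sparse_slice_stack <- function(grid, annotated_slices,
                               payload_kind = c("contour", "density",
                                                "lesion_grade")) {
  payload_kind <- match.arg(payload_kind)
  s <- as.integer(annotated_slices)
  nk <- dim(grid$values)[3]
  if (length(s) == 0) stop("annotated_slices must be non-empty")
  if (any(diff(s) <= 0)) stop("annotated_slices must be strictly increasing")
  if (s[1] < 1 || s[length(s)] > nk) stop("annotated slice index out of range")
  if (length(s) > 1 && any(diff(s) > 2))
    stop("gaps wider than one slice between annotated slices are not supported")
  if (payload_kind %in% c("contour", "lesion_grade")) {
    on_ann <- grid$values[, , s, drop = FALSE]
    if (!all(on_ann %in% c(0, 1)))
      stop(sprintf("%s payload must be binary on annotated slices",
                   payload_kind))
  }
  if (payload_kind == "density" && any(grid$values < 0))
    stop("density payload must be non-negative")
  off <- setdiff(seq_len(nk), s)
  if (length(off) && any(grid$values[, , off] != 0))
    stop("payload must be zero outside annotated slices before interpolation")
  structure(list(grid = grid, annotated_slices = s,
                 payload_kind = payload_kind),
            class = "sparse_slice_stack")
}

# 2D signed distance (mm) of a binary slice: positive inside, negative
# outside, measured between voxel centres.
signed_dist_slice <- function(mat, spacing2) {
  dims <- c(dim(mat), 1L)
  sp <- c(spacing2, max(spacing2))
  if (all(mat == 0)) return(matrix(-Inf, nrow(mat), ncol(mat)))
  d_in <- sqrt(cpp_edt_sq(as.integer(mat == 0), dims, sp))   # depth inside
  d_out <- sqrt(cpp_edt_sq(as.integer(mat != 0), dims, sp))  # distance outside
  sd <- ifelse(mat != 0, d_in, -d_out)
  matrix(sd, nrow(mat), ncol(mat))
}

# Shift a 2D field by a continuous offset (voxel units) with bilinear
# sampling and edge clamping: out(x) = f(x - offset).
shift_slice <- function(mat, offset_vox) {
  d <- c(dim(mat), 1L)
  nx <- d[1]; ny <- d[2]
  coords <- cbind(rep(seq_len(nx) - 1, times = ny) - offset_vox[1],
                  rep(seq_len(ny) - 1, each = nx) - offset_vox[2],
                  0)
  matrix(cpp_sample3(as.vector(mat), d, coords, linear = TRUE, clamp = TRUE,
                     fill = 0), nx, ny)
}

# Morphological interpolation of the slice midway between two binary
# slices: centroid-aligned signed distance functions are averaged and
# thresholded, then the result is produced at the mid-centroid position.
morph_interp_pair <- function(a, b, spacing2) {
  ea <- sum(a) == 0; eb <- sum(b) == 0
  if (ea && eb) return(a * 0)
  da <- signed_dist_slice(a, spacing2)
  db <- signed_dist_slice(b, spacing2)
  if (ea || eb) {
    # degenerate pair: shrink the non-empty region towards its deepest point
    d <- if (ea) db else da
    mdep <- max(d[is.finite(d)])
    return((d > mdep / 2 + 1e-9) * 1)
  }
  idx <- function(m) {
    w <- which(m != 0, arr.ind = TRUE)
    colMeans(w)
  }
  ca <- idx(a); cb <- idx(b)
  mid <- (ca + cb) / 2
  da <- shift_slice(da, mid - ca)
  db <- shift_slice(db, mid - cb)
  ((da + db) / 2 > 0) * 1
}

#' Morphological interpolation of contour stacks
#'
#' Fills each unannotated slice with a region geometrically intermediate
#' between its two annotated neighbours: the neighbours' 2D signed distance
#' functions are centroid-aligned, averaged and thresholded, giving a
#' smooth change of shape through the stack.  Annotated slices are
#' returned unchanged.
#'
#' @param stack a \code{sparse_slice_stack} with contour payload.
#' @return a binary \code{voxel_grid}.
#' @export
interpolate_contours <- function(stack) {
  stopifnot(inherits(stack, "sparse_slice_stack"))
  if (stack$payload_kind != "contour")
    stop("interpolate_contours requires a contour payload")
  g <- stack$grid
  out <- g$values
  s <- stack$annotated_slices
  sp2 <- g$spacing[1:2]
  for (i in seq_len(length(s) - 1)) {
    if (s[i + 1] - s[i] != 2) next
    mid <- s[i] + 1L
    out[, , mid] <- morph_interp_pair(g$values[, , s[i]],
                                      g$values[, , s[i + 1]], sp2)
  }
  grid_like(g, out)
}

#' Linear interpolation of cell-density stacks
#'
#' Each filled voxel receives the arithmetic mean of the two neighbouring
#' annotated slices at the same in-plane position, so interpolated values
#' always lie within the range of the actual values on the adjacent
#' slices.
#'
#' @param stack a \code{sparse_slice_stack} with density payload.
#' @return a \code{voxel_grid}, cells/mm^2.
#' @export
interpolate_density <- function(stack) {
  stopifnot(inherits(stack, "sparse_slice_stack"))
  if (stack$payload_kind != "density")
    stop("interpolate_density requires a density payload")
  g <- stack$grid
  out <- g$values
  s <- stack$annotated_slices
  for (i in seq_len(length(s) - 1)) {
    if (s[i + 1] - s[i] != 2) next
    out[, , s[i] + 1L] <- (g$values[, , s[i]] + g$values[, , s[i + 1]]) / 2
  }
  grid_like(g, out)
}

#' Convert cross-sectional to volumetric cell density
#'
#' Raises cross-sectional density (cells/mm^2) to \code{exponent} to obtain
#' volumetric density (cells/mm^3); the default 3/2 power corresponds to
#' isotropic cell packing.  The map is monotone, so the ordering of voxel
#' values is preserved.
#'
#' @param density non-negative \code{voxel_grid}, cells/mm^2.
#' @param exponent positive exponent (default 3/2).
#' @return a \code{voxel_grid}, cells/mm^3.
#' @export
to_volumetric <- function(density, exponent = 1.5) {
  stopifnot(inherits(density, "voxel_grid"))
  if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 0)
    stop("exponent must be a single positive number")
  if (any(density$values < 0))
    stop("density must be non-negative")
  grid_like(density, density$values^exponent)
}

#' Probabilistic interpolation of graded lesion stacks
#'
#' One 3D probabilistic label image per Gleason grade.  Lesion voxels on
#' annotated slices carry 1; on the slice between two annotated slices each
#' flanking lesion footprint contributes a weighting of 0.5, contributions
#' of the same grade add and are capped at 1.  A voxel flanked by
#' same-grade lesions on both sides therefore carries 1, while a voxel
#' flanked by lesions of two different grades carries 0.5 in each grade's
#' image.  A single annotated voxel may belong to at most one grade.
#'
#' @param stacks named list (grade -> \code{sparse_slice_stack}) sharing
#'   grid and annotated slices.
#' @return named list (grade -> \code{voxel_grid} with values in [0, 1]).
#' @export
interpolate_lesions <- function(stacks) {
  if (length(stacks) == 0) return(list())
  for (st in stacks) {
    stopifnot(inherits(st, "sparse_slice_stack"))
    if (st$payload_kind != "lesion_grade")
      stop("interpolate_lesions requires lesion_grade payloads")
  }
  s <- stacks[[1]]$annotated_slices
  for (st in stacks[-1]) {
    assert_aligned(stacks[[1]]$grid, st$grid, what = "lesion stacks")
    if (!identical(st$annotated_slices, s))
      stop("lesion stacks must share annotated slices")
  }
  if (length(stacks) > 1) {
    tot <- Reduce(`+`, lapply(stacks, function(st)
      st$grid$values[, , s, drop = FALSE]))
    if (any(tot > 1))
      stop("overlapping grades on an annotated slice voxel: one grade per annotated lesion voxel")
  }
  lapply(stacks, function(st) {
    out <- st$grid$values
    for (i in seq_len(length(s) - 1)) {
      if (s[i + 1] - s[i] != 2) next
      contrib <- 0.5 * st$grid$values[, , s[i]] +
        0.5 * st$grid$values[, , s[i + 1]]
      out[, , s[i] + 1L] <- pmin(1, contrib)
    }
    grid_like(st$grid, out)
  })
}

#' Interpolate every sparse volume of a patient
#'
#' Applies contour interpolation to the peripheral-zone and urethra masks,
#' linear interpolation plus the volumetric conversion to the density map,
#' and probabilistic interpolation to the graded lesion maps.  The validity
#' mask is set to the axial slab spanned by the annotated slices: slices
#' beyond the first/last annotated slice carry no histology-derived data
#' and are excluded from atlas statistics.
#'
#' @param patient a \code{patient_dataset} with sparse annotations.
#' @param config a \code{pipeline_config}.
#' @return a \code{patient_dataset} with filled volumes, volumetric density
#'   and a validity mask.
#' @export
fill_patient <- function(patient, config = pipeline_config()) {
  s <- patient$annotated_slices
  pz <- interpolate_contours(
    sparse_slice_stack(patient$pz_mask, s, "contour"))
  ur <- interpolate_contours(
    sparse_slice_stack(patient$urethra_mask, s, "contour"))
  dens <- interpolate_density(
    sparse_slice_stack(patient$density, s, "density"))
  dens <- to_volumetric(dens, config$density_exponent)
  lesions <- interpolate_lesions(lapply(patient$lesion_maps, function(g)
    sparse_slice_stack(g, s, "lesion_grade")))
  # clip the filled PZ to the gland so containment survives interpolation
  pz <- grid_like(pz, pz$values * patient$prostate_mask$values)
  for (g in names(lesions))
    lesions[[g]] <- grid_like(lesions[[g]],
                              lesions[[g]]$values * patient$prostate_mask$values)
  val <- array(0, dim(patient$prostate_mask$values))
  val[, , s[1]:s[length(s)]] <- 1
  patient_dataset(prostate_mask = patient$prostate_mask,
                  pz_mask = pz, urethra_mask = ur,
                  lesion_maps = lesions, density = dens,
                  annotated_slices = s, mri = patient$mri,
                  validity_mask = grid_like(patient$prostate_mask, val),
                  density_volumetric = TRUE)
}
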