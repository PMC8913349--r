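#' Assemble a single-subject dataset
#'
#' One subject's co-registered volumes: gland masks, per-grade probabilistic
#' lesion maps, a cell-density map and the list of axial slices that carry
#' histology-derived data.  Whole-mount sectioning samples the gland at
#' twice the axial slice thickness, so before interpolation the lesion and
#' density data exist only on \code{annotated_slices} (1-based indices along
#' the third axis).
#'
#' @param prostate_mask,pz_mask,urethra_mask binary \code{voxel_grid}s; the
#'   peripheral zone must lie inside the prostate.
#' @param lesion_maps named list (Gleason grade label -> \code{voxel_grid}
#'   with values in [0, 1]).
#' @param density cell-density \code{voxel_grid}; cells/mm^2
#'   (cross-sectional) unless \code{density_volumetric}.
#' @param annotated_slices strictly increasing integer slice indices.
#' @param mri optional intensity \code{voxel_grid}.
#' @param validity_mask optional binary \code{voxel_grid} marking voxels
#'   with usable data (filled in by \code{\link{fill_patient}}).
#' @param density_volumetric logical; TRUE after the 3/2-power conversion
#'   to cells/mm^3.
#' @return a \code{patient_dataset}.
#' @export
patient_dataset <- function(prostate_mask, pz_mask, urethra_mask,
                            lesion_maps, density, annotated_slices,
                            mri = NULL, validity_mask = NULL,
                            density_volumetric = FALSE) {
  p <- structure(list(mri = mri,
                      prostate_mask = prostate_mask,
                      pz_mask = pz_mask,
                      urethra_mask = urethra_mask,
                      lesion_maps = lesion_maps,
                      density = density,
                      annotated_slices = as.integer(annotated_slices),
                      validity_mask = validity_mask,
                      density_volumetric = isTRUE(density_volumetric)),
                 class = "patient_dataset")
  validate_patient(p)
}

validate_patient <- function(p) {
  grids <- c(list(p$prostate_mask, p$pz_mask, p$urethra_mask, p$density),
             unname(p$lesion_maps),
             if (!is.null(p$mri)) list(p$mri),
             if (!is.null(p$validity_mask)) list(p$validity_mask))
  do.call(assert_aligned, c(grids, list(what = "patient volumes")))
  assert_binary(p$prostate_mask, "prostate_mask")
  assert_binary(p$pz_mask, "pz_mask")
  assert_binary(p$urethra_mask, "urethra_mask")
  if (any(p$pz_mask$values > p$prostate_mask$values))
    stop("pz_mask must be contained in prostate_mask")
  for (g in names(p$lesion_maps)) {
    v <- p$lesion_maps[[g]]$values
    if (any(v < 0 | v > 1))
      stop(sprintf("lesion map '%s' has values outside [0, 1]", g))
    if (any(v > 0 & p$prostate_mask$values == 0))
      stop(sprintf("lesion map '%s' extends outside the prostate", g))
  }
  if (any(p$density$values < 0)) stop("density must be non-negative")
  s <- p$annotated_slices
  nk <- dim(p$density$values)[3]
  if (length(s) == 0 || any(diff(s) <= 0) || s[1] < 1 || s[length(s)] > nk)
    stop("annotated_slices must be strictly increasing valid slice indices")
  p
}

#' @export
print.patient_dataset <- function(x, ...) {
  d <- dim(x$prostate_mask$values)
  cat(sprintf("<patient_dataset> %d x %d x %d voxels; %d annotated slice(s); %d lesion grade(s)\n",
              d[1], d[2], d[3], length(x$annotated_slices),
              length(x$lesion_maps)))
  cat(sprintf("  density: cells/%s\n",
              if (x$density_volumetric) "mm^3" else "mm^2"))
  invisible(x)
}

#' Write / read a patient dataset as an image directory
#'
#' Volumes are written as NIfTI files plus a JSON sidecar holding the
#' annotated slice list, the grade labels and the density unit flag.
#'
#' @param patient a \code{patient_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{write_patient}: \code{dir} invisibly;
#'   \code{read_patient}: a \code{patient_dataset}.
#' @export
write_patient <- function(patient, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(patient$prostate_mask, file.path(dir, "prostate_mask.nii.gz"))
  write_image(patient$pz_mask, file.path(dir, "pz_mask.nii.gz"))
  write_image(patient$urethra_mask, file.path(dir, "urethra_mask.nii.gz"))
  write_image(patient$density, file.path(dir, "density.nii.gz"))
  if (!is.null(patient$mri))
    write_image(patient$mri, file.path(dir, "mri.nii.gz"))
  if (!is.null(patient$validity_mask))
    write_image(patient$validity_mask, file.path(dir, "validity_mask.nii.gz"))
  for (i in seq_along(patient$lesion_maps))
    write_image(patient$lesion_maps[[i]],
                file.path(dir, sprintf("lesion_%02d.nii.gz", i)))
  meta <- list(annotated_slices = patient$annotated_slices,
               grades = as.list(names(patient$lesion_maps)),
               density_volumetric = patient$density_volumetric)
  jsonlite::write_json(meta, file.path(dir, "patient.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_patient
#' @export
read_patient <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "patient.json"),
                              simplifyVector = TRUE)
  grades <- as.character(meta$grades)
  lesion_maps <- stats::setNames(lapply(seq_along(grades), function(i)
    read_image(file.path(dir, sprintf("lesion_%02d.nii.gz", i)))), grades)
  mri_path <- file.path(dir, "mri.nii.gz")
  val_path <- file.path(dir, "validity_mask.nii.gz")
  patient_dataset(
    prostate_mask = read_image(file.path(dir, "prostate_mask.nii.gz")),
    pz_mask = read_image(file.path(dir, "pz_mask.nii.gz")),
    urethra_mask = read_image(file.path(dir, "urethra_mask.nii.gz")),
    lesion_maps = lesion_maps,
    density = read_image(file.path(dir, "density.nii.gz")),
    annotated_slices = meta$annotated_slices,
    mri = if (file.exists(mri_path)) read_image(mri_path),
    validity_mask = if (file.exists(val_path)) read_image(val_path),
    density_volumetric = isTRUE(meta$density_volumetric))
}
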