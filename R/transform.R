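#' Transform chain: similarity stage plus deformable stages
#'
#' Orders the anisotropic similarity transform and one or two
#' displacement fields (whole-gland stage, then the pinned-boundary
#' peripheral-zone stage).  Applied right-to-left: a reference-space point
#' is displaced by the last deformable stage, then the first, then mapped
#' to patient space through the inverse similarity transform, which is the
#' composition used to pull patient data onto the reference grid.
#'
#' @param similarity a \code{similarity3} (moving/patient to fixed/reference).
#' @param fields list of 0-2 \code{displacement_field}s in stage order.
#' @return a \code{transform_chain}.
#' @export
transform_chain <- function(similarity = similarity_identity(),
                            fields = list()) {
  stopifnot(inherits(similarity, "similarity3"))
  for (f in fields) stopifnot(inherits(f, "displacement_field"))
  structure(list(similarity = similarity, fields = fields),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  cat(sprintf("<transform_chain> similarity + %d deformable stage(s)\n",
              length(x$fields)))
  invisible(x)
}

# reference-space mm points -> patient-space mm points
chain_map_points <- function(chain, pts) {
  for (f in rev(chain$fields))
    pts <- pts + sample_displacement(f, pts)
  similarity_inverse_points(chain$similarity, pts)
}

#' Map a patient volume onto the reference grid through a transform chain
#'
#' Resamples \code{data} (a volume on the patient grid) at the points the
#' chain maps each reference voxel to.  Use nearest mode for masks and
#' linear mode for probabilistic or density data; positions falling outside
#' the patient volume receive \code{missing} and should be excluded from
#' validity.
#'
#' @param chain a \code{transform_chain}.
#' @param data a \code{voxel_grid} on the patient grid.
#' @param reference a \code{voxel_grid} defining the output geometry.
#' @param mode \code{"nearest"} or \code{"linear"}.
#' @param missing value assigned outside the patient extent.
#' @return a \code{voxel_grid} on the reference grid.
#' @export
compose_and_apply <- function(chain, data, reference,
                              mode = c("linear", "nearest"), missing = NA) {
  mode <- match.arg(mode)
  stopifnot(inherits(chain, "transform_chain"), inherits(data, "voxel_grid"))
  pts <- chain_map_points(chain, grid_points(reference))
  vals <- cpp_sample3(as.vector(data$values), dim(data$values),
                      world_to_index(data, pts) - 1,
                      linear = mode == "linear", clamp = FALSE,
                      fill = as.numeric(missing))
  grid_like(reference, array(vals, dim(reference$values)))
}

# internal shorthand with a numeric fill (masks)
apply_chain_to_grid <- function(chain, data, reference, mode, fill = 0) {
  compose_and_apply(chain, data, reference, mode = mode, missing = fill)
}

#' Register a patient to the reference geometry
#'
#' Runs the full two-stage procedure: anisotropic similarity registration
#' of the gland, distance-preserving deformable registration of the gland,
#' then distance-preserving registration of the peripheral zone with the
#' gland boundary pinned so the second stage cannot disturb the first.
#'
#' @param patient a filled \code{patient_dataset}.
#' @param reference a \code{reference_geometry}.
#' @param config a \code{pipeline_config}.
#' @param pz_stage run the pinned-boundary PZ stage (default TRUE).
#' @return a \code{transform_chain}.
#' @export
register_patient <- function(patient, reference,
                             config = pipeline_config(), pz_stage = TRUE) {
  sim <- similarity_register(patient$prostate_mask, reference$prostate)
  chain <- transform_chain(sim)
  mov <- apply_chain_to_grid(chain, patient$prostate_mask,
                             reference$prostate, "nearest")
  d1 <- distance_preserving_register(mov, reference$prostate, config = config)
  chain <- transform_chain(sim, list(d1))
  if (pz_stage && sum(patient$pz_mask$values) > 0 &&
      sum(reference$pz$values) > 0) {
    pzw <- apply_chain_to_grid(chain, patient$pz_mask, reference$prostate,
                               "nearest")
    if (sum(pzw$values) > 0) {
      d2 <- distance_preserving_register(pzw, reference$pz,
                                         pin_boundary_of = reference$prostate,
                                         config = config)
      chain <- transform_chain(sim, list(d1, d2))
    }
  }
  chain
}

#' Warp a patient's histology-derived volumes into reference space
#'
#' @param patient a filled \code{patient_dataset}.
#' @param chain the patient's \code{transform_chain}.
#' @param reference a \code{reference_geometry}.
#' @return list with warped \code{lesion_maps} (linear, [0, 1]),
#'   \code{density} (linear, NA outside patient support), \code{validity}
#'   (nearest, 0 outside) and \code{prostate} (nearest).
#' @export
map_patient_to_reference <- function(patient, chain, reference) {
  ref <- reference$prostate
  lesions <- lapply(patient$lesion_maps, function(g) {
    w <- compose_and_apply(chain, g, ref, "linear", missing = 0)
    grid_like(w, pmin(1, pmax(0, w$values)))
  })
  density <- compose_and_apply(chain, patient$density, ref, "linear",
                               missing = NA)
  validity <- compose_and_apply(chain, patient$validity_mask, ref,
                                "nearest", missing = 0)
  validity <- grid_like(validity,
                        validity$values * (!is.na(density$values)))
  density <- grid_like(density,
                       ifelse(validity$values == 0, NA, density$values))
  prostate <- compose_and_apply(chain, patient$prostate_mask, ref,
                                "nearest", missing = 0)
  list(lesion_maps = lesions, density = density, validity = validity,
       prostate = prostate)
}

#' Write a displacement field as component NIfTI images
#'
#' @param field a \code{displacement_field}.
#' @param prefix output path prefix; files \code{<prefix>_x.nii.gz} etc.
#' @return the three paths, invisibly.
#' @export
write_displacement_field <- function(field, prefix) {
  dims <- dim(field$d)[1:3]
  paths <- character(3)
  for (a in 1:3) {
    g <- voxel_grid(field$d[, , , a], field$spacing, field$origin,
                    field$direction)
    paths[a] <- sprintf("%s_%s.nii.gz", prefix, c("x", "y", "z")[a])
    write_image(g, paths[a])
  }
  invisible(paths)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(prefix) {
  comps <- lapply(c("x", "y", "z"), function(a)
    read_image(sprintf("%s_%s.nii.gz", prefix, a)))
  d <- array(0, c(dim(comps[[1]]$values), 3))
  for (a in 1:3) d[, , , a] <- comps[[a]]$values
  new_displacement_field(d, comps[[1]]$spacing, comps[[1]]$origin,
                         comps[[1]]$direction)
}
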