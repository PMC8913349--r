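#' Pipeline configuration
#'
#' Collects every tunable parameter of the atlas pipeline with the study
#' defaults: 0.8 mm isotropic working resolution, half-or-more consensus,
#' 1.5 mm urethra tube radius and the 3/2-power cross-sectional to
#' volumetric cell-density conversion.
#'
#' @param iso_spacing isotropic working voxel size, mm.
#' @param consensus_fraction fraction of cohort masks that must cover a
#'   voxel for it to enter a consensus volume, in (0, 1].
#' @param urethra_radius urethra tube radius, mm.
#' @param density_exponent exponent of the cross-sectional (cells/mm^2) to
#'   volumetric (cells/mm^3) conversion; 3/2 by default, 1 selects the
#'   linear-scaling alternative.
#' @param demons list of deformable-registration parameters: \code{levels}
#'   (pyramid depth), \code{iterations} (per level, coarse to fine),
#'   \code{sigma_update} / \code{sigma_total} (Gaussian smoothing of the
#'   update and accumulated velocity, voxels), \code{pin_band} (width in
#'   voxels of the ramp outside the pinned boundary).
#' @param min_samples_fit minimum valid samples for a voxel to be fitted.
#' @param min_samples_kl minimum valid samples for KL evaluation.
#' @param lognormal_zero how the log-normal fit treats zero densities:
#'   \code{"exclude"} drops them at that voxel, \code{"floor"} replaces
#'   them with \code{zero_floor}.
#' @param zero_floor positive replacement used when
#'   \code{lognormal_zero = "floor"}.
#' @param rng_seed integer seed recorded with every pipeline product.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(iso_spacing = 0.8,
                            consensus_fraction = 0.5,
                            urethra_radius = 1.5,
                            density_exponent = 1.5,
                            demons = list(),
                            min_samples_fit = 3L,
                            min_samples_kl = 5L,
                            lognormal_zero = c("exclude", "floor"),
                            zero_floor = 1e-3,
                            rng_seed = 1L) {
  demons_def <- list(levels = 3L, iterations = c(50L, 30L, 20L),
                     sigma_update = 1.5, sigma_total = 0.5, pin_band = 3)
  demons <- utils::modifyList(demons_def, demons)
  cfg <- list(iso_spacing = iso_spacing,
              consensus_fraction = consensus_fraction,
              urethra_radius = urethra_radius,
              density_exponent = density_exponent,
              demons = demons,
              min_samples_fit = as.integer(min_samples_fit),
              min_samples_kl = as.integer(min_samples_kl),
              lognormal_zero = match.arg(lognormal_zero),
              zero_floor = zero_floor,
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("iso_spacing", "urethra_radius", "density_exponent", "zero_floor")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("config field '%s' must be a single positive number", f))
  if (cfg$consensus_fraction <= 0 || cfg$consensus_fraction > 1)
    stop("consensus_fraction must lie in (0, 1]")
  d <- cfg$demons
  if (d$levels < 1L || length(d$iterations) != d$levels)
    stop("demons$iterations must supply one entry per pyramid level")
  if (any(d$iterations < 1L) || d$sigma_update < 0 || d$sigma_total < 0 ||
      d$pin_band <= 0)
    stop("invalid demons parameters")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Unspecified fields take the package defaults, so a config file only needs
#' to list overrides.  Every pipeline stage writes the fully resolved
#' configuration next to its outputs for reproducibility.
#'
#' @param path YAML file path.
#' @return \code{read_config}: a \code{pipeline_config};
#'   \code{write_config}: \code{path}, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file does not exist: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
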