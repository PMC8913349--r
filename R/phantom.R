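# Synthetic phantom cohorts with the sampling structure of the study data:
# ellipsoidal glands with per-patient anisotropic scaling and rotation, a
# posterior-crescent peripheral zone, a spline urethra, posterolaterally
# seeded lesion blobs with Gleason grades, log-normal cell density, and
# histology annotations on every second axial slice away from apex/base.

#' Specify a phantom cohort
#'
#' @param n_patients number of patients to generate.
#' @param gland_radii canonical ellipsoid semi-axes (x, y, z), mm.
#' @param radii_jitter per-axis fractional scale jitter (uniform +/-).
#' @param rotation_deg per-axis rotation jitter, degrees (uniform +/-).
#' @param pz_fraction thickness of the posterior peripheral-zone crescent
#'   as a fraction of the normalised gland radius, in (0, 1).
#' @param lesion_rate expected lesions per patient (0 disables lesions;
#'   every patient with lesions receives at least one).
#' @param pz_posterolateral_weight probability that a patient's index
#'   lesion is seeded in the posterolateral peripheral zone.
#' @param lateral_offset minimum |x| (normalised units) from the
#'   midsagittal plane for "posterolateral".
#' @param lesion_radius_range lesion blob radius range, mm.
#' @param grades Gleason grade labels; \code{grade_probs} their sampling
#'   probabilities.
#' @param grade_probs see \code{grades}.
#' @param density_log_mean,density_log_sd log-space parameters of the
#'   baseline cell density, log(cells/mm^2).  The default spread gives a
#'   voxel-level volumetric log-sd of about 0.2 (CV about 20\%) after the
#'   3/2-power conversion, the mild-skew regime in which voxel-level
#'   KDE/KL model comparison operates in the study data.
#' @param lesion_density_multiplier density multiplier inside lesions.
#' @param density_kind \code{"lognormal"} (the study model) or
#'   \code{"normal"} (moment-matched, truncated at zero; mirrored control).
#' @param slice_spacing axial slice thickness, mm (study value 2.5).
#' @param in_plane_spacing in-plane voxel size, mm.
#' @param histology_interval sectioning interval, mm (study value 5); must
#'   be an integer multiple of \code{slice_spacing}.
#' @param apex_base_margin gland length excluded from annotation at each
#'   of apex and base, mm.
#' @param urethra_radius urethra tube radius, mm.
#' @param rng_seed integer; generation is a pure function of the spec
#'   including this seed.
#' @return a \code{phantom_spec}.
#' @export
phantom_spec <- function(n_patients = 10L,
                         gland_radii = c(22, 18, 20),
                         radii_jitter = 0.2,
                         rotation_deg = 15,
                         pz_fraction = 0.5,
                         lesion_rate = 1.5,
                         pz_posterolateral_weight = 0.4,
                         lateral_offset = 0.25,
                         lesion_radius_range = c(3.5, 7),
                         grades = c("3+3", "3+4", "4+3", "4+4"),
                         grade_probs = c(0.25, 0.35, 0.25, 0.15),
                         density_log_mean = log(1000),
                         density_log_sd = 0.13,
                         lesion_density_multiplier = 2,
                         density_kind = c("lognormal", "normal"),
                         slice_spacing = 2.5,
                         in_plane_spacing = 1.2,
                         histology_interval = 5,
                         apex_base_margin = 5,
                         urethra_radius = 1.5,
                         rng_seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               gland_radii = gland_radii, radii_jitter = radii_jitter,
               rotation_deg = rotation_deg, pz_fraction = pz_fraction,
               lesion_rate = lesion_rate,
               pz_posterolateral_weight = pz_posterolateral_weight,
               lateral_offset = lateral_offset,
               lesion_radius_range = lesion_radius_range,
               grades = grades, grade_probs = grade_probs,
               density_log_mean = density_log_mean,
               density_log_sd = density_log_sd,
               lesion_density_multiplier = lesion_density_multiplier,
               density_kind = match.arg(density_kind),
               slice_spacing = slice_spacing,
               in_plane_spacing = in_plane_spacing,
               histology_interval = histology_interval,
               apex_base_margin = apex_base_margin,
               urethra_radius = urethra_radius,
               rng_seed = as.integer(rng_seed))
  if (spec$n_patients < 1) stop("n_patients must be positive")
  if (any(spec$gland_radii <= 0) || spec$slice_spacing <= 0 ||
      spec$in_plane_spacing <= 0 || spec$urethra_radius <= 0)
    stop("physical phantom dimensions must be positive")
  if (spec$pz_fraction <= 0 || spec$pz_fraction >= 1)
    stop("pz_fraction must lie in (0, 1)")
  if (spec$pz_posterolateral_weight < 0 || spec$pz_posterolateral_weight > 1)
    stop("pz_posterolateral_weight must lie in [0, 1]")
  step <- spec$histology_interval / spec$slice_spacing
  if (abs(step - round(step)) > 1e-9 || round(step) < 1)
    stop("histology_interval must be an integer multiple of slice_spacing")
  if (length(spec$grade_probs) != length(spec$grades) ||
      any(spec$grade_probs < 0))
    stop("grade_probs must match grades")
  structure(spec, class = "phantom_spec")
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

phantom_grid <- function(spec) {
  h <- max(spec$gland_radii) * (1 + spec$radii_jitter) + 4
  nx <- 2L * as.integer(ceiling(h / spec$in_plane_spacing)) + 1L
  nz <- 2L * as.integer(ceiling(h / spec$slice_spacing)) + 1L
  sp <- c(spec$in_plane_spacing, spec$in_plane_spacing, spec$slice_spacing)
  voxel_grid(array(0, c(nx, nx, nz)), spacing = sp,
             origin = -c((nx - 1) / 2, (nx - 1) / 2, (nz - 1) / 2) * sp)
}

rot3 <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# anatomy of one patient: masks + normalised coordinates on the grid
phantom_anatomy <- function(spec, grid, jitter = TRUE) {
  s <- spec$gland_radii
  R <- diag(3)
  if (jitter) {
    s <- s * (1 + stats::runif(3, -spec$radii_jitter, spec$radii_jitter))
    R <- rot3(stats::runif(3, -1, 1) * spec$rotation_deg * pi / 180)
  }
  pts <- grid_points(grid)
  w <- sweep(pts %*% R, 2, s, "/")   # canonical unit-ball coordinates
  r <- sqrt(rowSums(w^2))
  d <- dim(grid$values)
  gland <- array(r <= 1, d)
  pz <- array(r <= 1 & r >= 1 - spec$pz_fraction & w[, 2] >= 0.1, d)
  pl <- array(r <= 1 & r >= 1 - spec$pz_fraction & w[, 2] > 0.3 &
                abs(w[, 1]) > spec$lateral_offset, d)
  # annotated slices: every (interval/thickness)-th gland slice outside the
  # apex/base margin
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  has_gland <- apply(gland, 3, any)
  zr <- range(zs[has_gland])
  eligible <- which(has_gland & zs >= zr[1] + spec$apex_base_margin &
                      zs <= zr[2] - spec$apex_base_margin)
  if (length(eligible) < 2)
    stop("gland too small for the requested apex_base_margin")
  step <- as.integer(round(spec$histology_interval / spec$slice_spacing))
  annotated <- eligible[seq(1, length(eligible), by = step)]
  # urethra: anteriorly bowed curve through the gland centre
  tt <- seq(-0.8, 0.8, length.out = 11)
  wline <- cbind(0, -0.25 * (1 - tt^2), tt)
  centreline <- (wline %*% diag(s)) %*% t(R)
  list(scales = s, rotation = R, gland = gland, pz = pz, posterolateral = pl,
       annotated = annotated, centreline = centreline)
}

# lesion occupancy: one integer array, 0 = none, g = index into grades,
# plus per-lesion provenance (seed voxel, posterolateral flag, grade, radius)
phantom_lesions <- function(spec, grid, anat) {
  d <- dim(grid$values)
  occ <- array(0L, d)
  info <- data.frame(seed = integer(), posterolateral = logical(),
                     grade = character(), radius = numeric())
  if (spec$lesion_rate == 0)
    return(list(occ = occ, info = info))
  n_les <- if (spec$lesion_rate < 1) stats::rbinom(1, 1, spec$lesion_rate)
  else 1L + stats::rpois(1, spec$lesion_rate - 1)
  if (n_les == 0) return(list(occ = occ, info = info))
  pl_idx <- which(anat$posterolateral)
  other_idx <- which(anat$gland & !anat$posterolateral)
  sp <- grid$spacing
  for (k in seq_len(n_les)) {
    use_pl <- k == 1 && length(pl_idx) > 0 &&
      stats::runif(1) < spec$pz_posterolateral_weight
    pool <- if (use_pl) pl_idx else other_idx
    if (length(pool) == 0) pool <- which(anat$gland)
    seed <- pool[sample.int(length(pool), 1)]
    r <- stats::runif(1, spec$lesion_radius_range[1],
                      spec$lesion_radius_range[2])
    si <- arrayInd(seed, d)
    half <- ceiling(1.6 * r / sp)
    lo <- pmax(si[1, ] - half, 1)
    hi <- pmin(si[1, ] + half, d)
    bd <- hi - lo + 1
    ax <- (seq(lo[1], hi[1]) - si[1, 1]) * sp[1]
    ay <- (seq(lo[2], hi[2]) - si[1, 2]) * sp[2]
    az <- (seq(lo[3], hi[3]) - si[1, 3]) * sp[3]
    dist <- sqrt(outer(outer(ax^2, ay^2, "+"), az^2, "+"))
    noise <- array(stats::rnorm(prod(bd)), bd)
    noise <- array(cpp_gauss3(as.vector(noise), bd, rep(1.5, 3)), bd)
    nsd <- stats::sd(noise)
    if (nsd > 0) noise <- noise / nsd
    field <- 1 - dist / r + 0.35 * noise
    g <- sample.int(length(spec$grades), 1, prob = spec$grade_probs)
    box <- occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    glb <- anat$gland[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    newv <- field > 0 & glb & (box == 0L | box == g)
    box[newv] <- g
    occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- box
    info <- rbind(info, data.frame(seed = seed, posterolateral = use_pl,
                                   grade = spec$grades[g], radius = r))
  }
  list(occ = occ, info = info)
}

# zero all slices except the annotated ones
keep_slices <- function(arr, slices) {
  out <- array(0, dim(arr))
  out[, , slices] <- arr[, , slices]
  out
}

# any-grade lesion weight field after probabilistic interpolation (the
# fill rule of interpolate_lesions, vectorised for the truth Monte Carlo)
lesion_weight_field <- function(occ, slices, n_grades) {
  d <- dim(occ)
  any_w <- array(0, d)
  for (g in seq_len(n_grades)) {
    wg <- array(0, d)
    wg[, , slices] <- (occ[, , slices] == g) * 1
    for (i in seq_len(length(slices) - 1)) {
      if (slices[i + 1] - slices[i] != 2) next
      wg[, , slices[i] + 1L] <-
        pmin(1, 0.5 * wg[, , slices[i]] + 0.5 * wg[, , slices[i + 1]])
    }
    any_w <- any_w + wg
  }
  pmin(1, any_w)
}

phantom_density <- function(spec, grid, anat, occ) {
  d <- dim(grid$values)
  dens <- array(0, d)
  sl <- anat$annotated
  idx <- which(keep_slices(anat$gland, sl) > 0)
  n <- length(idx)
  base <- if (spec$density_kind == "lognormal") {
    exp(stats::rnorm(n, spec$density_log_mean, spec$density_log_sd))
  } else {
    m <- exp(spec$density_log_mean + spec$density_log_sd^2 / 2)
    s <- m * sqrt(exp(spec$density_log_sd^2) - 1)
    pmax(0, stats::rnorm(n, m, s))
  }
  mult <- ifelse(occ[idx] > 0, spec$lesion_density_multiplier, 1)
  dens[idx] <- base * mult
  dens
}

phantom_patient <- function(spec, grid, jitter = TRUE) {
  anat <- phantom_anatomy(spec, grid, jitter = jitter)
  les <- phantom_lesions(spec, grid, anat)
  occ <- les$occ
  dens <- phantom_density(spec, grid, anat, occ)
  sl <- anat$annotated
  urethra <- urethra_tube(anat$centreline, spec$urethra_radius, grid)
  lesion_maps <- stats::setNames(lapply(seq_along(spec$grades), function(g)
    grid_like(grid, keep_slices((occ == g) * 1, sl))), spec$grades)
  lesion_maps <- lesion_maps[vapply(lesion_maps, function(m)
    sum(m$values) > 0, logical(1))]
  out <- patient_dataset(
    prostate_mask = grid_like(grid, anat$gland * 1),
    pz_mask = grid_like(grid, keep_slices(anat$pz * 1, sl)),
    urethra_mask = grid_like(grid, keep_slices(urethra$values *
                                                 anat$gland, sl)),
    lesion_maps = lesion_maps,
    density = grid_like(grid, dens),
    annotated_slices = sl)
  attr(out, "lesion_info") <- les$info
  out
}

#' Generate a synthetic patient cohort
#'
#' A pure function of the spec (including its seed): two calls with the
#' same spec produce identical cohorts.  Each patient is an anisotropically
#' scaled, rotated ellipsoidal gland with a posterior peripheral zone, a
#' spline urethra, Gleason-graded lesion blobs preferentially seeded in
#' the posterolateral peripheral zone, and log-normally distributed cell
#' density (multiplied inside lesions).  Lesion, density, peripheral-zone
#' and urethra data exist only on the annotated slices.
#'
#' @param spec a \code{phantom_spec}.
#' @return list of \code{patient_dataset}s with the generating spec
#'   attached as attribute \code{"spec"}; each patient additionally carries
#'   a \code{"lesion_info"} attribute (data.frame: seed voxel index,
#'   posterolateral seeding flag, grade, blob radius in mm).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)
  cohort <- with_local_seed(spec$rng_seed,
                            lapply(seq_len(spec$n_patients), function(i)
                              phantom_patient(spec, grid)))
  attr(cohort, "spec") <- spec
  cohort
}

#' Ground truth of the phantom generator
#'
#' Returns the latent fields the generator draws from, on the canonical
#' (jitter-free) geometry: the per-voxel any-grade lesion-probability
#' field (the marginal probability that a patient's interpolated lesion
#' weight covers the voxel, evaluated by Monte Carlo over \code{n_mc}
#' independent lesion realisations with a fixed internal seed, so it is
#' identical across spec seeds), the canonical gland/PZ/posterolateral
#' masks, the annotated slices, and the density parameters.
#'
#' @param spec a \code{phantom_spec}.
#' @param n_mc Monte-Carlo replicates for the lesion-probability field.
#' @return list with \code{p_field} (\code{voxel_grid} of expected lesion
#'   weight), \code{gland}, \code{pz}, \code{posterolateral},
#'   \code{annotated_slices}, \code{density} (list: kind, log_mean,
#'   log_sd, multiplier) and \code{n_mc}.
#' @export
cohort_truth <- function(spec, n_mc = 800L) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- phantom_grid(spec)
  anat <- with_local_seed(1L, phantom_anatomy(spec, grid, jitter = FALSE))
  d <- dim(grid$values)
  acc <- array(0, d)
  if (spec$lesion_rate > 0) {
    acc <- with_local_seed(20220306L, {
      a <- array(0, d)
      for (rep in seq_len(n_mc)) {
        occ <- phantom_lesions(spec, grid, anat)$occ
        a <- a + lesion_weight_field(occ, anat$annotated,
                                     length(spec$grades))
      }
      a / n_mc
    })
  }
  list(p_field = grid_like(grid, acc),
       gland = grid_like(grid, anat$gland * 1),
       pz = grid_like(grid, anat$pz * 1),
       posterolateral = grid_like(grid, anat$posterolateral * 1),
       annotated_slices = anat$annotated,
       density = list(kind = spec$density_kind,
                      log_mean = spec$density_log_mean,
                      log_sd = spec$density_log_sd,
                      multiplier = spec$lesion_density_multiplier),
       n_mc = n_mc)
}

#' Write / read a phantom cohort directory
#'
#' One subdirectory per patient (standard volumes plus a JSON sidecar) and
#' a cohort-level spec file.
#'
#' @param cohort list of \code{patient_dataset}s from
#'   \code{\link{generate_cohort}}.
#' @param dir cohort directory.
#' @return \code{write_cohort}: \code{dir} invisibly; \code{read_cohort}:
#'   the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort))
    write_patient(cohort[[i]], file.path(dir, sprintf("patient_%03d", i)))
  spec <- attr(cohort, "spec")
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  dirs <- dirs[grepl("patient_\\d+$", dirs)]
  if (length(dirs) == 0) stop(sprintf("no patient directories under %s", dir))
  cohort <- lapply(dirs, read_patient)
  specfile <- file.path(dir, "cohort_spec.json")
  if (file.exists(specfile)) {
    raw <- jsonlite::read_json(specfile, simplifyVector = TRUE)
    attr(cohort, "spec") <- do.call(phantom_spec, raw)
  }
  cohort
}
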