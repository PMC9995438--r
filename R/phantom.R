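#' Specification of a synthetic CT-perfusion brain phantom
#'
#' Describes an ellipsoidal "brain" on a regular voxel grid carrying a
#' nested spherical lesion: a hypoperfused penumbra with an optional
#' ischemic core inside it.  Each tissue compartment (healthy brain,
#' penumbra, core) draws its four perfusion parameters — delay time (DT,
#' seconds), cerebral blood flow (CBF), mean transit time (MTT, seconds)
#' and cerebral blood volume (CBV) — from Gaussian distributions, with
#' additional additive measurement noise on top.  CBF and CBV are in
#' arbitrary units: only the ratio of lesion to healthy CBF matters for the
#' dual-threshold lesion definition, so healthy CBF is normalized to a mean
#' of 100 by default.
#'
#' The default compartment means respect the threshold structure used to
#' define perfusion lesions clinically: penumbra and core DT sit well above
#' the 3 s delay-time threshold, and core CBF sits well below 30% of the
#' healthy CBF mean, so that (in the absence of noise) thresholding a
#' generated study recovers the simulated geometry exactly.
#'
#' @param grid_shape integer vector of length 3, voxel grid dimensions.
#' @param voxel_spacing_mm positive numeric vector of length 3 (mm).
#' @param brain_axes_mm ellipsoid semi-axes of the brain (mm), centered in
#'   the volume.
#' @param lesion_center_mm lesion center (mm) relative to the volume
#'   center; must lie inside the brain ellipsoid.  The default places the
#'   lesion in the left hemisphere (negative x).
#' @param penumbra_radius_mm radius of the spherical perfusion lesion (mm).
#' @param core_radius_mm radius of the spherical core (mm); must not
#'   exceed `penumbra_radius_mm`.  `0` produces a penumbra with no core.
#' @param healthy_params,penumbra_params,core_params named lists with
#'   entries `dt`, `cbf`, `mtt`, `cbv`, each `c(mean, sd)`, giving the
#'   within-compartment parameter distributions.
#' @param noise_sd named numeric vector (`dt`, `cbf`, `mtt`, `cbv`) of
#'   additive Gaussian measurement-noise standard deviations applied to
#'   every brain voxel.
#' @param artifact optional [skull_artifact()] descriptor applied by
#'   [generate_study()] after tissue synthesis.
#' @param seed integer seed; generation is a pure function of the spec.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_study()], [generate_cohort()], [skull_artifact()]
#' @export
#' @examples
#' spec <- phantom_spec(grid_shape = c(24, 24, 16), brain_axes_mm = c(20, 20, 24),
#'                      penumbra_radius_mm = 10, core_radius_mm = 6)
#' st <- generate_study(spec)
#' dim(st$study$dt)
phantom_spec <- function(grid_shape = c(48, 48, 28),
                         voxel_spacing_mm = c(2, 2, 4),
                         brain_axes_mm = c(40, 40, 50),
                         lesion_center_mm = c(-14, 0, 0),
                         penumbra_radius_mm = 18,
                         core_radius_mm = 12,
                         healthy_params = list(
                           dt  = c(mean = 1,   sd = 0.2),
                           cbf = c(mean = 100, sd = 4),
                           mtt = c(mean = 4,   sd = 0.4),
                           cbv = c(mean = 4,   sd = 0.3)),
                         penumbra_params = list(
                           dt  = c(mean = 6,  sd = 0.3),
                           cbf = c(mean = 60, sd = 4),
                           mtt = c(mean = 10, sd = 0.8),
                           cbv = c(mean = 3.5, sd = 0.3)),
                         core_params = list(
                           dt  = c(mean = 8,  sd = 0.4),
                           cbf = c(mean = 10, sd = 4),
                           mtt = c(mean = 14, sd = 1),
                           cbv = c(mean = 1.5, sd = 0.2)),
                         noise_sd = c(dt = 0.15, cbf = 2, mtt = 0.3, cbv = 0.15),
                         artifact = NULL,
                         seed = 1L) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    brain_axes_mm = as.numeric(brain_axes_mm),
    lesion_center_mm = as.numeric(lesion_center_mm),
    penumbra_radius_mm = penumbra_radius_mm,
    core_radius_mm = core_radius_mm,
    healthy_params = healthy_params,
    penumbra_params = penumbra_params,
    core_params = core_params,
    noise_sd = noise_sd,
    artifact = artifact,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 1))
    stop("`grid_shape` must be 3 positive integers", call. = FALSE)
  check_positive(spec$voxel_spacing_mm, "voxel_spacing_mm")
  check_positive(spec$brain_axes_mm, "brain_axes_mm")
  check_positive(spec$penumbra_radius_mm, "penumbra_radius_mm")
  check_positive(spec$core_radius_mm, "core_radius_mm", strict = FALSE)
  if (spec$core_radius_mm > spec$penumbra_radius_mm)
    stop("`core_radius_mm` must not exceed `penumbra_radius_mm` (nested core)",
         call. = FALSE)
  for (nm in c("healthy_params", "penumbra_params", "core_params")) {
    p <- spec[[nm]]
    if (!all(c("dt", "cbf", "mtt", "cbv") %in% names(p)))
      stop(sprintf("`%s` must name dt, cbf, mtt and cbv", nm), call. = FALSE)
    if (any(vapply(p, function(v) v[2] < 0, logical(1))))
      stop(sprintf("`%s` standard deviations must be non-negative", nm),
           call. = FALSE)
  }
  if (spec$penumbra_params$dt[["mean"]] < 3)
    stop("penumbra mean DT must be >= 3 s so the lesion crosses the delay-time threshold",
         call. = FALSE)
  if (spec$core_radius_mm > 0 &&
      spec$core_params$cbf[["mean"]] >= 0.30 * spec$healthy_params$cbf[["mean"]])
    stop("core mean CBF must be below 30% of healthy mean CBF", call. = FALSE)
  if (any(spec$noise_sd < 0))
    stop("`noise_sd` must be non-negative", call. = FALSE)
  if (sum((spec$lesion_center_mm / spec$brain_axes_mm)^2) > 1)
    stop("`lesion_center_mm` lies outside the brain ellipsoid", call. = FALSE)
  invisible(spec)
}

#' Skull-rim artifact descriptor
#'
#' Describes a beam-hardening / partial-volume style artifact confined to a
#' thin rim of brain voxels near the superior brain surface.  The dominant
#' effect is an elevated delay time, which can push rim voxels across the
#' 3 s perfusion-lesion threshold; optional CBF/MTT perturbations let the
#' rim mimic genuine hypoperfusion more aggressively for robustness
#' studies.
#'
#' @param thickness_mm rim thickness measured inward from the brain
#'   surface (mm); must be smaller than the smallest brain semi-axis.
#' @param dt_elevation_s mean delay-time elevation added to rim voxels (s).
#' @param cap_height_fraction fraction of the brain surface covered by the
#'   superior cap carrying the artifact (for a spherical brain, a value
#'   `f` keeps rim voxels with z >= (1 - 2 f) * semi-axis).  Restricting the
#'   rim to a cap keeps artifact components smaller than typical lesions,
#'   as seen clinically near the vertex.
#' @param noise_sd Gaussian noise added to the rim perturbations.
#' @param cbf_offset mean CBF change applied to rim voxels (negative values
#'   mimic artifactual hypoperfusion).
#' @param mtt_offset_modes optional numeric vector of MTT offsets; each rim
#'   voxel receives one mode chosen uniformly at random.  Two well-spaced
#'   modes create an artifact population that is not linearly separable
#'   from penumbra along MTT.
#'
#' @return An object of class `skull_artifact`.
#' @seealso [add_skull_artifact()]
#' @export
skull_artifact <- function(thickness_mm = 4, dt_elevation_s = 4,
                           cap_height_fraction = 0.15, noise_sd = 0.2,
                           cbf_offset = 0, mtt_offset_modes = NULL) {
  if (thickness_mm < 0) stop("`thickness_mm` must be non-negative", call. = FALSE)
  if (dt_elevation_s < 0) stop("`dt_elevation_s` must be non-negative", call. = FALSE)
  if (cap_height_fraction <= 0 || cap_height_fraction > 0.5)
    stop("`cap_height_fraction` must be in (0, 0.5]", call. = FALSE)
  structure(list(thickness_mm = thickness_mm,
                 dt_elevation_s = dt_elevation_s,
                 cap_height_fraction = cap_height_fraction,
                 noise_sd = noise_sd,
                 cbf_offset = cbf_offset,
                 mtt_offset_modes = mtt_offset_modes),
            class = "skull_artifact")
}

#' Generate one synthetic CT-perfusion study
#'
#' Builds the four parameter volumes of a [phantom_spec()]: an ellipsoidal
#' brain whose voxels draw from the healthy compartment, overwritten inside
#' the spherical penumbra and core by the corresponding lesion
#' compartments, plus additive Gaussian measurement noise on every brain
#' voxel.  All values outside the brain mask are exactly zero.  Generation
#' is a pure function of `spec` (including its seed): the same spec always
#' yields bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @param study_id character identifier stored in the study.
#'
#' @return A list with components
#'   \describe{
#'     \item{study}{a `perfusion_study`: `dt`, `cbf`, `mtt`, `cbv` 3D
#'       arrays, `brain_mask` (logical array), `voxel_spacing_mm`,
#'       `study_id`, and `geometry` (brain axes and lesion placement, used
#'       by [add_skull_artifact()]).}
#'     \item{truth}{a `truth_geometry`: the exact linear voxel index sets
#'       of the simulated core and penumbra (`core_idx`, `penumbra_idx`,
#'       mutually exclusive), usable as a gold standard.}
#'   }
#' @export
generate_study <- function(spec, study_id = "phantom") {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  co <- coord_arrays_mm(d, spec$voxel_spacing_mm)
  ax <- spec$brain_axes_mm
  mask <- (co$x / ax[1])^2 + (co$y / ax[2])^2 + (co$z / ax[3])^2 <= 1
  if (!any(mask)) stop("brain ellipsoid contains no voxels", call. = FALSE)

  lc <- spec$lesion_center_mm
  dist2 <- (co$x - lc[1])^2 + (co$y - lc[2])^2 + (co$z - lc[3])^2
  lesion <- mask & dist2 <= spec$penumbra_radius_mm^2
  core <- if (spec$core_radius_mm > 0) mask & dist2 <= spec$core_radius_mm^2
          else array(FALSE, d)
  penumbra <- lesion & !core
  healthy <- mask & !lesion
  if (!any(penumbra)) stop("penumbra region contains no voxels", call. = FALSE)

  regions <- list(healthy = which(healthy), penumbra = which(penumbra),
                  core = which(core))
  params <- list(healthy = spec$healthy_params,
                 penumbra = spec$penumbra_params,
                 core = spec$core_params)
  maps <- c("dt", "cbf", "mtt", "cbv")
  vols <- with_seed(spec$seed, {
    out <- lapply(maps, function(m) {
      v <- array(0, d)
      for (rg in names(regions)) {
        idx <- regions[[rg]]
        if (length(idx)) {
          pm <- params[[rg]][[m]]
          v[idx] <- rnorm(length(idx), pm[["mean"]], pm[["sd"]])
        }
      }
      bm <- which(mask)
      v[bm] <- v[bm] + rnorm(length(bm), 0, spec$noise_sd[[m]])
      v
    })
    names(out) <- maps
    out
  })

  study <- new_perfusion_study(
    dt = vols$dt, cbf = vols$cbf, mtt = vols$mtt, cbv = vols$cbv,
    brain_mask = mask, voxel_spacing_mm = spec$voxel_spacing_mm,
    study_id = study_id,
    geometry = list(brain_axes_mm = ax,
                    lesion_center_mm = lc,
                    penumbra_radius_mm = spec$penumbra_radius_mm,
                    core_radius_mm = spec$core_radius_mm))
  truth <- structure(list(core_idx = regions$core,
                          penumbra_idx = regions$penumbra,
                          dim = d,
                          voxel_spacing_mm = spec$voxel_spacing_mm),
                     class = "truth_geometry")
  if (!is.null(spec$artifact))
    study <- add_skull_artifact(study, spec$artifact, seed = spec$seed + 1L)
  list(study = study, truth = truth)
}

new_perfusion_study <- function(dt, cbf, mtt, cbv, brain_mask,
                                voxel_spacing_mm, study_id,
                                geometry = NULL, artifact_rim = NULL) {
  st <- structure(list(dt = dt, cbf = cbf, mtt = mtt, cbv = cbv,
                       brain_mask = brain_mask,
                       voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                       study_id = study_id,
                       geometry = geometry,
                       artifact_rim = artifact_rim),
                  class = "perfusion_study")
  validate_perfusion_study(st)
  st
}

validate_perfusion_study <- function(study) {
  stopifnot(inherits(study, "perfusion_study"))
  d <- dim(study$brain_mask)
  for (m in c("dt", "cbf", "mtt", "cbv"))
    if (!identical(dim(study[[m]]), d))
      stop("all parameter volumes and the brain mask must share one shape",
           call. = FALSE)
  check_positive(study$voxel_spacing_mm, "voxel_spacing_mm")
  invisible(study)
}

#' @exportS3Method base::print
print.perfusion_study <- function(x, ...) {
  d <- dim(x$brain_mask)
  cat(sprintf("<perfusion_study '%s'> grid %s, spacing %s mm, %d brain voxels\n",
              x$study_id, paste(d, collapse = "x"),
              paste(x$voxel_spacing_mm, collapse = "x"),
              sum(x$brain_mask)))
  invisible(x)
}

#' Convert simulated lesion geometry to a four-class lesion map
#'
#' Renders a `truth_geometry` against a study's brain mask using the
#' standard label coding: 0 background, 1 non-ischemic brain, 2 penumbra,
#' 3 core.
#'
#' @param truth a `truth_geometry` from [generate_study()].
#' @param study the matching `perfusion_study` (supplies the brain mask).
#' @return A `lesion_map`.
#' @export
truth_lesion_map <- function(truth, study) {
  stopifnot(inherits(truth, "truth_geometry"),
            identical(truth$dim, dim(study$brain_mask)))
  labels <- array(0L, truth$dim)
  labels[study$brain_mask] <- 1L
  labels[truth$penumbra_idx] <- 2L
  labels[truth$core_idx] <- 3L
  new_lesion_map(labels, truth$voxel_spacing_mm)
}

#' Add a skull-rim artifact to a study
#'
#' Elevates the delay time (and optionally perturbs CBF and MTT) in a thin
#' rim of brain voxels near the superior brain surface, emulating
#' beam-hardening / partial-volume artifacts that can mimic a perfusion
#' lesion.  The affected voxel set is recorded in the returned study's
#' `artifact_rim` field so tests and evaluations can assert on it.  The
#' true lesion geometry is untouched.
#'
#' @param study a `perfusion_study` generated by [generate_study()] (the
#'   stored brain geometry is used to locate the rim).
#' @param artifact a [skull_artifact()] descriptor.
#' @param seed integer seed for the artifact noise draws.
#' @return The modified `perfusion_study`, with `artifact_rim` set to the
#'   linear indices of rim voxels.
#' @export
add_skull_artifact <- function(study, artifact, seed = 1L) {
  validate_perfusion_study(study)
  stopifnot(inherits(artifact, "skull_artifact"))
  geom <- study$geometry
  if (is.null(geom))
    stop("study carries no brain geometry; only phantom studies support artifact injection",
         call. = FALSE)
  ax <- geom$brain_axes_mm
  if (artifact$thickness_mm >= min(ax))
    stop("`thickness_mm` must be smaller than the smallest brain semi-axis",
         call. = FALSE)
  d <- dim(study$brain_mask)
  co <- coord_arrays_mm(d, study$voxel_spacing_mm)
  r <- sqrt((co$x / ax[1])^2 + (co$y / ax[2])^2 + (co$z / ax[3])^2)
  rad <- sqrt(co$x^2 + co$y^2 + co$z^2)
  # distance to the brain surface along the radial ray
  dist_surf <- ifelse(r > 0, rad * (1 / pmax(r, 1e-12) - 1), min(ax))
  z_min <- (1 - 2 * artifact$cap_height_fraction) * ax[3]
  rim <- study$brain_mask & dist_surf <= artifact$thickness_mm & co$z >= z_min
  idx <- which(rim)
  if (length(idx)) {
    study <- with_seed(seed, {
      n <- length(idx)
      study$dt[idx] <- study$dt[idx] +
        rnorm(n, artifact$dt_elevation_s, artifact$noise_sd)
      if (artifact$cbf_offset != 0)
        study$cbf[idx] <- pmax(0, study$cbf[idx] +
          rnorm(n, artifact$cbf_offset, artifact$noise_sd))
      if (!is.null(artifact$mtt_offset_modes)) {
        modes <- sample(artifact$mtt_offset_modes, n, replace = TRUE)
        study$mtt[idx] <- study$mtt[idx] + rnorm(n, modes, artifact$noise_sd)
      }
      study
    })
  }
  study$artifact_rim <- idx
  study
}

#' Generate a synthetic study cohort
#'
#' Produces `n_images` phantom studies with jittered lesion size and
#' location, of which exactly `n_no_core` carry a penumbra but no core
#' (their core radius is set to zero and, downstream, balanced sampling
#' substitutes extra healthy-tissue voxels for the missing core class).
#' Per-study generation seeds are `seed + i` for study `i`, and jitter
#' draws for study `i` use `seed + n_images + i`, so any single study can
#' be regenerated without rebuilding the cohort.
#'
#' @param n_images number of studies (>= 1).
#' @param n_no_core number of studies without a core (<= `n_images`);
#'   which studies lack a core is chosen deterministically from `seed`.
#' @param base_spec the [phantom_spec()] to jitter.
#' @param seed cohort seed.
#' @param size_jitter multiplicative lesion-radius jitter half-width
#'   (radii scale by a factor uniform in `1 +/- size_jitter`).
#' @param center_jitter_mm additive uniform jitter half-width for each
#'   lesion-center coordinate (mm).
#'
#' @return A list with `studies` (list of `perfusion_study`), `truths`
#'   (list of `truth_geometry`), and `no_core` (indices of the core-free
#'   studies).
#' @export
generate_cohort <- function(n_images, n_no_core = 0, base_spec = phantom_spec(),
                            seed = 1L, size_jitter = 0.08,
                            center_jitter_mm = 3) {
  if (n_images < 1) stop("`n_images` must be >= 1", call. = FALSE)
  if (n_no_core > n_images)
    stop("`n_no_core` must not exceed `n_images`", call. = FALSE)
  validate_phantom_spec(base_spec)
  no_core <- if (n_no_core > 0)
    with_seed(seed, sort(sample.int(n_images, n_no_core))) else integer(0)

  studies <- vector("list", n_images)
  truths <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    jit <- with_seed(seed + n_images + i, {
      list(scale = runif(1, 1 - size_jitter, 1 + size_jitter),
           shift = runif(3, -center_jitter_mm, center_jitter_mm))
    })
    spec_i <- base_spec
    spec_i$penumbra_radius_mm <- base_spec$penumbra_radius_mm * jit$scale
    spec_i$core_radius_mm <- if (i %in% no_core) 0 else
      base_spec$core_radius_mm * jit$scale
    spec_i$lesion_center_mm <- base_spec$lesion_center_mm + jit$shift
    spec_i$seed <- as.integer(seed + i)
    res <- generate_study(spec_i, study_id = sprintf("study%03d", i))
    studies[[i]] <- res$study
    truths[[i]] <- res$truth
  }
  list(studies = studies, truths = truths, no_core = no_core)
}

#' Read or write a phantom specification as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path file path.
#' @return `read_phantom_spec()` returns a `phantom_spec`;
#'   `write_phantom_spec()` returns `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  validate_phantom_spec(spec)
  x <- unclass(spec)
  # named vectors serialize as JSON objects, not bare arrays
  for (nm in c("healthy_params", "penumbra_params", "core_params"))
    x[[nm]] <- lapply(x[[nm]], as.list)
  x$noise_sd <- as.list(x$noise_sd)
  if (!is.null(x$artifact)) x$artifact <- unclass(x$artifact)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  art <- if (!is.null(x$artifact))
    do.call(skull_artifact, x$artifact[!vapply(x$artifact, is.null, logical(1))])
  num <- function(v) { out <- unlist(v); stats::setNames(as.numeric(out), names(out)) }
  phantom_spec(grid_shape = x$grid_shape,
               voxel_spacing_mm = x$voxel_spacing_mm,
               brain_axes_mm = x$brain_axes_mm,
               lesion_center_mm = x$lesion_center_mm,
               penumbra_radius_mm = x$penumbra_radius_mm,
               core_radius_mm = x$core_radius_mm,
               healthy_params = lapply(x$healthy_params, num),
               penumbra_params = lapply(x$penumbra_params, num),
               core_params = lapply(x$core_params, num),
               noise_sd = num(x$noise_sd),
               artifact = art,
               seed = x$seed)
}
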