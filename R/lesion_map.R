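#' Dual-threshold configuration for lesion ground truth
#'
#' The perfusion lesion is the set of brain voxels with delay time at or
#' above `dt_threshold_s`; within it, voxels whose CBF falls strictly
#' below `cbf_relative_threshold` times a reference CBF form the ischemic
#' core, and the remainder the penumbra.  The reference CBF is the mean
#' over presumed-healthy tissue: by default the non-candidate brain of the
#' hemisphere contralateral to the lesion (midline = central sagittal
#' plane of the volume), falling back to the whole non-candidate brain
#' when laterality cannot be established.
#'
#' @param dt_threshold_s delay-time threshold in seconds (default 3,
#'   inclusive).
#' @param cbf_relative_threshold fraction of reference CBF below which a
#'   lesion voxel is core (default 0.30, exclusive).
#' @param reference_region `"contralateral_brain"` or
#'   `"whole_brain_nonlesion"`.
#' @param connectivity connectivity for single-lesion cleanup (6, 18, 26).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(dt_threshold_s = 3.0,
                             cbf_relative_threshold = 0.30,
                             reference_region = c("contralateral_brain",
                                                  "whole_brain_nonlesion"),
                             connectivity = 26) {
  if (dt_threshold_s <= 0) stop("`dt_threshold_s` must be positive", call. = FALSE)
  if (cbf_relative_threshold <= 0 || cbf_relative_threshold >= 1)
    stop("`cbf_relative_threshold` must be in (0, 1)", call. = FALSE)
  structure(list(dt_threshold_s = dt_threshold_s,
                 cbf_relative_threshold = cbf_relative_threshold,
                 reference_region = match.arg(reference_region),
                 connectivity = connectivity),
            class = "threshold_config")
}

new_lesion_map <- function(labels, voxel_spacing_mm) {
  stopifnot(is.integer(labels), length(dim(labels)) == 3,
            all(labels %in% 0:3))
  check_positive(voxel_spacing_mm, "voxel_spacing_mm")
  structure(list(labels = labels,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
            class = "lesion_map")
}

#' @exportS3Method base::print
print.lesion_map <- function(x, ...) {
  tb <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf(paste0("<lesion_map> grid %s | background %d, brain %d, ",
                     "penumbra %d, core %d voxels\n"),
              paste(dim(x$labels), collapse = "x"),
              tb[1], tb[2], tb[3], tb[4]))
  invisible(x)
}

#' Reference CBF for the relative core threshold
#'
#' Mean CBF over presumed-healthy brain tissue, excluding all
#' perfusion-lesion candidate voxels.  With
#' `reference_region = "contralateral_brain"` the mean is restricted to
#' the half of the volume (split at the central sagittal plane) opposite
#' the candidate-mask centroid; if the candidate mask is empty the whole
#' non-candidate brain is used.
#'
#' @param study a `perfusion_study`.
#' @param candidate_mask 3D logical array of perfusion-lesion candidates.
#' @param cfg a [threshold_config()].
#' @return The scalar reference CBF.
#' @export
reference_cbf <- function(study, candidate_mask, cfg = threshold_config()) {
  validate_perfusion_study(study)
  stopifnot(identical(dim(candidate_mask), dim(study$brain_mask)))
  ref <- study$brain_mask & !candidate_mask
  if (cfg$reference_region == "contralateral_brain" && any(candidate_mask)) {
    d1 <- dim(candidate_mask)[1]
    xi <- slice.index(candidate_mask, 1)
    mid <- (d1 + 1) / 2
    lesion_left <- mean(xi[candidate_mask]) < mid
    ref <- ref & (if (lesion_left) xi > mid else xi < mid)
  }
  if (!any(ref))
    stop("reference region is empty: no non-candidate brain tissue available",
         call. = FALSE)
  mean(study$cbf[ref])
}

#' Build the four-class lesion map by dual thresholds
#'
#' Applies the dual-threshold lesion definition to a study: brain voxels
#' with DT >= `dt_threshold_s` form the perfusion-lesion candidate mask;
#' [single_lesion_cleanup()] keeps its largest connected component;
#' surviving voxels with CBF strictly below
#' `cbf_relative_threshold * reference CBF` are labeled core (3) and the
#' rest of the lesion penumbra (2).  Remaining brain voxels are labeled 1
#' and non-brain voxels 0.  The reference CBF excludes the full
#' (pre-cleanup) candidate mask, so artifactual hyperintense regions do
#' not contaminate the reference.
#'
#' @param study a `perfusion_study`.
#' @param cfg a [threshold_config()].
#' @return A `lesion_map`.
#' @export
build_lesion_map <- function(study, cfg = threshold_config()) {
  validate_perfusion_study(study)
  candidate <- study$brain_mask & study$dt >= cfg$dt_threshold_s
  lesion <- single_lesion_cleanup(candidate, cfg$connectivity)
  labels <- array(0L, dim(study$brain_mask))
  labels[study$brain_mask] <- 1L
  if (any(lesion)) {
    ref <- reference_cbf(study, candidate, cfg)
    core <- lesion & study$cbf < cfg$cbf_relative_threshold * ref
    labels[lesion] <- 2L
    labels[core] <- 3L
  }
  new_lesion_map(labels, study$voxel_spacing_mm)
}
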