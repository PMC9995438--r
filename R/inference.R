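#' Predict voxel classes at arbitrary coordinates
#'
#' Extracts the 3x3x3 neighborhood patch at each coordinate, standardizes
#' it with the bundle's frozen training standardizer, and scores it with
#' the fitted classifier.
#'
#' @param study a `perfusion_study`.
#' @param bundle a `ctp_model`.
#' @param coords integer matrix or data frame with columns `x`, `y`, `z`.
#' @return A list with `class` (predicted labels) and `scores`
#'   (n x K matrix, columns named by class).
#' @export
predict_voxels <- function(study, bundle, coords) {
  stopifnot(inherits(bundle, "ctp_model"))
  missing_maps <- setdiff(bundle$feature_maps, c("dt", "cbf", "mtt", "cbv"))
  if (length(missing_maps))
    stop("bundle requires maps absent from the study", call. = FALSE)
  feats <- extract_patches(study, coords, bundle$feature_maps)
  scores <- bundle_scores(bundle, feats)
  list(class = score_to_class(scores, bundle$classes), scores = scores)
}

#' Whole-study voxel-wise prediction and reconstruction
#'
#' Classifies every voxel of a study (by default every brain-mask voxel,
#' with voxels outside the mask forced to class 0) from its standardized
#' 27-value-per-map neighborhood patch, and reassembles the predictions
#' in the study's space as a `lesion_map`.  Voxels are processed in
#' batches of `batch_size`; batching never changes the result.
#'
#' @param study a `perfusion_study`.
#' @param bundle a `ctp_model` from [tune_and_train()].
#' @param batch_size voxels scored per batch.
#' @param mask_only if `TRUE` (default) only brain-mask voxels are
#'   predicted; `FALSE` classifies every voxel of the volume.
#' @param return_scores if `TRUE`, also return the per-voxel class-score
#'   channels.
#' @return A `ctp_prediction`: `predicted` (a `lesion_map`), optional
#'   `scores` (4D array, last dimension one channel per class, with the
#'   predicted label equal to the argmax channel at every scored voxel),
#'   `study_id` and `algorithm`.
#' @export
predict_study <- function(study, bundle, batch_size = 20000L,
                          mask_only = TRUE, return_scores = FALSE) {
  validate_perfusion_study(study)
  stopifnot(inherits(bundle, "ctp_model"), batch_size >= 1)
  d <- dim(study$brain_mask)
  idx <- if (mask_only) which(study$brain_mask) else seq_len(prod(d))
  labels <- array(0L, d)
  scores <- if (return_scores)
    array(0, c(d, length(bundle$classes))) else NULL
  nvox <- prod(d)
  if (length(idx)) {
    co <- arrayInd(idx, d)
    colnames(co) <- c("x", "y", "z")
    starts <- seq(1L, length(idx), by = batch_size)
    for (s in starts) {
      batch <- s:min(s + batch_size - 1L, length(idx))
      pr <- predict_voxels(study, bundle, co[batch, , drop = FALSE])
      labels[idx[batch]] <- pr$class
      if (return_scores)
        for (k in seq_along(bundle$classes))
          scores[idx[batch] + (k - 1L) * nvox] <- pr$scores[, k]
    }
  }
  structure(list(predicted = new_lesion_map(labels, study$voxel_spacing_mm),
                 scores = scores,
                 classes = bundle$classes,
                 study_id = study$study_id,
                 algorithm = bundle$algorithm),
            class = "ctp_prediction")
}

#' @exportS3Method base::print
print.ctp_prediction <- function(x, ...) {
  cat(sprintf("<ctp_prediction '%s' by %s>\n", x$study_id, x$algorithm))
  print(x$predicted)
  invisible(x)
}

#' Post-process a predicted lesion map
#'
#' With `policy = "largest_component"`, keeps only the largest connected
#' component of the predicted lesion (labels 2 and 3 combined, mirroring
#' the single-lesion cleanup used for the ground truth) and relabels
#' removed lesion voxels as non-ischemic brain (1).  The default policy
#' `"none"` returns the raw reconstruction unchanged.
#'
#' @param predicted a `lesion_map` (e.g. `prediction$predicted`).
#' @param policy `"none"` or `"largest_component"`.
#' @param connectivity see [label_components()].
#' @return A `lesion_map`.
#' @export
postprocess_lesion_map <- function(predicted,
                                   policy = c("none", "largest_component"),
                                   connectivity = 26) {
  stopifnot(inherits(predicted, "lesion_map"))
  policy <- match.arg(policy)
  if (policy == "none") return(predicted)
  lesion <- predicted$labels >= 2L
  keep <- single_lesion_cleanup(lesion, connectivity)
  drop <- lesion & !keep
  predicted$labels[drop] <- 1L
  predicted
}
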