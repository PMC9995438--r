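as_binary_mask <- function(m, name) {
  if (is.logical(m)) return(m)
  if (is.numeric(m) && all(m %in% c(0, 1))) return(m != 0)
  stop(sprintf("`%s` must be a logical (or 0/1) mask", name), call. = FALSE)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks agree perfectly (1); if
#' exactly one mask is empty the score is 0.
#'
#' @param a,b binary masks (logical arrays or vectors) of equal shape.
#' @return A number in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("mask shapes differ", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Jaccard index (intersection over union) of two binary masks
#'
#' `|A n B| / |A u B|`, with the same empty-mask conventions as [dsc()].
#' Related to the Dice coefficient by `JI = DSC / (2 - DSC)`.
#'
#' @inheritParams dsc
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- as_binary_mask(a, "a"); b <- as_binary_mask(b, "b")
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop("mask shapes differ", call. = FALSE)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Agreement category for a Dice score
#'
#' Maps a Dice coefficient onto six qualitative agreement bands:
#' exactly 0 is "No Agreement"; then half-open intervals `[lo, hi)` at
#' 0.2/0.4/0.6/0.8 give "Slight", "Fair", "Moderate" and "Substantial"
#' agreement, with `[0.8, 1]` (including 1) "Almost perfect agreement".
#'
#' @param dsc_value numeric vector of Dice scores in `[0, 1]`.
#' @return A character vector of category labels.
#' @export
agreement_category <- function(dsc_value) {
  if (any(!is.finite(dsc_value)) || any(dsc_value < 0) || any(dsc_value > 1))
    stop("`dsc_value` must lie in [0, 1]", call. = FALSE)
  bands <- c("Slight agreement", "Fair agreement", "Moderate agreement",
             "Substantial agreement", "Almost perfect agreement")
  out <- bands[pmin(findInterval(dsc_value, c(0, 0.2, 0.4, 0.6, 0.8)), 5L)]
  out[dsc_value == 0] <- "No Agreement"
  out
}

#' Region volume in milliliters
#'
#' Voxel count times voxel volume (product of the spacings, mm^3),
#' converted to mL.
#'
#' @param mask binary mask.
#' @param voxel_spacing_mm positive spacings (mm) of the three axes.
#' @return Volume in mL.
#' @export
region_volume_ml <- function(mask, voxel_spacing_mm) {
  mask <- as_binary_mask(mask, "mask")
  check_positive(voxel_spacing_mm, "voxel_spacing_mm")
  sum(mask) * prod(voxel_spacing_mm) / 1000
}

#' Per-image core and penumbra overlap metrics
#'
#' Compares a predicted lesion map against the ground truth region by
#' region — core against core (label 3) and penumbra against penumbra
#' (label 2), as binary masks — reporting Dice, Jaccard, both volumes in
#' mL and the qualitative agreement category.
#'
#' @param gt,pred `lesion_map` objects of equal shape.
#' @param study_id identifier copied into the output.
#' @return A data frame with one row per region (`core`, `penumbra`).
#' @export
region_metrics <- function(gt, pred, study_id = NA_character_) {
  stopifnot(inherits(gt, "lesion_map"))
  if (inherits(pred, "ctp_prediction")) pred <- pred$predicted
  stopifnot(inherits(pred, "lesion_map"),
            identical(dim(gt$labels), dim(pred$labels)))
  rows <- lapply(c(core = 3L, penumbra = 2L), function(lab) {
    a <- gt$labels == lab
    b <- pred$labels == lab
    d <- dsc(a, b)
    data.frame(dsc = d, ji = jaccard(a, b),
               gt_volume_ml = region_volume_ml(a, gt$voxel_spacing_mm),
               pred_volume_ml = region_volume_ml(b, pred$voxel_spacing_mm),
               agreement = agreement_category(d))
  })
  cbind(data.frame(study_id = study_id,
                   region = names(rows)),
        do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

paired_t_safe <- function(a, b) {
  dif <- a - b
  if (all(dif == 0)) return(list(statistic = 0, p.value = 1))
  if (sd(dif) == 0) return(list(statistic = sign(mean(dif)) * Inf, p.value = 0))
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

cor_safe <- function(x, y) {
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cohort-level evaluation summary
#'
#' Aggregates per-image region metrics (from [region_metrics()]) into the
#' cohort report: per-region mean and SD of Dice and Jaccard, a paired
#' two-tailed t-test of Dice vs Jaccard, Pearson correlations of each
#' metric with ground-truth volume, and — when follow-up infarct volumes
#' are supplied — the Pearson correlation between predicted core volume
#' and follow-up volume, overall and after excluding artifact-flagged
#' images.
#'
#' @param per_image data frame of stacked [region_metrics()] rows.
#' @param followup_volumes optional numeric vector of follow-up infarct
#'   volumes (mL), one per image in the order the images appear in
#'   `per_image`.
#' @param artifact_flag optional logical vector, one per image, marking
#'   images with visible skull artifacts.
#' @return An object of class `ctp_cohort_report`.
#' @export
cohort_summary <- function(per_image, followup_volumes = NULL,
                           artifact_flag = NULL) {
  stopifnot(is.data.frame(per_image),
            all(c("study_id", "region", "dsc", "ji", "gt_volume_ml",
                  "pred_volume_ml") %in% names(per_image)))
  ids <- unique(per_image$study_id)
  if (length(ids) < 3)
    stop("cohort tests and correlations require at least 3 images", call. = FALSE)
  regions <- lapply(c(core = "core", penumbra = "penumbra"), function(rg) {
    sub <- per_image[per_image$region == rg, ]
    tt <- paired_t_safe(sub$dsc, sub$ji)
    list(n = nrow(sub),
         dsc_mean = mean(sub$dsc), dsc_sd = sd(sub$dsc),
         ji_mean = mean(sub$ji), ji_sd = sd(sub$ji),
         dsc_vs_ji_t = tt$statistic, dsc_vs_ji_p = tt$p.value,
         dsc_vs_volume = cor_safe(sub$dsc, sub$gt_volume_ml),
         ji_vs_volume = cor_safe(sub$ji, sub$gt_volume_ml))
  })
  followup <- NULL
  if (!is.null(followup_volumes)) {
    core <- per_image[per_image$region == "core", ]
    if (length(followup_volumes) != nrow(core))
      stop("`followup_volumes` must supply one volume per image", call. = FALSE)
    followup <- list(all = cor_safe(core$pred_volume_ml, followup_volumes))
    if (!is.null(artifact_flag)) {
      keep <- !artifact_flag
      followup$no_artifact <- cor_safe(core$pred_volume_ml[keep],
                                       followup_volumes[keep])
    }
  }
  structure(list(per_image = per_image, regions = regions,
                 followup = followup),
            class = "ctp_cohort_report")
}

#' @exportS3Method base::print
print.ctp_cohort_report <- function(x, ...) {
  cat(sprintf("<ctp_cohort_report> %d images\n",
              length(unique(x$per_image$study_id))))
  for (rg in names(x$regions)) {
    r <- x$regions[[rg]]
    cat(sprintf("  %-8s DSC %.2f (SD %.2f), JI %.2f (SD %.2f), paired t=%.2f p=%.3g\n",
                rg, r$dsc_mean, r$dsc_sd, r$ji_mean, r$ji_sd,
                r$dsc_vs_ji_t, r$dsc_vs_ji_p))
  }
  if (!is.null(x$followup))
    cat(sprintf("  predicted core vs follow-up volume: r=%.2f p=%.3g\n",
                x$followup$all$r, x$followup$all$p))
  invisible(x)
}
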