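#' Configuration for class-balanced voxel sampling
#'
#' @param n_per_class voxels sampled per class per image (default 300).
#' @param seed integer seed; sampling, splitting and per-study seeds are
#'   derived from it.
#' @param feature_maps ordered subset of `c("dt","cbf","mtt","cbv")` whose
#'   patches are concatenated into each feature row.
#' @param train_fraction fraction of rows assigned to the training split
#'   (default 0.60).
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(n_per_class = 300, seed = 1L,
                            feature_maps = c("dt", "cbf", "mtt", "cbv"),
                            train_fraction = 0.60) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  feature_maps <- match.arg(feature_maps, c("dt", "cbf", "mtt", "cbv"),
                            several.ok = TRUE)
  if (anyDuplicated(feature_maps))
    stop("`feature_maps` must not contain duplicates", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed),
                 feature_maps = feature_maps,
                 train_fraction = train_fraction),
            class = "sampling_config")
}

#' Class-balanced random voxel sampling from a lesion map
#'
#' Samples exactly `n_per_class` voxels uniformly without replacement from
#' each class present in the map (0 background, 1 non-ischemic brain,
#' 2 penumbra, 3 core).  When the core class is absent — a penumbra
#' without core — `n_per_class` *additional* non-ischemic voxels are drawn
#' instead, so every image contributes `4 * n_per_class` samples.  A
#' present class with fewer than `n_per_class` voxels is an error.
#'
#' @param lesion_map a `lesion_map`.
#' @param cfg a [sampling_config()]; `cfg$seed` makes the draw
#'   deterministic.
#' @return A data frame with integer voxel coordinates `x`, `y`, `z` and
#'   the class `label`.
#' @export
sample_voxels <- function(lesion_map, cfg = sampling_config()) {
  stopifnot(inherits(lesion_map, "lesion_map"))
  labels <- lesion_map$labels
  n <- cfg$n_per_class
  counts <- vapply(0:3, function(k) sum(labels == k), integer(1))
  core_absent <- counts[4] == 0L
  take <- ifelse(counts > 0L, n, 0L)
  if (core_absent) take[2] <- take[2] + n  # extra healthy-tissue samples
  short <- which(counts > 0L & counts < take)
  if (length(short))
    stop(sprintf("class %s has only %s voxels; %s required for balanced sampling",
                 paste(short - 1L, collapse = ","),
                 paste(counts[short], collapse = ","),
                 paste(take[short], collapse = ",")),
         call. = FALSE)
  d <- dim(labels)
  with_seed(cfg$seed, {
    rows <- lapply(0:3, function(k) {
      m <- take[k + 1L]
      if (m == 0L) return(NULL)
      idx <- which(labels == k)
      pick <- idx[sample.int(length(idx), m)]
      co <- arrayInd(pick, d)
      data.frame(x = co[, 1], y = co[, 2], z = co[, 3], label = k)
    })
    do.call(rbind, rows)
  })
}

# 27 neighborhood offsets in fixed raster order: dx fastest, then dy, then
# dz, from (-1,-1,-1) to (1,1,1); the center voxel is offset 14.
patch_offsets <- function() {
  as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
}

#' Extract 3x3x3 neighborhood patches as feature rows
#'
#' For each coordinate, collects the 27 values (center voxel plus its 26
#' face/edge/corner neighbors) from each requested parameter map and
#' concatenates them map-by-map into one row.  Neighbors falling outside
#' the volume contribute zeros (zero padding), never missing values.  The
#' offset order is fixed raster order over `(dx, dy, dz)` from
#' `(-1,-1,-1)` to `(1,1,1)` with `dx` varying fastest, so the center
#' voxel occupies position 14 within each 27-column map block.
#'
#' @param study a `perfusion_study`.
#' @param coords integer matrix (or data frame) with columns `x`, `y`,
#'   `z`; all coordinates must lie inside the volume.
#' @param feature_maps ordered subset of `c("dt","cbf","mtt","cbv")`.
#' @return A numeric matrix with `nrow(coords)` rows and
#'   `27 * length(feature_maps)` named columns (`<map>_01` ... `<map>_27`).
#' @export
extract_patches <- function(study, coords,
                            feature_maps = c("dt", "cbf", "mtt", "cbv")) {
  validate_perfusion_study(study)
  co <- as.matrix(coords[, c("x", "y", "z")])
  storage.mode(co) <- "integer"
  d <- dim(study$brain_mask)
  if (any(co < 1L) || any(sweep(co, 2, d, `>`)))
    stop("patch coordinates outside the volume", call. = FALSE)
  offs <- patch_offsets()
  blocks <- lapply(feature_maps, function(m) {
    vol <- study[[m]]
    block <- matrix(0, nrow(co), 27L,
                    dimnames = list(NULL, sprintf("%s_%02d", m, 1:27)))
    for (k in 1:27) {
      nc <- sweep(co, 2, offs[k, ], `+`)
      ok <- nc[, 1] >= 1L & nc[, 1] <= d[1] &
            nc[, 2] >= 1L & nc[, 2] <= d[2] &
            nc[, 3] >= 1L & nc[, 3] <= d[3]
      if (any(ok))
        block[ok, k] <- vol[coords_to_index(nc[ok, , drop = FALSE], d)]
    }
    block
  })
  do.call(cbind, blocks)
}

#' @rdname extract_patches
#' @param x,y,z a single voxel coordinate.
#' @export
extract_patch <- function(study, x, y, z,
                          feature_maps = c("dt", "cbf", "mtt", "cbv")) {
  drop(extract_patches(study, data.frame(x = x, y = y, z = z), feature_maps))
}

new_patch_matrix <- function(features, labels, provenance, feature_maps) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            nrow(features) == nrow(provenance))
  structure(list(features = features,
                 labels = as.integer(labels),
                 provenance = provenance,
                 feature_maps = feature_maps),
            class = "patch_matrix")
}

#' @exportS3Method base::print
print.patch_matrix <- function(x, ...) {
  cat(sprintf("<patch_matrix> %d rows x %d features (%s), classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(x$feature_maps, collapse = ","),
              paste(sprintf("%d=%d", 0:3, tabulate(x$labels + 1L, 4L)),
                    collapse = " ")))
  invisible(x)
}

#' @exportS3Method
dim.patch_matrix <- function(x) dim(x$features)

# Row subset that keeps features, labels and provenance aligned.
subset_rows <- function(pm, i) {
  new_patch_matrix(pm$features[i, , drop = FALSE], pm$labels[i],
                   pm$provenance[i, , drop = FALSE], pm$feature_maps)
}

#' Restrict a patch matrix to a subset of parameter maps
#'
#' Selects the 27-column blocks of the requested maps (in the requested
#' order) without re-sampling, so a two-map matrix is an exact column
#' subset of the four-map matrix built from the same draw.
#'
#' @param pm a `patch_matrix`.
#' @param feature_maps ordered subset of `pm$feature_maps`.
#' @return A `patch_matrix`.
#' @export
subset_feature_maps <- function(pm, feature_maps) {
  stopifnot(inherits(pm, "patch_matrix"))
  if (!all(feature_maps %in% pm$feature_maps))
    stop("requested maps not present in the patch matrix", call. = FALSE)
  cols <- unlist(lapply(feature_maps, function(m) sprintf("%s_%02d", m, 1:27)))
  new_patch_matrix(pm$features[, cols, drop = FALSE], pm$labels,
                   pm$provenance, feature_maps)
}

#' Build the training matrix over a cohort
#'
#' Runs [sample_voxels()] and [extract_patches()] over aligned lists of
#' studies and lesion maps and stacks the per-image rows into one
#' `patch_matrix`.  The per-image sampling seed is `cfg$seed + i - 1` for
#' image `i`, so the build is reproducible as a whole and per image.
#'
#' @param studies list of `perfusion_study`.
#' @param lesion_maps list of `lesion_map`, aligned one-to-one with
#'   `studies`.
#' @param cfg a [sampling_config()].
#' @return A `patch_matrix` with per-row provenance (`study_id`, `x`,
#'   `y`, `z`).
#' @export
build_patch_matrix <- function(studies, lesion_maps, cfg = sampling_config()) {
  if (length(studies) != length(lesion_maps))
    stop("`studies` and `lesion_maps` must be aligned one-to-one", call. = FALSE)
  parts <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    sv <- tryCatch(sample_voxels(lesion_maps[[i]], cfg_i),
                   error = function(e)
                     stop(sprintf("study '%s': %s", st$study_id,
                                  conditionMessage(e)), call. = FALSE))
    feats <- extract_patches(st, sv, cfg$feature_maps)
    parts[[i]] <- list(features = feats, labels = sv$label,
                       provenance = data.frame(study_id = st$study_id,
                                               sv[, c("x", "y", "z")]))
  }
  new_patch_matrix(do.call(rbind, lapply(parts, `[[`, "features")),
                   unlist(lapply(parts, `[[`, "labels")),
                   do.call(rbind, lapply(parts, `[[`, "provenance")),
                   cfg$feature_maps)
}

#' Split a patch matrix into training and validation rows
#'
#' Random row-level split: `round(n * train_fraction)` rows go to
#' training, the rest to validation; every row lands in exactly one side.
#'
#' @param pm a `patch_matrix`.
#' @param cfg a [sampling_config()]; uses `train_fraction` and `seed`.
#' @return A list with `train` and `validation` patch matrices.
#' @export
split_train_validation <- function(pm, cfg = sampling_config()) {
  stopifnot(inherits(pm, "patch_matrix"))
  n <- nrow(pm$features)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  n_train <- round(n * cfg$train_fraction)
  idx <- with_seed(cfg$seed, sample.int(n, n_train))
  list(train = subset_rows(pm, sort(idx)),
       validation = subset_rows(pm, setdiff(seq_len(n), idx)))
}

#' Fit and apply a per-column standardizer
#'
#' `fit_standardizer()` learns per-column means and standard deviations
#' from the training rows only; `apply_standardizer()` centers and scales
#' any matrix with those frozen moments (validation and test data are
#' never re-estimated).  Zero-variance columns are centered and passed
#' through with scale 1, so constant columns become all zeros.
#'
#' @param pm a `patch_matrix` (training rows).
#' @return `fit_standardizer()` returns a `ctp_standardizer`;
#'   `apply_standardizer()` returns a `patch_matrix` with transformed
#'   features.
#' @export
fit_standardizer <- function(pm) {
  stopifnot(inherits(pm, "patch_matrix"), nrow(pm$features) > 0)
  center <- colMeans(pm$features)
  scale <- apply(pm$features, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale,
                 columns = colnames(pm$features)),
            class = "ctp_standardizer")
}

#' @rdname fit_standardizer
#' @param s a `ctp_standardizer`.
#' @param newdata a `patch_matrix` or bare feature matrix with the same
#'   columns the standardizer was fitted on.
#' @export
apply_standardizer <- function(s, newdata) {
  stopifnot(inherits(s, "ctp_standardizer"))
  feats <- if (inherits(newdata, "patch_matrix")) newdata$features else newdata
  if (!identical(colnames(feats), s$columns))
    stop("column mismatch between standardizer and data", call. = FALSE)
  out <- sweep(sweep(feats, 2, s$center), 2, s$scale, `/`)
  if (inherits(newdata, "patch_matrix")) {
    newdata$features <- out
    newdata
  } else out
}
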