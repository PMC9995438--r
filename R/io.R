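# NIfTI input/output for studies and lesion maps, via RNifti.

study_file_suffixes <- c(dt = "_dt.nii.gz", cbf = "_cbf.nii.gz",
                         mtt = "_mtt.nii.gz", cbv = "_cbv.nii.gz",
                         mask = "_mask.nii.gz")

write_volume <- function(arr, spacing, path) {
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write and read a perfusion study as NIfTI volumes
#'
#' Each study is stored as five co-registered volumes named
#' `<id>_dt.nii.gz`, `<id>_cbf.nii.gz`, `<id>_mtt.nii.gz`,
#' `<id>_cbv.nii.gz` and `<id>_mask.nii.gz`, with the voxel spacing in
#' the NIfTI header.
#'
#' @param study a `perfusion_study`.
#' @param dir output directory (created if missing).
#' @return `write_study()` returns the written file paths invisibly;
#'   `read_study()` returns a `perfusion_study`.
#' @export
write_study <- function(study, dir) {
  validate_perfusion_study(study)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- study$voxel_spacing_mm
  paths <- character(0)
  for (m in c("dt", "cbf", "mtt", "cbv")) {
    p <- file.path(dir, paste0(study$study_id, study_file_suffixes[[m]]))
    write_volume(study[[m]], sp, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0(study$study_id, study_file_suffixes[["mask"]]))
  write_volume(study$brain_mask * 1L, sp, p)
  invisible(c(paths, p))
}

#' @rdname write_study
#' @param study_id study identifier (file-name prefix).
#' @export
read_study <- function(dir, study_id) {
  vols <- lapply(c("dt", "cbf", "mtt", "cbv", "mask"), function(m) {
    p <- file.path(dir, paste0(study_id, study_file_suffixes[[m]]))
    if (!file.exists(p)) stop(sprintf("missing volume: %s", p), call. = FALSE)
    RNifti::readNifti(p)
  })
  spacing <- RNifti::pixdim(vols[[1]])[1:3]
  new_perfusion_study(dt = as.array(vols[[1]]), cbf = as.array(vols[[2]]),
                      mtt = as.array(vols[[3]]), cbv = as.array(vols[[4]]),
                      brain_mask = as.array(vols[[5]]) != 0,
                      voxel_spacing_mm = spacing, study_id = study_id)
}

#' Write and read a lesion map as an integer NIfTI label volume
#'
#' Uses the standard 0-3 class coding (0 background, 1 non-ischemic
#' brain, 2 penumbra, 3 core).
#'
#' @param lesion_map a `lesion_map`.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `write_lesion_map()` returns `path` invisibly;
#'   `read_lesion_map()` returns a `lesion_map`.
#' @export
write_lesion_map <- function(lesion_map, path) {
  stopifnot(inherits(lesion_map, "lesion_map"))
  write_volume(lesion_map$labels, lesion_map$voxel_spacing_mm, path)
}

#' @rdname write_lesion_map
#' @export
read_lesion_map <- function(path) {
  im <- RNifti::readNifti(path)
  labels <- as.array(im)
  storage.mode(labels) <- "integer"
  new_lesion_map(labels, RNifti::pixdim(im)[1:3])
}

#' Write a patch matrix as CSV
#'
#' One row per sample: the named feature columns, then `label`,
#' `study_id` and the voxel coordinate `x`, `y`, `z`.
#'
#' @param pm a `patch_matrix`.
#' @param path CSV file path.
#' @return `write_patch_matrix_csv()` returns `path` invisibly;
#'   `read_patch_matrix_csv()` returns a `patch_matrix`.
#' @export
write_patch_matrix_csv <- function(pm, path) {
  stopifnot(inherits(pm, "patch_matrix"))
  df <- cbind(as.data.frame(pm$features), label = pm$labels, pm$provenance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_matrix_csv
#' @export
read_patch_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("label", "study_id", "x", "y", "z")
  feat_cols <- setdiff(names(df), meta)
  maps <- unique(sub("_[0-9]+$", "", feat_cols))
  new_patch_matrix(as.matrix(df[, feat_cols]), df$label,
                   df[, c("study_id", "x", "y", "z")], maps)
}
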