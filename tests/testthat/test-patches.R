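make_map_and_study <- function(seed = 1, core_radius_mm = 6) {
  res <- generate_study(small_spec(seed = seed, core_radius_mm = core_radius_mm))
  list(study = res$study, map = build_lesion_map(res$study), truth = res$truth)
}

test_that("balanced sampling draws n voxels per present class", {
  fx <- make_map_and_study()
  sv <- sample_voxels(fx$map, sampling_config(n_per_class = 20, seed = 3))
  expect_identical(nrow(sv), 80L)
  expect_true(all(table(sv$label) == 20))
  # sampled coordinates carry the class they claim
  lab_at <- fx$map$labels[cbind(sv$x, sv$y, sv$z)]
  expect_identical(lab_at, sv$label)
  # no duplicate voxels within a class (sampling without replacement)
  expect_false(anyDuplicated(sv[c("x", "y", "z", "label")]) > 0)
  # minimal draw: one voxel per class
  expect_identical(nrow(sample_voxels(fx$map, sampling_config(n_per_class = 1, seed = 1))), 4L)
})

test_that("missing core is backfilled with extra healthy-tissue samples", {
  fx <- make_map_and_study(core_radius_mm = 0)
  expect_identical(sum(fx$map$labels == 3L), 0L)
  sv <- sample_voxels(fx$map, sampling_config(n_per_class = 20, seed = 3))
  expect_identical(nrow(sv), 80L)
  counts <- table(factor(sv$label, levels = 0:3))
  expect_identical(as.integer(counts), c(20L, 40L, 20L, 0L))
})

test_that("under-populated classes are a sampling error", {
  fx <- make_map_and_study()
  expect_error(sample_voxels(fx$map, sampling_config(n_per_class = 500)),
               "voxels")
})

test_that("patches hold 27 values per map in fixed raster order", {
  fx <- make_map_and_study()
  row <- extract_patch(fx$study, 12, 12, 8)
  expect_length(row, 27 * 4)
  expect_identical(names(row)[1:27], sprintf("dt_%02d", 1:27))
  # offset 14 is the center voxel of each block
  expect_identical(unname(row["dt_14"]), fx$study$dt[12, 12, 8])
  expect_identical(unname(row["cbv_14"]), fx$study$cbv[12, 12, 8])
  # constant map: every entry of its interior block equals the constant
  st <- fx$study
  st$mtt[] <- 7
  row2 <- extract_patch(st, 12, 12, 8, feature_maps = "mtt")
  expect_true(all(row2 == 7))
})

test_that("out-of-volume neighbors are zero padded, never missing", {
  fx <- make_map_and_study()
  st <- fx$study
  st$dt[] <- 5  # make every in-volume value visibly nonzero
  row <- extract_patch(st, 1, 1, 1, feature_maps = "dt")
  # brute-force count of in-bounds offsets at a corner of a 3D grid
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  inb <- rowSums(offs + 1 >= 1 & sweep(offs + 1, 2, dim(st$dt), `<=`)) == 3
  expect_identical(sum(row != 0), sum(inb))
  expect_identical(sum(row == 0), sum(!inb))
  expect_false(anyNA(row))
  expect_error(extract_patch(st, 0, 1, 1), "outside")
  expect_error(extract_patch(st, 25, 1, 1), "outside")
})

test_that("zero padding makes patch extraction linear in the study", {
  a <- generate_study(small_spec(seed = 5))$study
  b <- generate_study(small_spec(seed = 6))$study
  ab <- a
  for (m in c("dt", "cbf", "mtt", "cbv")) ab[[m]] <- a[[m]] + b[[m]]
  coords <- data.frame(x = c(1, 5, 24), y = c(1, 12, 24), z = c(1, 8, 16))
  expect_equal(extract_patches(ab, coords),
               extract_patches(a, coords) + extract_patches(b, coords))
})

test_that("cohort matrices stack per-image samples reproducibly", {
  ch <- generate_cohort(3, 1, small_spec(), seed = 11)
  maps <- lapply(ch$studies, build_lesion_map)
  cfg <- sampling_config(n_per_class = 15, seed = 11)
  pm <- build_patch_matrix(ch$studies, maps, cfg)
  expect_identical(nrow(pm$features), 3L * 4L * 15L)
  expect_identical(ncol(pm$features), 108L)
  expect_identical(sort(unique(pm$provenance$study_id)),
                   sort(vapply(ch$studies, `[[`, "", "study_id")))
  pm2 <- build_patch_matrix(ch$studies, maps, cfg)
  expect_identical(pm$features, pm2$features)
  # feature rows match direct patch extraction at the recorded provenance
  i <- c(1L, 50L, 120L)
  st_of <- function(id) ch$studies[[match(id, vapply(ch$studies, `[[`, "", "study_id"))]]
  for (r in i) {
    st <- st_of(pm$provenance$study_id[r])
    expect_equal(pm$features[r, ],
                 extract_patch(st, pm$provenance$x[r], pm$provenance$y[r],
                               pm$provenance$z[r]))
  }
})

test_that("train/validation split partitions rows at the configured fraction", {
  pm <- separable_patch_matrix(n_per_class = 10)  # 40 rows
  sp <- split_train_validation(pm, sampling_config(train_fraction = 0.6, seed = 2))
  expect_identical(nrow(sp$train$features), 24L)
  expect_identical(nrow(sp$validation$features), 16L)
  # partition: every row lands on exactly one side
  key <- function(p) paste(p$provenance$x, p$labels)
  expect_setequal(c(key(sp$train), key(sp$validation)), key(pm))
  expect_length(intersect(key(sp$train), key(sp$validation)), 0)
  sp2 <- split_train_validation(pm, sampling_config(train_fraction = 0.6, seed = 2))
  expect_identical(sp$train$features, sp2$train$features)
  # 10 rows at 0.6 -> 6 + 4
  sp3 <- split_train_validation(ctpseg:::subset_rows(pm, 1:10),
                                sampling_config(train_fraction = 0.6, seed = 1))
  expect_identical(nrow(sp3$train$features), 6L)
})

test_that("standardizer freezes training moments and never re-estimates", {
  pm <- separable_patch_matrix(n_per_class = 30, seed = 7)
  sp <- split_train_validation(pm, sampling_config(seed = 7))
  s <- fit_standardizer(sp$train)
  z <- apply_standardizer(s, sp$train)
  expect_equal(unname(colMeans(z$features)), rep(0, ncol(z$features)))
  expect_equal(unname(apply(z$features, 2, sd)), rep(1, ncol(z$features)))
  # constant column collapses to zeros
  pm2 <- sp$train
  pm2$features[, 1] <- 42
  z2 <- apply_standardizer(fit_standardizer(pm2), pm2)
  expect_true(all(z2$features[, 1] == 0))
  # transforming different validation data never changes the moments used
  v1 <- apply_standardizer(s, sp$validation)
  pert <- sp$validation
  pert$features <- pert$features + 100
  v2 <- apply_standardizer(s, pert)
  expect_equal(v2$features, v1$features + 100 / rep(s$scale, each = nrow(v1$features)))
  expect_error(apply_standardizer(s, pm$features[, 1:10]), "mismatch")
})

test_that("two-map features are an exact column block of the four-map matrix", {
  fx <- make_map_and_study()
  pm <- build_patch_matrix(list(fx$study), list(fx$map),
                           sampling_config(n_per_class = 10, seed = 2))
  sub <- subset_feature_maps(pm, c("dt", "cbf"))
  expect_identical(sub$features,
                   pm$features[, c(sprintf("dt_%02d", 1:27),
                                   sprintf("cbf_%02d", 1:27))])
  expect_identical(sub$labels, pm$labels)
  expect_error(subset_feature_maps(sub, "mtt"), "not present")
})
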