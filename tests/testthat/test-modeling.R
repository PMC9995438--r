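fast_cfg <- function(alg, fs = "two_map", seed = 1, ...) {
  model_config(alg, fs, random_candidates = 2, grid_refine = FALSE,
               cv_folds = 2, seed = seed, ...)
}

test_that("every learner fits a well-separated matrix perfectly", {
  pm <- separable_patch_matrix(n_per_class = 40, seed = 3)
  sp <- split_train_validation(pm, sampling_config(seed = 3))
  for (alg in c("LR", "RF", "XGB", "SVM")) {
    b <- tune_and_train(sp$train, fast_cfg(alg, seed = 5))
    m <- evaluate_on_validation(b, sp$validation)
    expect_identical(m$accuracy, 1)
    expect_equal(m$auc_macro, 1)
    expect_true(all(m$per_class$dsc == 1))
    expect_true(all(m$per_class$ji == 1))
  }
})

test_that("logistic regression is multinomial over all four classes", {
  pm <- separable_patch_matrix(n_per_class = 30)
  b <- tune_and_train(pm, fast_cfg("LR"))
  expect_identical(b$classes, 0:3)
  sc <- ctpseg:::bundle_scores(b, pm$features)
  expect_identical(dim(sc), c(nrow(pm$features), 4L))
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)))  # class probabilities
})

test_that("tuning is deterministic in the configuration seed", {
  pm <- separable_patch_matrix(n_per_class = 25, seed = 2)
  b1 <- tune_and_train(pm, model_config("XGB", "two_map", random_candidates = 3,
                                        grid_refine = TRUE, cv_folds = 2, seed = 8))
  b2 <- tune_and_train(pm, model_config("XGB", "two_map", random_candidates = 3,
                                        grid_refine = TRUE, cv_folds = 2, seed = 8))
  expect_identical(b1$best_params, b2$best_params)
  expect_identical(b1$cv_score, b2$cv_score)
  b3 <- tune_and_train(pm, model_config("XGB", "two_map", random_candidates = 3,
                                        grid_refine = TRUE, cv_folds = 2, seed = 9))
  expect_false(identical(b1$search_trace, b3$search_trace))
})

test_that("hyperparameter choice never sees validation rows", {
  pm <- separable_patch_matrix(n_per_class = 30, seed = 4)
  sp <- split_train_validation(pm, sampling_config(seed = 4))
  b <- tune_and_train(sp$train, fast_cfg("XGB"))
  # evaluating on wildly perturbed validation data returns different
  # metrics but the bundle (hyperparameters, standardizer) is untouched
  pert <- sp$validation
  pert$features <- pert$features + 50
  m1 <- evaluate_on_validation(b, sp$validation)
  m2 <- evaluate_on_validation(b, pert)
  expect_false(isTRUE(all.equal(m1$accuracy, m2$accuracy)))
  b2 <- tune_and_train(sp$train, fast_cfg("XGB"))
  expect_identical(b$best_params, b2$best_params)
  expect_identical(b$standardizer, b2$standardizer)
})

test_that("uninformative features score near-chance AUC", {
  pm <- separable_patch_matrix(n_per_class = 1000, sep = 0, seed = 12)
  sp <- split_train_validation(pm, sampling_config(seed = 12))
  b <- tune_and_train(sp$train, fast_cfg("LR"))
  m <- evaluate_on_validation(b, sp$validation)
  expect_lt(abs(m$auc_macro - 0.5), 0.05)
})

test_that("degenerate training inputs are rejected", {
  pm <- separable_patch_matrix(n_per_class = 10)
  single <- ctpseg:::subset_rows(pm, which(pm$labels == 2L))
  expect_error(tune_and_train(single, fast_cfg("XGB")), "2 classes")
  expect_error(tune_and_train(pm, fast_cfg("XGB", fs = "four_map")),
               "not present")
  expect_error(model_config("XGB", cv_folds = 1), "cv_folds")
  expect_error(model_config("XGB", random_candidates = 0), "candidates")
})

test_that("four maps win when only MTT separates the classes", {
  pm <- separable_patch_matrix(n_per_class = 60, maps = c("dt", "cbf", "mtt", "cbv"),
                               seed = 6, signal_maps = "mtt")
  sp <- split_train_validation(pm, sampling_config(seed = 6))
  cmp <- compare_feature_sets(sp$train, sp$validation, algorithm = "XGB",
                              seed = 6, random_candidates = 2,
                              grid_refine = FALSE, cv_folds = 2)
  acc2 <- cmp$comparison$accuracy[cmp$comparison$feature_set == "two_map"]
  acc4 <- cmp$comparison$accuracy[cmp$comparison$feature_set == "four_map"]
  expect_lt(acc2, 0.5)   # DT/CBF carry no signal
  expect_gt(acc4, 0.95)
  expect_gt(acc4, acc2 + 0.4)
  expect_identical(cmp$two_map$bundle$n_features, 54L)
  expect_identical(cmp$four_map$bundle$n_features, 108L)
})

test_that("model bundles survive serialization without metric change", {
  pm <- separable_patch_matrix(n_per_class = 60, seed = 9)
  sp <- split_train_validation(pm, sampling_config(seed = 9))
  for (alg in c("XGB", "LR")) {
    b <- tune_and_train(sp$train, fast_cfg(alg))
    f <- tempfile(fileext = ".bundle")
    on.exit(unlink(f), add = TRUE)
    save_model(b, f)
    b2 <- load_model(f)
    m1 <- evaluate_on_validation(b, sp$validation)
    m2 <- evaluate_on_validation(b2, sp$validation)
    expect_identical(m1$auc_macro, m2$auc_macro)
    expect_identical(m1$per_class, m2$per_class)
    expect_identical(b2$best_params, b$best_params)
  }
})

test_that("the shipped search ranges cover all four algorithms", {
  rg <- hyperparameter_ranges()
  expect_setequal(intersect(names(rg), c("LR", "RF", "XGB", "SVM")),
                  c("LR", "RF", "XGB", "SVM"))
  expect_setequal(unlist(rg$SVM$params$kernel$values),
                  c("polynomial", "linear"))
  expect_length(rg$SVM$refine, 0)  # no grid refinement for SVM
})
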