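#' Configuration for classifier tuning and training
#'
#' @param algorithm one of `"LR"` (multinomial elastic-net logistic
#'   regression), `"RF"` (random forest), `"XGB"` (gradient-boosted
#'   trees) or `"SVM"` (support vector machine; only polynomial and linear
#'   kernels are searched and grid refinement is skipped).
#' @param feature_set `"four_map"` (DT, CBF, MTT, CBV) or `"two_map"`
#'   (DT, CBF).
#' @param random_candidates number of random hyperparameter candidates.
#' @param grid_refine whether to refine around the best random candidate
#'   with a local grid (ignored for SVM).
#' @param cv_folds number of cross-validation folds (>= 2, default 3).
#' @param seed integer seed controlling candidate draws, fold assignment
#'   and any stochastic fitting.
#' @param n_jobs threads passed to learners that support them.
#' @return An object of class `model_config`.
#' @export
model_config <- function(algorithm = c("XGB", "RF", "SVM", "LR"),
                         feature_set = c("four_map", "two_map"),
                         random_candidates = 10, grid_refine = TRUE,
                         cv_folds = 3, seed = 1L, n_jobs = 1L) {
  if (cv_folds < 2) stop("`cv_folds` must be >= 2", call. = FALSE)
  if (random_candidates < 1) stop("`random_candidates` must be >= 1", call. = FALSE)
  structure(list(algorithm = match.arg(algorithm),
                 feature_set = match.arg(feature_set),
                 random_candidates = as.integer(random_candidates),
                 grid_refine = isTRUE(grid_refine),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed),
                 n_jobs = as.integer(n_jobs)),
            class = "model_config")
}

feature_set_maps <- function(feature_set) {
  switch(feature_set,
         two_map = c("dt", "cbf"),
         four_map = c("dt", "cbf", "mtt", "cbv"),
         stop("unknown feature set", call. = FALSE))
}

#' Randomized-search hyperparameter ranges
#'
#' Returns the per-algorithm search ranges shipped with the package
#' (`inst/extdata/hyperparameter-ranges.json`), so search spaces are
#' versioned alongside the code.
#'
#' @return A named list, one entry per algorithm, each with `params`
#'   (distributions) and `refine` (parameters grid-refined around the best
#'   random candidate).
#' @export
hyperparameter_ranges <- function() {
  path <- system.file("extdata", "hyperparameter-ranges.json",
                      package = "ctpseg", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

draw_param <- function(rng) {
  switch(rng$dist,
         uniform = runif(1, rng$low, rng$high),
         loguniform = exp(runif(1, log(rng$low), log(rng$high))),
         int = sample(seq.int(rng$low, rng$high), 1),
         choice = sample(unlist(rng$values), 1),
         stop("unknown distribution", call. = FALSE))
}

# Random candidates; for SVM the kernel cycles through the two allowed
# kernels so both are always represented in the search.
sample_candidates <- function(algorithm, n, seed, ranges = hyperparameter_ranges()) {
  rgs <- ranges[[algorithm]]$params
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cand <- lapply(rgs, draw_param)
      if (algorithm == "SVM")
        cand$kernel <- unlist(rgs$kernel$values)[(i - 1) %% 2 + 1]
      cand
    })
  })
}

# Local grid around the best candidate: each refine parameter takes its
# best value plus a lower and upper neighbor clamped to the search range.
refine_grid <- function(algorithm, best, ranges = hyperparameter_ranges()) {
  spec <- ranges[[algorithm]]
  refine <- unlist(spec$refine)
  if (!length(refine)) return(list())
  vals <- lapply(refine, function(p) {
    rng <- spec$params[[p]]
    b <- best[[p]]
    v <- switch(rng$dist,
                loguniform = c(b / 2, b, b * 2),
                uniform = b + c(-1, 0, 1) * (rng$high - rng$low) / 4,
                int = b + c(-1, 0, 1) * max(1L, round((rng$high - rng$low) / 8)))
    v <- pmin(pmax(v, rng$low), rng$high)
    if (rng$dist == "int") v <- as.integer(round(v))
    sort(unique(v))
  })
  names(vals) <- refine
  grid <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    cand <- best
    for (p in refine) cand[[p]] <- grid[i, p]
    cand
  })
}

fit_classifier <- function(algorithm, x, y, classes, params, seed, n_jobs = 1L) {
  yf <- factor(y, levels = classes)
  switch(algorithm,
    LR = glmnet::glmnet(x, yf, family = "multinomial",
                        alpha = params$alpha, lambda = params$lambda),
    RF = ranger::ranger(x = x, y = yf, probability = TRUE,
                        num.trees = params$num.trees,
                        mtry = min(params$mtry, ncol(x)),
                        min.node.size = params$min.node.size,
                        sample.fraction = params$sample.fraction,
                        seed = seed, num.threads = n_jobs),
    XGB = with_seed(seed, xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes),
                    tree_method = "hist",
                    eta = params$eta,
                    max_depth = params$max_depth,
                    min_child_weight = params$min_child_weight,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    nthread = n_jobs, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = match(y, classes) - 1L,
                                  nthread = n_jobs),
      nrounds = params$nrounds, verbose = 0)),
    SVM = e1071::svm(x, yf, kernel = params$kernel, cost = params$cost,
                     degree = params$degree %||% 3, coef0 = 1,
                     gamma = 1 / ncol(x), scale = FALSE),
    stop("unknown algorithm", call. = FALSE))
}

# n x K score matrix (probabilities, or aggregated decision values for
# SVM), columns named by class.
classifier_scores <- function(algorithm, fit, x, classes) {
  cls <- as.character(classes)
  out <- switch(algorithm,
    LR = {
      p <- predict(fit, x, type = "response")
      p <- p[, , 1, drop = TRUE]
      if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
      p[, cls, drop = FALSE]
    },
    RF = predict(fit, data = x, num.threads = 1L)$predictions[, cls, drop = FALSE],
    XGB = {
      p <- predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L))
      colnames(p) <- cls
      p
    },
    SVM = {
      # one-vs-one voting; summed decision values only break vote ties
      # (pairwise decision scales are not comparable across pairs)
      pr <- predict(fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      votes <- matrix(0, nrow(x), length(cls), dimnames = list(NULL, cls))
      tie <- votes
      for (cn in colnames(dv)) {
        pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
        win <- dv[, cn] > 0
        votes[, pair[1]] <- votes[, pair[1]] + win
        votes[, pair[2]] <- votes[, pair[2]] + !win
        tie[, pair[1]] <- tie[, pair[1]] + dv[, cn]
        tie[, pair[2]] <- tie[, pair[2]] - dv[, cn]
      }
      votes + 0.5 * stats::plogis(tie)
    })
  out
}

score_to_class <- function(scores, classes) {
  classes[max.col(scores, ties.method = "first")]
}

cv_score <- function(algorithm, x, y, classes, params, folds, seed, n_jobs) {
  acc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fit_classifier(algorithm, x[tr, , drop = FALSE], y[tr], classes,
                          params, seed, n_jobs)
    sc <- classifier_scores(algorithm, fit, x[!tr, , drop = FALSE], classes)
    mean(score_to_class(sc, classes) == y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Tune and train a classifier on a patch matrix
#'
#' Reproduces the optimization protocol at configurable scale: a
#' randomized search over the documented per-algorithm hyperparameter
#' ranges, scored by `cv_folds`-fold cross-validated accuracy on the
#' training rows, optionally refined by a local grid around the best
#' random candidate, followed by a refit of the winning configuration on
#' all training rows.  For SVM only polynomial and linear kernels are
#' searched and the grid-refinement step is skipped.  The standardizer is
#' fitted on the training rows inside this function and stored in the
#' bundle, so validation or test data can never leak into either the
#' feature scaling or the hyperparameter choice.
#'
#' @param train a `patch_matrix` of training rows (unstandardized; built
#'   with at least the maps of `cfg$feature_set`).
#' @param cfg a [model_config()].
#' @return A `ctp_model` bundle: fitted classifier, frozen standardizer,
#'   configuration, chosen hyperparameters and the search trace.
#' @export
tune_and_train <- function(train, cfg = model_config()) {
  stopifnot(inherits(train, "patch_matrix"), inherits(cfg, "model_config"))
  maps <- feature_set_maps(cfg$feature_set)
  pm <- subset_feature_maps(train, maps)
  if (ncol(pm$features) != 27L * length(maps))
    stop("feature dimensionality does not match the feature set", call. = FALSE)
  classes <- sort(unique(pm$labels))
  if (length(classes) < 2)
    stop("training data must contain at least 2 classes", call. = FALSE)

  std <- fit_standardizer(pm)
  x <- apply_standardizer(std, pm$features)
  y <- pm$labels
  folds <- with_seed(cfg$seed, sample(rep(seq_len(cfg$cv_folds),
                                          length.out = nrow(x))))

  ranges <- hyperparameter_ranges()
  candidates <- sample_candidates(cfg$algorithm, cfg$random_candidates,
                                  cfg$seed, ranges)
  trace <- data.frame(stage = character(0), score = numeric(0))
  eval_cands <- function(cands, stage) {
    scores <- vapply(cands, function(p)
      cv_score(cfg$algorithm, x, y, classes, p, folds, cfg$seed, cfg$n_jobs),
      numeric(1))
    trace <<- rbind(trace, data.frame(stage = stage, score = scores))
    list(best = cands[[which.max(scores)]], score = max(scores))
  }
  best <- eval_cands(candidates, "random")
  if (cfg$grid_refine && cfg$algorithm != "SVM") {
    grid <- refine_grid(cfg$algorithm, best$best, ranges)
    if (length(grid)) {
      refined <- eval_cands(grid, "grid")
      if (refined$score >= best$score) best <- refined
    }
  }

  fit <- fit_classifier(cfg$algorithm, x, y, classes, best$best,
                        cfg$seed, cfg$n_jobs)
  structure(list(algorithm = cfg$algorithm,
                 feature_set = cfg$feature_set,
                 feature_maps = maps,
                 fit = fit,
                 standardizer = std,
                 config = cfg,
                 best_params = best$best,
                 cv_score = best$score,
                 search_trace = trace,
                 classes = classes,
                 n_features = ncol(x)),
            class = "ctp_model")
}

#' @exportS3Method base::print
print.ctp_model <- function(x, ...) {
  cat(sprintf("<ctp_model> %s on %s (%d features), CV accuracy %.4f\n",
              x$algorithm, x$feature_set, x$n_features, x$cv_score))
  invisible(x)
}

# Scores for arbitrary (unstandardized) feature rows matching the bundle.
bundle_scores <- function(bundle, features) {
  x <- apply_standardizer(bundle$standardizer, features)
  classifier_scores(bundle$algorithm, bundle$fit, x, bundle$classes)
}

#' Evaluate a fitted model on validation rows
#'
#' Computes one-vs-rest macro ROC-AUC, overall accuracy, and per-class
#' sample-level Dice and Jaccard scores on the label vectors (not on
#' reconstructed images).  Validation features are standardized with the
#' bundle's frozen training standardizer.
#'
#' @param bundle a `ctp_model` from [tune_and_train()].
#' @param validation a `patch_matrix`.
#' @return A list with `auc_macro`, `accuracy`, `per_class` (data frame
#'   of class, dsc, ji) and `n`.
#' @export
evaluate_on_validation <- function(bundle, validation) {
  stopifnot(inherits(bundle, "ctp_model"), inherits(validation, "patch_matrix"))
  pm <- subset_feature_maps(validation, bundle$feature_maps)
  if (ncol(pm$features) != bundle$n_features)
    stop("validation feature dimensionality does not match the model", call. = FALSE)
  scores <- bundle_scores(bundle, pm$features)
  pred <- score_to_class(scores, bundle$classes)
  y <- pm$labels
  aucs <- vapply(seq_along(bundle$classes), function(k) {
    resp <- y == bundle$classes[k]
    if (length(unique(resp)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = resp, predictor = scores[, k],
                                   quiet = TRUE, direction = "<")))
  }, numeric(1))
  per_class <- data.frame(
    class = bundle$classes,
    dsc = vapply(bundle$classes, function(k) dsc(y == k, pred == k), numeric(1)),
    ji = vapply(bundle$classes, function(k) jaccard(y == k, pred == k), numeric(1)))
  list(auc_macro = mean(aucs, na.rm = TRUE),
       accuracy = mean(pred == y),
       per_class = per_class,
       n = length(y))
}

#' Train the same algorithm on two-map and four-map features
#'
#' Trains one model on the DT/CBF column blocks and one on all four maps
#' of the same training matrix (the two-map features are an exact column
#' subset — rows are never re-sampled), and reports both validation
#' metrics side by side.
#'
#' @param train,validation `patch_matrix` objects built with all four
#'   maps.
#' @param algorithm see [model_config()].
#' @param seed shared seed for both runs.
#' @param ... further arguments passed to [model_config()].
#' @return A list with `two_map` and `four_map`, each holding `bundle`
#'   and `metrics`, plus a `comparison` data frame.
#' @export
compare_feature_sets <- function(train, validation, algorithm = "XGB",
                                 seed = 1L, ...) {
  out <- lapply(c(two_map = "two_map", four_map = "four_map"), function(fs) {
    cfg <- model_config(algorithm = algorithm, feature_set = fs,
                        seed = seed, ...)
    bundle <- tune_and_train(train, cfg)
    list(bundle = bundle, metrics = evaluate_on_validation(bundle, validation))
  })
  comparison <- do.call(rbind, lapply(names(out), function(fs) {
    m <- out[[fs]]$metrics
    data.frame(feature_set = fs, auc_macro = m$auc_macro,
               accuracy = m$accuracy,
               dsc_core = m$per_class$dsc[m$per_class$class == 3],
               dsc_penumbra = m$per_class$dsc[m$per_class$class == 2])
  }))
  c(out, list(comparison = comparison))
}

#' Persist and restore a model bundle
#'
#' Writes the bundle to a single archive with an embedded JSON manifest
#' (algorithm, feature set, chosen hyperparameters, seed and package
#' version).  The boosted-tree handle is converted to its raw byte
#' representation so the archive survives across sessions; metrics are
#' unchanged after a round trip.
#'
#' @param bundle a `ctp_model`.
#' @param path file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `ctp_model`.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "ctp_model"))
  manifest <- jsonlite::toJSON(list(
    algorithm = bundle$algorithm,
    feature_set = bundle$feature_set,
    feature_maps = bundle$feature_maps,
    best_params = bundle$best_params,
    seed = bundle$config$seed,
    classes = bundle$classes,
    package_version = as.character(utils::packageVersion("ctpseg"))),
    auto_unbox = TRUE, digits = NA)
  if (bundle$algorithm == "XGB")
    bundle$fit <- xgboost::xgb.save.raw(bundle$fit)
  saveRDS(list(manifest = manifest, bundle = bundle), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  bundle <- obj$bundle
  if (bundle$algorithm == "XGB" && is.raw(bundle$fit))
    bundle$fit <- xgboost::xgb.load.raw(bundle$fit)
  bundle
}
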