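#' Classifier parameter sets
#'
#' Parameters for the extremely-randomized-trees ensemble.  Two named
#' defaults are provided: `"set1"` (100 trees, floor(sqrt(8)) = 2 candidate
#' features per split) and `"set2"` (1000 trees, all 8 features per split);
#' both grow unbounded trees with single-observation leaves.
#'
#' @param set_name `"set1"`, `"set2"`, or `"custom"`.
#' @param n_trees Number of trees (>= 1); overrides the set default.
#' @param features_per_split Candidate features per split (1..8); overrides
#'   the set default.
#' @param max_depth Maximum tree depth, or `NULL` for unbounded.
#' @param seed Optional default training seed.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(set_name = c("set1", "set2", "custom"),
                              n_trees = NULL, features_per_split = NULL,
                              max_depth = NULL, seed = NULL) {
  set_name <- match.arg(set_name)
  defaults <- switch(set_name,
    set1 = list(n_trees = 100L, features_per_split = 2L),
    set2 = list(n_trees = 1000L, features_per_split = 8L),
    custom = list(n_trees = 100L, features_per_split = 2L))
  n_trees <- as.integer(n_trees %||% defaults$n_trees)
  features_per_split <- as.integer(features_per_split %||%
                                     defaults$features_per_split)
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (features_per_split < 1L || features_per_split > 8L)
    stop("features_per_split must be between 1 and 8")
  structure(list(set_name = set_name, n_trees = n_trees,
                 features_per_split = features_per_split,
                 max_depth = max_depth, seed = seed),
            class = "classifier_params")
}

#' @export
print.classifier_params <- function(x, ...) {
  cat(sprintf("Classifier params '%s': %d trees, %d features/split, depth %s\n",
              x$set_name, x$n_trees, x$features_per_split,
              if (is.null(x$max_depth)) "unbounded" else x$max_depth))
  invisible(x)
}

label_factor <- function(labels) {
  factor(ifelse(labels == 1L, "beautiful", "ugly"),
         levels = c("ugly", "beautiful"))
}

#' Train an extremely-randomized-trees ensemble
#'
#' Fits a probability forest of extremely randomized trees (random split
#' thresholds, random candidate-feature subsets, no bootstrap resampling,
#' single-observation leaves) on the raw feature matrix.  Trees are
#' scale-invariant, so the non-standardized features are used.  With
#' unbounded depth and distinct feature rows the training-set predictions
#' are perfect.
#'
#' @param ds A [beauty_dataset()] (both classes present).
#' @param params A [classifier_params()].
#' @param seed Training seed; defaults to `params$seed` or 1.
#' @return An object of class `beauty_ensemble`.
#' @export
train_ensemble <- function(ds, params = classifier_params("set1"),
                           seed = NULL) {
  stopifnot(inherits(ds, "beauty_dataset"), inherits(params, "classifier_params"))
  if (length(unique(ds$labels)) < 2L)
    stop("cannot train on a single-class dataset")
  seed <- seed %||% params$seed %||% 1L
  y <- label_factor(ds$labels)
  fit <- ranger::ranger(
    x = as.data.frame(ds$features), y = y,
    num.trees = params$n_trees,
    mtry = params$features_per_split,
    splitrule = "extratrees", num.random.splits = 1L,
    replace = FALSE, sample.fraction = 1,
    min.node.size = 1L,
    max.depth = if (is.null(params$max_depth)) 0L else params$max_depth,
    probability = TRUE, importance = "impurity",
    seed = as.integer(seed), num.threads = 1L)
  structure(list(fit = fit, params = params, seed = as.integer(seed),
                 feature_names = colnames(ds$features),
                 n_obs = length(ds$words)),
            class = "beauty_ensemble")
}

#' Predict beauty probabilities
#'
#' @param object A [train_ensemble()] fit.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the "beautiful" class
#'   (fraction of trees voting beautiful).
#' @export
predict.beauty_ensemble <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  p <- predict(object$fit, data = newdata, num.threads = 1L)$predictions
  as.numeric(p[, "beautiful"])
}

#' @export
print.beauty_ensemble <- function(x, ...) {
  cat(sprintf("ERT ensemble ('%s'): %d trees on %d observations\n",
              x$params$set_name, x$params$n_trees, x$n_obs))
  invisible(x)
}

#' Confusion matrix of thresholded scores
#'
#' @param labels Binary truth labels (beautiful = 1).
#' @param scores Probability scores for the beautiful class.
#' @param threshold Decision threshold (default 0.5).
#' @return 2x2 integer matrix, truth in rows, prediction in columns.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  truth <- label_factor(labels)
  pred <- label_factor(as.integer(scores > threshold))
  table(truth = truth, predicted = pred)
}

#' ROC curve by threshold sweep
#'
#' @param labels Binary truth labels (beautiful = 1).
#' @param scores Probability scores for the beautiful class.
#' @return Data frame of `threshold`, `fpr`, `tpr`, ordered from the
#'   all-positive to the all-negative operating point.
#' @export
roc_curve <- function(labels, scores) {
  r <- pROC::roc(response = label_factor(labels), predictor = scores,
                 levels = c("ugly", "beautiful"), direction = "<",
                 quiet = TRUE)
  data.frame(threshold = r$thresholds,
             fpr = 1 - r$specificities,
             tpr = r$sensitivities)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC of the threshold-sweep ROC; ties in scores are handled
#' by linear interpolation, so the value equals the concordant-pair
#' (Mann-Whitney) statistic.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  r <- pROC::roc(response = label_factor(labels), predictor = scores,
                 levels = c("ugly", "beautiful"), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Stratified k-fold cross-validated ROC/AUC
#'
#' Partitions the words into k folds preserving the class proportions
#' (within one item), trains an ensemble on each training split and scores
#' the held-out fold.  One master seed fans out into the fold assignment
#' and the per-fold tree seeds.
#'
#' @param ds A [beauty_dataset()].
#' @param params A [classifier_params()].
#' @param k Number of folds (>= 2 and at most the minority class count).
#' @param seed Master seed for fold assignment and tree construction.
#' @return Object of class `cv_result` with `fold_aucs`, `mean_auc`,
#'   `fold_rocs`, `folds`, `k`, `seed` and `params`.
#' @export
stratified_kfold_auc <- function(ds, params = classifier_params("set1"),
                                 k = 5L, seed = 1L) {
  stopifnot(inherits(ds, "beauty_dataset"))
  k <- as.integer(k)
  n_min <- min(table(ds$labels))
  if (k < 2L) stop("k must be >= 2")
  if (k > n_min)
    stop("k = ", k, " exceeds the minority class count (", n_min, ")")
  seeds <- derive_seeds(seed, k + 1L)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seeds[1L])
  folds <- caret::createFolds(label_factor(ds$labels), k = k)
  fold_aucs <- numeric(k)
  fold_rocs <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    train_ds <- subset_dataset(ds, setdiff(seq_along(ds$words), test_idx))
    fit <- train_ensemble(train_ds, params, seed = seeds[1L + i])
    scores <- predict(fit, ds$features[test_idx, , drop = FALSE])
    fold_aucs[i] <- auc_score(ds$labels[test_idx], scores)
    fold_rocs[[i]] <- roc_curve(ds$labels[test_idx], scores)
  }
  structure(list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 fold_rocs = fold_rocs, folds = folds, k = k,
                 seed = seed, params = params),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Stratified %d-fold CV: mean AUC %.3f (folds: %s)\n",
              x$k, x$mean_auc, paste(sprintf("%.2f", x$fold_aucs),
                                     collapse = ", ")))
  invisible(x)
}

# Row-subset a beauty dataset (z view recomputed on the subset).
subset_dataset <- function(ds, idx) {
  beauty_dataset(ds$words[idx], ds$labels[idx],
                 ds$features[idx, , drop = FALSE])
}

#' Label-permutation null for the cross-validated AUC
#'
#' Randomly permutes the beautiful/ugly labels and reruns the stratified
#' k-fold evaluation; repeated for `n_runs` runs (default 5), giving an
#' empirical chance-level reference of AUC approximately 0.5.
#'
#' @param ds A [beauty_dataset()].
#' @param params A [classifier_params()].
#' @param k Folds per run.
#' @param n_runs Number of permutation runs (>= 1).
#' @param seed Master seed; fans out into per-run permutation and CV seeds.
#' @return Object of class `permutation_result` with `perm_aucs` (one mean
#'   AUC per run), `runs` (the per-run `cv_result`s), `n_runs`, `k`,
#'   `seed` and `params`.
#' @export
permutation_test <- function(ds, params = classifier_params("set1"),
                             k = 5L, n_runs = 5L, seed = 1L) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  seeds <- derive_seeds(seed, 2L * n_runs)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  runs <- vector("list", n_runs)
  perms <- vector("list", n_runs)
  perm_aucs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[2L * r - 1L])
    perm <- sample(ds$labels)
    while (identical(perm, ds$labels) && length(ds$labels) > 1L)
      perm <- sample(ds$labels)
    ds_perm <- beauty_dataset(ds$words, perm, ds$features)
    runs[[r]] <- stratified_kfold_auc(ds_perm, params, k = k,
                                      seed = seeds[2L * r])
    perms[[r]] <- perm
    perm_aucs[r] <- runs[[r]]$mean_auc
  }
  structure(list(perm_aucs = perm_aucs, runs = runs,
                 permutations = perms, n_runs = n_runs,
                 k = k, seed = seed, params = params),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation null (%d runs): mean AUCs %s; grand mean %.3f\n",
              x$n_runs, paste(sprintf("%.3f", x$perm_aucs), collapse = ", "),
              mean(x$perm_aucs)))
  invisible(x)
}

#' Normalized feature importances of a fitted ensemble
#'
#' Mean impurity-decrease importances, normalized to sum to one, with the
#' descending feature ranking attached as attribute `"ranking"`.  The
#' values are a descriptive ranking of the predictors, not effect sizes.
#'
#' @param ensemble A [train_ensemble()] fit.
#' @return Named non-negative numeric vector summing to 1.
#' @export
feature_importances <- function(ensemble) {
  if (!inherits(ensemble, "beauty_ensemble") ||
      is.null(ensemble$fit$variable.importance))
    stop("expected a fitted ensemble with impurity importances")
  imp <- ensemble$fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) == 0)
    stop("all importances are zero; ensemble appears degenerate")
  imp <- imp / sum(imp)
  attr(imp, "ranking") <- names(sort(imp, decreasing = TRUE))
  imp
}
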