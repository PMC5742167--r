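#' Run configuration for an end-to-end evaluation
#'
#' Bundles the resource paths, classifier parameters, fold count,
#' permutation count and master seed of a run, so every report can embed
#' the full parameterization.
#'
#' @param study_dir Directory holding the study files written by
#'   [simulate_study_files()] (or equivalent hand-made files).
#' @param params A [classifier_params()].
#' @param k Folds for cross-validation.
#' @param n_permutations Permutation runs for the null.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(study_dir, params = classifier_params("set1"),
                       k = 5L, n_permutations = 5L, seed = 1L) {
  structure(list(study_dir = study_dir, params = params, k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}

study_file_names <- function() {
  c(frequency = "frequency.tsv",
    edges = "taxonomy_edges.tsv",
    lemmas = "taxonomy_lemmas.tsv",
    dataset = "dataset.csv",
    labels = "label_sets.yml")
}

#' Write a synthetic study to disk
#'
#' Generates a study from `config` and writes the five study files
#' (frequency TSV, taxonomy edge and lemma TSVs, labeled dataset CSV,
#' label-set YAML) plus a JSON manifest recording the seed, generator
#' configuration and injected ground truth.  The directory is created if
#' missing; rerunning with the same config yields byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @return Named character vector of the six written paths, invisibly;
#'   the generated study is attached as attribute `"study"`.
#' @export
simulate_study_files <- function(config = generator_config(), dir) {
  stopifnot(inherits(config, "generator_config"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  study <- generate_study(config)
  files <- file.path(dir, study_file_names())
  names(files) <- names(study_file_names())
  write_frequency_table(study$frequency_table, files[["frequency"]])
  write_taxonomy(study$taxonomy, files[["edges"]], files[["lemmas"]])
  utils::write.csv(study$dataset, files[["dataset"]], row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  write_label_sets(list(valence = study$valence_labels,
                        ap = study$ap_labels), files[["labels"]])
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   ground_truth = study$ground_truth,
                   files = as.list(basename(files)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out <- c(files, manifest = manifest_path)
  attr(out, "study") <- study
  invisible(out)
}

#' Load study files and build the feature matrix
#'
#' Reads the resources and labeled word list from `study_dir`, filters the
#' targets to those covered by both resources (logging the per-resource
#' coverage), builds the [beauty_dataset()] and writes `features.csv`
#' (word, the eight feature columns, label).
#'
#' @param study_dir Directory with the files of [simulate_study_files()].
#' @param out_csv Path of the feature CSV to write; `NULL` skips writing.
#' @return The [beauty_dataset()], with the coverage reports attached as
#'   attribute `"coverage"`.
#' @export
featurize_study <- function(study_dir,
                            out_csv = file.path(study_dir, "features.csv")) {
  fn <- file.path(study_dir, study_file_names())
  names(fn) <- names(study_file_names())
  freq <- read_frequency_table(fn[["frequency"]])
  tax <- read_taxonomy(fn[["edges"]], fn[["lemmas"]])
  targets <- utils::read.csv(fn[["dataset"]], stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  sets <- read_label_sets(fn[["labels"]])
  kept <- intersect_targets(targets, freq, tax)
  cov <- attr(kept, "coverage")
  message(sprintf("coverage: frequency %d/%d, taxonomy %d/%d; %d of %d targets kept",
                  cov$frequency$n_hit, cov$frequency$n_targets,
                  cov$taxonomy$n_hit, cov$taxonomy$n_targets,
                  nrow(kept), nrow(targets)))
  ds <- build_beauty_dataset(kept, freq, tax, sets$valence, sets$ap)
  if (!is.null(out_csv))
    write_features(ds, out_csv)
  attr(ds, "coverage") <- cov
  ds
}

#' Write a beauty dataset to a feature CSV
#'
#' One row per word: `word`, the eight feature columns in canonical order,
#' and `label` (`beautiful`/`ugly`).
#'
#' @param ds A [beauty_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(ds, path) {
  stopifnot(inherits(ds, "beauty_dataset"))
  df <- data.frame(word = ds$words, ds$features,
                   label = ifelse(ds$labels == 1L, "beautiful", "ugly"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Read a feature CSV back into a beauty dataset
#'
#' @param path A CSV written by [write_features()].
#' @return A [beauty_dataset()].
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  beauty_dataset(df$word, df$label,
                 as.matrix(df[, qna_feature_names(), drop = FALSE]))
}

#' Run the full classification and statistics study
#'
#' Executes the complete evaluation on a feature dataset: train-on-all
#' confusion matrix and feature importances, stratified k-fold ROC/AUC,
#' label-permutation null, per-feature one-way ANOVAs (with group means on
#' the raw and z scale) and the pairwise feature R-squared matrix.  The
#' per-feature p-values are reported raw, without multiple-testing
#' correction across the eight features.
#'
#' @param ds A [beauty_dataset()].
#' @param params A [classifier_params()].
#' @param k Folds for cross-validation.
#' @param n_permutations Permutation runs.
#' @param seed Master seed; fans out into training, fold and permutation
#'   seeds.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_study <- function(ds, params = classifier_params("set1"), k = 5L,
                           n_permutations = 5L, seed = 1L) {
  stopifnot(inherits(ds, "beauty_dataset"))
  seeds <- derive_seeds(seed, 3L)
  fit <- train_ensemble(ds, params, seed = seeds[1L])
  train_scores <- predict(fit, ds$features)
  cv <- stratified_kfold_auc(ds, params, k = k, seed = seeds[2L])
  perm <- permutation_test(ds, params, k = k, n_runs = n_permutations,
                           seed = seeds[3L])
  anovas <- lapply(stats::setNames(nm = colnames(ds$features)), function(f)
    one_way_anova(ds$features[, f], label_factor(ds$labels)))
  r2 <- stats::cor(ds$features)^2
  structure(list(confusion_train = confusion_counts(ds$labels, train_scores),
                 importances = feature_importances(fit),
                 cv = cv,
                 fold_aucs = cv$fold_aucs,
                 mean_auc = cv$mean_auc,
                 permutation = perm,
                 permutation_aucs = perm$perm_aucs,
                 anovas = anovas,
                 pairwise_r2 = r2,
                 group_summary = group_summary(ds),
                 params = params, k = as.integer(k),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 n_words = length(ds$words)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Word-beauty evaluation report\n")
  print(x$params)
  cat("Train-on-all confusion matrix:\n")
  print(x$confusion_train)
  cat(sprintf("Stratified %d-fold CV mean AUC: %.3f (folds %s)\n", x$k,
              x$mean_auc, paste(sprintf("%.2f", x$fold_aucs), collapse = ", ")))
  cat(sprintf("Permutation null (%d runs): grand mean AUC %.3f\n",
              x$n_permutations, mean(x$permutation_aucs)))
  cat("Feature importances (sum 1):\n")
  print(round(x$importances[order(-x$importances)], 3))
  cat("Per-feature ANOVA (raw p-values, no multiplicity correction):\n")
  for (f in names(x$anovas)) {
    a <- x$anovas[[f]]
    cat(sprintf("  %-14s F(%d,%d) = %6.2f, p = %.4g, R2adj = %.3f\n", f,
                a$df_between, a$df_within, a$f_stat, a$p_value, a$r2_adj))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes `evaluation.json` (confusion matrix, fold and permutation AUCs,
#' importances, full parameterization), `stats.json` (ANOVAs, pairwise
#' R-squared, group summary), `roc.tsv` (fold, threshold, fpr, tpr) and
#' `confusion.csv`.
#'
#' @param report An [evaluate_study()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_evaluation_report <- function(report, dir) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  eval_path <- file.path(dir, "evaluation.json")
  stats_path <- file.path(dir, "stats.json")
  roc_path <- file.path(dir, "roc.tsv")
  conf_path <- file.path(dir, "confusion.csv")
  jsonlite::write_json(list(
    n_words = report$n_words,
    params = unclass(report$params),
    k = report$k,
    n_permutations = report$n_permutations,
    seed = report$seed,
    confusion_train = as.vector(t(report$confusion_train)),
    confusion_labels = dimnames(report$confusion_train),
    fold_aucs = report$fold_aucs,
    mean_auc = report$mean_auc,
    importances = as.list(report$importances),
    importance_ranking = attr(report$importances, "ranking"),
    permutation_aucs = report$permutation_aucs,
    permutation_grand_mean = mean(report$permutation_aucs)),
    eval_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(
    anovas = lapply(report$anovas, unclass),
    pairwise_r2 = as.data.frame(report$pairwise_r2),
    group_summary = report$group_summary,
    note = "p-values are raw; no multiple-testing correction across features"),
    stats_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  roc <- do.call(rbind, lapply(seq_along(report$cv$fold_rocs), function(i)
    cbind(fold = i, report$cv$fold_rocs[[i]])))
  utils::write.table(roc, roc_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(as.data.frame(report$confusion_train), conf_path,
                   row.names = FALSE)
  invisible(c(evaluation = eval_path, stats = stats_path, roc = roc_path,
              confusion = conf_path))
}
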