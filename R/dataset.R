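#' Column-standardize a feature matrix
#'
#' Centers each column to mean 0 and scales it to sample standard deviation
#' 1 (denominator `n - 1`).  With two groups of sizes `n1`, `n2` the
#' z-scored group means then satisfy `n1 * m1 + n2 * m2 = 0`, which is the
#' identity relating the two reported group z-means of any feature.
#'
#' @param m Numeric matrix with at least two rows; every column must have
#'   nonzero variance.
#' @return Matrix of the same shape with standardized columns.
#' @export
zscore_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L)
    stop("need at least two rows to standardize")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(m)[sds == 0 | !is.finite(sds)] %||% which(sds == 0)
    stop("constant column(s) cannot be z-scored: ",
         paste(bad, collapse = ", "))
  }
  scaled <- sweep(sweep(m, 2L, colMeans(m), "-"), 2L, sds, "/")
  dimnames(scaled) <- dimnames(m)
  scaled
}

#' Construct a labeled beauty dataset
#'
#' Bundles the target words, their binary beautiful/ugly labels, the
#' n-by-8 feature matrix and its column-standardized view.
#'
#' @param words Character vector of target word forms.
#' @param labels Binary labels: 1/0, logical, or the strings
#'   `"beautiful"`/`"ugly"` (beautiful = 1).  Both classes must be present.
#' @param features Numeric matrix, one row per word, with the
#'   [qna_feature_names()] columns (any order; reordered canonically).
#' @return An object of class `beauty_dataset` with `words`, `labels`
#'   (integer 0/1), `features` and `z_features`.
#' @export
beauty_dataset <- function(words, labels, features) {
  words <- normalize_word(words)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("beautiful", "ugly")))
      stop("character labels must be 'beautiful' or 'ugly'")
    labels <- as.integer(labels == "beautiful")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || anyNA(labels))
    stop("labels must be binary (beautiful = 1, ugly = 0)")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the dataset")
  features <- as.matrix(features)
  if (nrow(features) != length(words) || length(labels) != length(words))
    stop("words, labels and feature rows must align")
  if (!setequal(colnames(features), qna_feature_names()))
    stop("feature columns must be exactly: ",
         paste(qna_feature_names(), collapse = ", "))
  features <- features[, qna_feature_names(), drop = FALSE]
  if (anyNA(features) || any(!is.finite(features)))
    stop("feature matrix contains missing or non-finite values")
  rownames(features) <- words
  structure(list(words = words,
                 labels = labels,
                 features = features,
                 z_features = zscore_columns(features)),
            class = "beauty_dataset")
}

#' @export
print.beauty_dataset <- function(x, ...) {
  cat(sprintf("Beauty dataset: %d words (%d beautiful, %d ugly), %d features\n",
              length(x$words), sum(x$labels == 1L), sum(x$labels == 0L),
              ncol(x$features)))
  invisible(x)
}

#' Build a beauty dataset from labeled targets and resources
#'
#' Featurizes every surviving target word (see [featurize()]) and assembles
#' the [beauty_dataset()].  Label sets are resolved against the taxonomy
#' once, so unresolvable labels trigger a single warning.
#'
#' @param targets Data frame with columns `word` and `label`
#'   (`"beautiful"`/`"ugly"` or 1/0), e.g. the output of
#'   [intersect_targets()].
#' @param freq A [frequency_table()].
#' @param tax A [semantic_taxonomy()].
#' @param valence_labels,ap_labels [label_set()]s.
#' @param scale Sonority scale.
#' @param method Relatedness method.
#' @return A [beauty_dataset()].
#' @export
build_beauty_dataset <- function(targets, freq, tax, valence_labels,
                                 ap_labels,
                                 scale = default_sonority_scale(),
                                 method = "depth") {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "label") %in% names(targets)))
  words <- normalize_word(targets$word)
  valence_labels <- resolve_label_set(valence_labels, tax)
  ap_labels <- resolve_label_set(ap_labels, tax)
  rows <- lapply(words, featurize, freq = freq, tax = tax, targets = words,
                 valence_labels = valence_labels, ap_labels = ap_labels,
                 scale = scale, method = method)
  features <- do.call(rbind, rows)
  beauty_dataset(words, targets$label, features)
}

# Drop labels missing from the taxonomy, warning once per label set.
resolve_label_set <- function(labels, tax) {
  stopifnot(inherits(labels, "label_set"))
  known <- names(tax$lemma_index)
  pos <- intersect(labels$positive, known)
  neg <- intersect(labels$negative, known)
  dropped <- length(labels$positive) + length(labels$negative) -
    length(pos) - length(neg)
  if (dropped > 0L)
    warning("label set '", labels$name, "': ", dropped,
            " label(s) not in taxonomy, dropped")
  if (length(pos) == 0L || length(neg) == 0L)
    stop("label set '", labels$name, "': no resolvable label on one side")
  label_set(labels$name, pos, neg)
}
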