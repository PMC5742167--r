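#' Default sonority scale for German orthography
#'
#' Maps every letter of the German alphabet (including umlauts and eszett)
#' to a manner-of-articulation class and each class to a numeric sonority
#' rank.  Ranks increase from obstruents to vowels, following the classical
#' sonority hierarchy: plosive 1, fricative 2, nasal 3, liquid 4, glide 4.5,
#' vowel 5.  The sonority score of a word is the mean rank of its letters,
#' a transparent orthographic proxy for phonological euphony.
#'
#' @param ranks Optional named numeric vector overriding the class ranks;
#'   must be strictly increasing from plosive to vowel.
#' @return An object of class `sonority_scale` with `ranks` (class to rank)
#'   and `classes` (letter to class).
#' @export
default_sonority_scale <- function(ranks = NULL) {
  default_ranks <- c(plosive = 1, fricative = 2, nasal = 3,
                     liquid = 4, glide = 4.5, vowel = 5)
  ranks <- ranks %||% default_ranks
  if (!all(names(default_ranks) %in% names(ranks)))
    stop("ranks must name all six classes: ",
         paste(names(default_ranks), collapse = ", "))
  ord <- ranks[names(default_ranks)]
  if (any(diff(ord) <= 0))
    stop("ranks must strictly increase from plosive to vowel")
  classes <- c(
    a = "vowel", e = "vowel", i = "vowel", o = "vowel", u = "vowel",
    "ä" = "vowel", "ö" = "vowel", "ü" = "vowel", y = "vowel",
    j = "glide", h = "glide",
    l = "liquid", r = "liquid",
    m = "nasal", n = "nasal",
    f = "fricative", s = "fricative", v = "fricative", w = "fricative",
    z = "fricative", x = "fricative", "ß" = "fricative",
    b = "plosive", p = "plosive", d = "plosive", t = "plosive",
    g = "plosive", k = "plosive", q = "plosive", c = "plosive")
  structure(list(ranks = ord, classes = classes), class = "sonority_scale")
}

word_letters <- function(word) {
  word <- normalize_word(word)
  if (length(word) != 1L || !nzchar(word))
    stop("expected a single non-empty word form")
  strsplit(word, "", fixed = FALSE)[[1L]]
}

german_vowels <- function() {
  c("a", "e", "i", "o", "u", "ä", "ö", "ü", "y")
}

german_diphthongs <- function() {
  c("ei", "ai", "au", "eu", "äu", "ie")
}

#' Count syllables of a word form
#'
#' Counts vowel nuclei: maximal vowel runs are scanned left to right and
#' German diphthongs/digraphs (ei, ai, au, eu, au-umlaut, ie) are greedily
#' merged into a single nucleus, so "morgenröte" has four nuclei and
#' "ei" one.
#'
#' @param word A single word form containing at least one vowel letter.
#' @return Integer syllable count (>= 1).
#' @export
count_syllables <- function(word) {
  letters_ <- word_letters(word)
  is_vowel <- letters_ %in% german_vowels()
  if (!any(is_vowel))
    stop("cannot syllabify '", normalize_word(word), "': no vowel letter")
  diph <- german_diphthongs()
  n <- 0L
  i <- 1L
  len <- length(letters_)
  while (i <= len) {
    if (is_vowel[i]) {
      n <- n + 1L
      if (i < len && is_vowel[i + 1L] &&
          paste0(letters_[i], letters_[i + 1L]) %in% diph) {
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    } else {
      i <- i + 1L
    }
  }
  n
}

#' Mean sonority rank of a word
#'
#' @param word A single word form.
#' @param scale A [default_sonority_scale()] (or a modified one).
#' @return Arithmetic mean of the per-letter sonority ranks.
#' @export
sonority_score <- function(word, scale = default_sonority_scale()) {
  stopifnot(inherits(scale, "sonority_scale"))
  letters_ <- word_letters(word)
  cls <- scale$classes[letters_]
  if (anyNA(cls))
    stop("unclassifiable character '", letters_[which(is.na(cls))[1L]],
         "' in '", normalize_word(word), "'")
  mean(scale$ranks[cls])
}

#' Surprisal of a word in bits
#'
#' Information content `-log2(count / total_tokens)` under the relative
#' corpus frequency; rarer words carry more bits.
#'
#' @param word A single word form; must be present in `freq` with count
#'   of at least 1.
#' @param freq A [frequency_table()].
#' @return Surprisal in bits (>= 0).
#' @export
surprisal <- function(word, freq) {
  stopifnot(inherits(freq, "frequency_table"))
  word <- normalize_word(word)
  count <- freq$counts[word]
  if (is.na(count) || count < 1)
    stop("word '", word, "' not in frequency table; ",
         "filter targets with intersect_targets() first")
  -log2(as.numeric(count) / freq$total_tokens)
}

#' Orthographic neighborhood density (Coltheart's N)
#'
#' Number of lexicon entries of identical length at Hamming distance
#' exactly one (single-letter substitution) from the word; the word itself
#' is excluded.
#'
#' @param word A single word form.
#' @param lexicon A [frequency_table()] or character vector of word forms.
#' @return Integer neighbor count (>= 0).
#' @export
orthographic_n <- function(word, lexicon) {
  word <- normalize_word(word)
  lex <- unique(resource_words(lexicon))
  lex <- setdiff(lex[nchar(lex) == nchar(word)], word)
  if (length(lex) == 0L) return(0L)
  chars <- strsplit(word, "")[[1L]]
  cand <- strsplit(lex, "")
  sum(vapply(cand, function(x) sum(x != chars) == 1L, logical(1)))
}

#' Semantic relatedness of two word forms
#'
#' Path-length-based relatedness over the is-a taxonomy.  For the default
#' `"depth"` method the relatedness of two lemmas is
#' `1 - d / (2 * depth)` where `d` is the shortest undirected path between
#' their concept nodes, minimized (i.e. relatedness maximized) over all node
#' pairs, and `depth` is the maximum root distance of the taxonomy.  The
#' measure is symmetric, lies in `[0, 1]`, and equals 1 exactly when the
#' lemmas share a node.  The `"path"` method uses `1 / (1 + d)` instead.
#'
#' @param w1,w2 Word forms; both must be attached in the taxonomy.
#' @param tax A [semantic_taxonomy()].
#' @param method `"depth"` (default) or `"path"`.
#' @return Relatedness value in `[0, 1]`.
#' @export
relatedness <- function(w1, w2, tax, method = c("depth", "path")) {
  relatedness_many(w1, w2, tax, method)[[1L]]
}

# Vectorized over `others`; one cached-distance-matrix lookup per pair.
relatedness_many <- function(word, others, tax, method = c("depth", "path")) {
  stopifnot(inherits(tax, "semantic_taxonomy"))
  method <- match.arg(method)
  word <- normalize_word(word)
  others <- normalize_word(others)
  idx <- tax$lemma_index
  n1 <- idx[[word]]
  if (is.null(n1))
    stop("unknown lemma '", word, "' in taxonomy")
  miss <- setdiff(others, names(idx))
  if (length(miss) > 0L)
    stop("unknown lemma '", miss[1L], "' in taxonomy")
  D <- node_distances(tax)
  d <- vapply(others, function(w) min(D[n1, idx[[w]], drop = FALSE]),
              numeric(1))
  if (method == "depth") {
    pmin(1, pmax(0, 1 - d / (2 * tax$depth)))
  } else {
    1 / (1 + d)
  }
}

#' Mean relatedness of a word to the other target words
#'
#' Label-blind word similarity: the mean taxonomy relatedness between the
#' word and every other word of the target list.
#'
#' @param word A target word form; must be an element of `targets`.
#' @param targets Character vector of at least two target word forms.
#' @param tax A [semantic_taxonomy()].
#' @param method Relatedness method, see [relatedness()].
#' @return Mean relatedness in `[0, 1]`.
#' @export
word_similarity <- function(word, targets, tax, method = "depth") {
  targets <- normalize_word(targets)
  word <- normalize_word(word)
  if (!word %in% targets)
    stop("word '", word, "' is not in the target list")
  others <- targets[targets != word]
  if (length(others) == 0L)
    stop("target list must contain at least two distinct words")
  mean(relatedness_many(word, others, tax, method))
}

#' Construct a label set
#'
#' A named pair of positive and negative label word lists used for signed
#' relatedness contrasts: the 36-label valence set and the 124-label
#' aesthetic-potential set are both instances.
#'
#' @param name Label-set name.
#' @param positive,negative Non-empty, disjoint character vectors of label
#'   word forms.
#' @return An object of class `label_set`.
#' @export
label_set <- function(name, positive, negative) {
  positive <- unique(normalize_word(positive))
  negative <- unique(normalize_word(negative))
  if (length(positive) == 0L || length(negative) == 0L)
    stop("label set '", name, "' needs non-empty positive and negative lists")
  overlap <- intersect(positive, negative)
  if (length(overlap) > 0L)
    stop("label set '", name, "' has overlapping labels: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  structure(list(name = as.character(name), positive = positive,
                 negative = negative), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("Label set '%s': %d positive / %d negative labels\n",
              x$name, length(x$positive), length(x$negative)))
  invisible(x)
}

#' Signed relatedness contrast against a label set
#'
#' The word's mean relatedness to the positive labels minus its mean
#' relatedness to the negative labels.  With the 36-label valence set this
#' is the valence feature; with the 124-label aesthetic vocabulary it is
#' the aesthetic potential (AP).  Labels missing from the taxonomy are
#' dropped with a warning; if a whole side is unresolvable the contrast is
#' undefined and an error is raised.
#'
#' @param word A word form attached in the taxonomy.
#' @param labels A [label_set()].
#' @param tax A [semantic_taxonomy()].
#' @param method Relatedness method, see [relatedness()].
#' @return Signed contrast value.
#' @export
label_score <- function(word, labels, tax, method = "depth") {
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
    stop("label set '", labels$name,
         "': no resolvable label on one side")
  mean(relatedness_many(word, pos, tax, method)) -
    mean(relatedness_many(word, neg, tax, method))
}

#' Compute the eight-feature vector of one target word
#'
#' Composes the eight feature operations: syllable count, sonority score,
#' length in letters, surprisal, orthographic neighborhood density, word
#' similarity (against the full target list), valence contrast and
#' aesthetic-potential contrast.  Deterministic given the resources and
#' configurations.
#'
#' @param word A target word form surviving [intersect_targets()].
#' @param freq A [frequency_table()].
#' @param tax A [semantic_taxonomy()].
#' @param targets Character vector of all target word forms (including
#'   `word`).
#' @param valence_labels,ap_labels [label_set()]s for the valence and
#'   aesthetic-potential contrasts.
#' @param scale Sonority scale, see [default_sonority_scale()].
#' @param method Relatedness method, see [relatedness()].
#' @return Named numeric vector in the [qna_feature_names()] order.
#' @export
featurize <- function(word, freq, tax, targets, valence_labels, ap_labels,
                      scale = default_sonority_scale(), method = "depth") {
  word <- normalize_word(word)
  out <- tryCatch(
    c(n_syllables = as.numeric(count_syllables(word)),
      sonority = sonority_score(word, scale),
      length = as.numeric(nchar(word)),
      surprisal = surprisal(word, freq),
      neighborhood_n = as.numeric(orthographic_n(word, freq)),
      similarity = word_similarity(word, targets, tax, method),
      valence = label_score(word, valence_labels, tax, method),
      ap = label_score(word, ap_labels, tax, method)),
    error = function(e) stop("featurize failed for word '", word, "': ",
                             conditionMessage(e), call. = FALSE))
  out[qna_feature_names()]
}
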