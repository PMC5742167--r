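#' Configuration of the synthetic study generator
#'
#' Defaults reproduce the shape and the reported group structure of the
#' word-beauty study: 75 beautiful and 55 ugly target words, an
#' aesthetic-potential separation of 0.58 z-units (group z-means 0.25 and
#' about -0.34 under the pooled-standardization constraint), group sonority
#' means of 3.12 versus 2.9, and a mean word length of about 12 letters in
#' both groups (length itself carries no group effect).
#'
#' @param n_beautiful,n_ugly Group sizes (default 75 / 55).
#' @param lexicon_size Total number of word forms in the synthetic lexicon,
#'   dataset words included (default 2000).
#' @param zipf_exponent Exponent of the Zipf rank-frequency law
#'   (default 1).
#' @param taxonomy_depth Maximum root distance of the synthetic taxonomy
#'   (default 6, minimum 2).
#' @param ap_effect Target z-mean separation of the aesthetic potential
#'   between groups (default 0.58); 0 disables the semantic group signal.
#' @param ap_noise Optional attachment noise in `[0, 1]` overriding the
#'   calibration: 0 attaches every word to its congruent semantic pole
#'   (perfect separation), 1 attaches at random (no signal).  `NULL`
#'   (default) calibrates the noise by bisection against `ap_effect`.
#' @param sonority_means Length-2 numeric, target mean sonority of the
#'   beautiful and ugly group (default `c(3.12, 2.9)`).
#' @param length_mean Target mean word length in letters (default 12,
#'   minimum 2).
#' @param seed Master seed of the study.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_beautiful = 75L, n_ugly = 55L,
                             lexicon_size = 2000L, zipf_exponent = 1,
                             taxonomy_depth = 6L, ap_effect = 0.58,
                             ap_noise = NULL,
                             sonority_means = c(3.12, 2.9),
                             length_mean = 12, seed = 1L) {
  cfg <- list(n_beautiful = as.integer(n_beautiful),
              n_ugly = as.integer(n_ugly),
              lexicon_size = as.integer(lexicon_size),
              zipf_exponent = as.numeric(zipf_exponent),
              taxonomy_depth = as.integer(taxonomy_depth),
              ap_effect = as.numeric(ap_effect),
              ap_noise = ap_noise,
              sonority_means = as.numeric(sonority_means),
              length_mean = as.numeric(length_mean),
              seed = as.integer(seed))
  if (cfg$n_beautiful < 1L || cfg$n_ugly < 1L)
    stop("group sizes must be positive")
  if (cfg$lexicon_size < cfg$n_beautiful + cfg$n_ugly)
    stop("lexicon_size must be at least n_beautiful + n_ugly (",
         cfg$n_beautiful + cfg$n_ugly, ")")
  if (cfg$zipf_exponent <= 0)
    stop("zipf_exponent must be positive")
  if (cfg$taxonomy_depth < 2L)
    stop("taxonomy_depth must be at least 2")
  if (cfg$length_mean < 2)
    stop("infeasible config: length_mean must be at least 2 letters")
  if (!all(is.finite(c(cfg$ap_effect, cfg$sonority_means))))
    stop("effects must be finite")
  if (length(cfg$sonority_means) != 2L)
    stop("sonority_means must give beautiful and ugly targets")
  if (!is.null(ap_noise) && (ap_noise < 0 || ap_noise > 1))
    stop("ap_noise must lie in [0, 1]")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("Generator config: %d beautiful / %d ugly of %d words, ",
                     "AP effect %.2f z, sonority %.2f/%.2f, length %.1f, seed %d\n"),
              x$n_beautiful, x$n_ugly, x$lexicon_size, x$ap_effect,
              x$sonority_means[1L], x$sonority_means[2L], x$length_mean,
              x$seed))
  invisible(x)
}

# Letter pools for German-like word synthesis, grouped by sonority class.
syn_letters <- function() {
  list(vowels = c("a", "e", "i", "o", "u", "ä", "ö", "ü"),
       vowel_w = c(.20, .26, .12, .12, .10, .07, .07, .06),
       diphthongs = c("ei", "au", "eu", "ie", "ai", "äu"),
       plosive = c("b", "d", "g", "k", "p", "t"),
       fricative = c("f", "s", "w", "z"),
       nasal = c("m", "n"),
       liquid = c("l", "r"))
}

# Calibration constants of the syllable template: mean letters per
# synthesized syllable (onset + nucleus + coda incl. geminates), used to
# convert the target word length into a syllable count, and the per-word
# vowel-letter share, used to convert the sonority target into a
# consonant-class mixture.
SYL_MEAN_LETTERS <- 3.5
VOWEL_LETTER_SHARE <- 0.358

# Consonant-class mixture whose mean rank hits `target` between a
# plosive-heavy (mean 1.3) and a nasal/liquid (mean 3.5) distribution.
consonant_mixture <- function(sonority_target) {
  p_v <- VOWEL_LETTER_SHARE
  cbar <- (sonority_target - 5 * p_v) / (1 - p_v)
  lambda <- min(1, max(0, (cbar - 1.3) / 2.2))
  (1 - lambda) * c(plosive = .7, fricative = .3, nasal = 0, liquid = 0) +
    lambda * c(plosive = 0, fricative = 0, nasal = .5, liquid = .5)
}

sample_consonant <- function(n, mix, pools) {
  cls <- sample(names(mix), n, replace = TRUE, prob = mix)
  vapply(cls, function(k) sample(pools[[k]], 1L), character(1),
         USE.NAMES = FALSE)
}

# One German-like word: syllables of onset cluster, vowel/diphthong nucleus
# and optional (geminate) coda, consonant classes drawn from `mix`.
synth_word <- function(n_syl, mix, pools) {
  parts <- character(0)
  for (s in seq_len(n_syl)) {
    n_on <- sample(c(1L, 2L), 1L, prob = c(.7, .3))
    onset <- sample_consonant(n_on, mix, pools)
    if (n_on == 1L && stats::runif(1) < .2)
      onset <- c(onset, onset)           # geminate onset (ll, tt, ...)
    nucleus <- if (stats::runif(1) < .2)
      sample(pools$diphthongs, 1L)
    else
      sample(pools$vowels, 1L, prob = pools$vowel_w)
    n_co <- sample(c(0L, 1L, 2L), 1L, prob = c(.40, .45, .15))
    coda <- if (n_co > 0L) sample_consonant(n_co, mix, pools) else character(0)
    if (n_co == 1L && stats::runif(1) < .25)
      coda <- c(coda, coda)              # geminate coda
    parts <- c(parts, onset, nucleus, coda)
  }
  paste(parts, collapse = "")
}

#' Generate German-like word forms for a synthetic lexicon
#'
#' Produces `lexicon_size` unique, pronounceable word forms (alternating
#' consonant-cluster/vowel syllables with umlauts, diphthongs and
#' geminates).  The first `n_beautiful + n_ugly` forms are the dataset
#' words, whose consonant-class mixtures are tuned so the group sonority
#' means approach `sonority_means`; the rest are neutral filler vocabulary.
#'
#' @param config A [generator_config()].
#' @param seed Seed; defaults to the config seed.
#' @param reserved Word forms that must not be generated (e.g. label
#'   words).
#' @return Character vector of length `lexicon_size` with attribute
#'   `"group"` (`"beautiful"`, `"ugly"` or `"none"` per word).
#' @export
generate_word_forms <- function(config, seed = config$seed,
                                reserved = character(0)) {
  stopifnot(inherits(config, "generator_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  pools <- syn_letters()
  groups <- c(rep("beautiful", config$n_beautiful),
              rep("ugly", config$n_ugly),
              rep("none", config$lexicon_size -
                    config$n_beautiful - config$n_ugly))
  mixes <- list(beautiful = consonant_mixture(config$sonority_means[1L]),
                ugly = consonant_mixture(config$sonority_means[2L]),
                none = consonant_mixture(mean(config$sonority_means)))
  syl_mean <- max(1, config$length_mean / SYL_MEAN_LETTERS)
  draw_one <- function(group) {
    n_syl <- max(1L, as.integer(round(stats::rnorm(1, syl_mean, 0.5))))
    synth_word(n_syl, mixes[[group]], pools)
  }
  words <- vapply(groups, draw_one, character(1), USE.NAMES = FALSE)
  reserved <- normalize_word(reserved)
  for (attempt in seq_len(100L)) {
    bad <- duplicated(words) | words %in% reserved
    if (!any(bad)) break
    words[bad] <- vapply(groups[bad], draw_one, character(1),
                         USE.NAMES = FALSE)
  }
  # Turn a share of the filler vocabulary into single-letter substitutions
  # of existing words (minimal pairs), so orthographic neighborhood
  # densities vary instead of collapsing to zero for long random forms.
  n_data <- config$n_beautiful + config$n_ugly
  filler <- which(groups == "none")
  mutate <- filler[stats::runif(length(filler)) < 0.2]
  for (i in mutate) {
    base <- if (stats::runif(1) < 0.4 && n_data > 0L)
      words[sample.int(n_data, 1L)]
    else
      words[sample.int(length(words), 1L)]
    mut <- mutate_word(base, pools)
    if (!mut %in% words && !mut %in% reserved)
      words[i] <- mut
  }
  if (anyDuplicated(words) || any(words %in% reserved))
    stop("could not generate a unique lexicon; increase length_mean or ",
         "decrease lexicon_size")
  attr(words, "group") <- groups
  words
}

#' Generate Zipf-distributed word frequencies
#'
#' Assigns ranks to the words at random and draws each count from a
#' Poisson law around `C / rank^s` (plus one, so every count is at least
#' 1), giving a rank-frequency curve with slope `-s` on the log-log scale.
#'
#' @param words Unique word forms.
#' @param config A [generator_config()] (supplies `zipf_exponent`).
#' @param seed Seed; defaults to the config seed plus one.
#' @return A [frequency_table()] covering every word.
#' @export
generate_frequencies <- function(words, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "generator_config"))
  words <- normalize_word(words)
  if (anyDuplicated(words)) stop("words must be unique")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- length(words)
  ranks <- sample.int(n)
  lambda <- (10 * n) / ranks^config$zipf_exponent
  counts <- 1 + stats::rpois(n, lambda)
  names(counts) <- words
  frequency_table(counts)
}

# Substitute one random letter by another of the same broad class
# (vowel for vowel, consonant for consonant), keeping the form
# pronounceable; the result is an orthographic neighbor of `word`.
mutate_word <- function(word, pools) {
  chars <- strsplit(word, "")[[1L]]
  pos <- sample.int(length(chars), 1L)
  vowels <- pools$vowels
  pool <- if (chars[pos] %in% vowels) vowels
          else c(pools$plosive, pools$fricative, pools$nasal, pools$liquid)
  pool <- setdiff(pool, chars[pos])
  chars[pos] <- sample(pool, 1L)
  paste(chars, collapse = "")
}

# Random rooted tree of `n` nodes: node 1 is the subtree root (local depth
# 0); every later node attaches to a uniformly chosen node of local depth
# < maxdepth.  Returns the parent-index vector.
random_subtree <- function(n, maxdepth) {
  parent <- integer(n)
  depth <- integer(n)
  for (i in seq_len(n)[-1L]) {
    eligible <- which(depth[seq_len(i - 1L)] < maxdepth)
    parent[i] <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    depth[i] <- depth[parent[i]] + 1L
  }
  list(parent = parent, depth = depth)
}

#' Generate a synthetic semantic taxonomy with a group-separating geometry
#'
#' Builds a rooted tree with two mirrored "semantic pole" subtrees and one
#' neutral subtree.  Positive aesthetic-potential labels sit at nodes of
#' one pole and negative labels at the mirrored nodes of the other, so the
#' two poles are exactly symmetric.  Beautiful words attach to their
#' congruent pole with probability `pi` and to the mirrored node of the
#' opposite pole otherwise (ugly words vice versa); `pi = 1` separates the
#' groups perfectly in the AP feature, `pi = 0.5` removes the signal.
#' When `config$ap_noise` is `NULL`, `pi` is calibrated by bisection so
#' that the z-scored AP mean of the beautiful group matches the target
#' implied by `config$ap_effect`.  Valence labels are scattered in
#' positive/negative pairs across all three subtrees, giving the valence
#' feature variance but no built-in group signal or AP correlation.
#' Filler words attach to uniformly random nodes.
#'
#' @param words Word forms with the `"group"` attribute of
#'   [generate_word_forms()].
#' @param labels Named list with [label_set()]s `valence` and `ap`.
#' @param config A [generator_config()].
#' @param seed Seed; defaults to the config seed plus two.
#' @return List with elements `taxonomy` (a [semantic_taxonomy()]),
#'   `congruence` (the attachment probability used) and `ap_zmeans`
#'   (realized z-scored AP group means).
#' @export
generate_taxonomy <- function(words, labels, config,
                              seed = config$seed + 2L) {
  stopifnot(inherits(config, "generator_config"),
            inherits(labels$ap, "label_set"),
            inherits(labels$valence, "label_set"))
  groups <- attr(words, "group")
  if (is.null(groups)) stop("words must carry the 'group' attribute")
  words <- normalize_word(words)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  n_pos <- length(labels$ap$positive)
  n_pole <- max(120L, 2L * n_pos)
  n_mid <- 80L
  sub_depth <- config$taxonomy_depth - 1L
  pole <- random_subtree(n_pole, sub_depth)
  mid <- random_subtree(n_mid, sub_depth)
  p_ids <- sprintf("P%03d", seq_len(n_pole))
  q_ids <- sprintf("Q%03d", seq_len(n_pole))
  m_ids <- sprintf("M%03d", seq_len(n_mid))
  edge_child <- c("P001", "Q001", "M001",
                  p_ids[-1L], q_ids[-1L], m_ids[-1L])
  edge_parent <- c("root", "root", "root",
                   p_ids[pole$parent[-1L]], q_ids[pole$parent[-1L]],
                   m_ids[mid$parent[-1L]])
  edges <- data.frame(child = edge_child, parent = edge_parent,
                      stringsAsFactors = FALSE)

  # aesthetic labels: positive in pole P, negatives at the mirrored nodes
  ap_slots <- sample(seq_len(n_pole), n_pos)
  ap_pos_nodes <- p_ids[ap_slots]
  ap_neg_nodes <- q_ids[ap_slots]

  # valence labels: positive/negative pairs scattered over all subtrees
  all_sub <- list(p_ids, q_ids, m_ids)
  n_val <- length(labels$valence$positive)
  val_sub <- rep_len(seq_along(all_sub), n_val)
  val_pos_nodes <- vapply(val_sub, function(s) sample(all_sub[[s]], 1L),
                          character(1))
  val_neg_nodes <- vapply(val_sub, function(s) sample(all_sub[[s]], 1L),
                          character(1))

  # dataset word candidates: congruent node and its mirror, plus one
  # pre-drawn uniform each.  Attachment is stratified: at congruence
  # probability pi, exactly round(pi * n) words of each group (those with
  # the smallest uniforms) attach congruently, so the injected effect --
  # not attachment sampling noise -- sets the group difference, and at
  # pi = 0.5 each group splits exactly half/half across the poles.
  # Ranking the common uniforms keeps the assignment monotone in pi.
  is_data <- groups != "none"
  slot <- sample.int(n_pole, sum(is_data), replace = TRUE)
  cong_node <- ifelse(groups[is_data] == "beautiful", p_ids[slot],
                      q_ids[slot])
  opp_node <- ifelse(groups[is_data] == "beautiful", q_ids[slot],
                     p_ids[slot])
  u <- stats::runif(sum(is_data))
  u_rank <- stats::ave(u, groups[is_data], FUN = rank)
  grp_n <- stats::ave(u, groups[is_data], FUN = length)
  congruent_at <- function(p_cong) u_rank <= round(p_cong * grp_n)
  filler_node <- sample(c(p_ids, q_ids, m_ids), sum(!is_data),
                        replace = TRUE)

  # AP of every node against the label nodes, from the tree distances
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  D <- igraph::distances(g, mode = "all")
  dep <- max(D[, "root"])
  ap_node <- (rowMeans(D[, ap_neg_nodes, drop = FALSE]) -
                rowMeans(D[, ap_pos_nodes, drop = FALSE])) / (2 * dep)

  beautiful <- groups[is_data] == "beautiful"
  zmean_beautiful <- function(p_cong) {
    ap <- ifelse(congruent_at(p_cong), ap_node[cong_node], ap_node[opp_node])
    z <- (ap - mean(ap)) / stats::sd(ap)
    mean(z[beautiful])
  }
  if (!is.null(config$ap_noise)) {
    p_cong <- 1 - config$ap_noise / 2
  } else if (config$ap_effect == 0) {
    p_cong <- 0.5
  } else {
    target <- config$ap_effect * sum(!beautiful) / length(beautiful)
    lo <- 0.5; hi <- 1
    for (it in seq_len(40L)) {
      mid_p <- (lo + hi) / 2
      if (zmean_beautiful(mid_p) < target) lo <- mid_p else hi <- mid_p
    }
    p_cong <- (lo + hi) / 2
  }
  word_node <- character(length(words))
  word_node[is_data] <- ifelse(congruent_at(p_cong), cong_node, opp_node)
  word_node[!is_data] <- filler_node

  lemmas <- data.frame(
    lemma = c(words, labels$ap$positive, labels$ap$negative,
              labels$valence$positive, labels$valence$negative),
    node = c(word_node, ap_pos_nodes, ap_neg_nodes,
             val_pos_nodes, val_neg_nodes),
    stringsAsFactors = FALSE)
  tax <- semantic_taxonomy(edges, lemmas)

  ap_real <- ap_node[word_node[is_data]]
  z <- (ap_real - mean(ap_real)) / stats::sd(ap_real)
  list(taxonomy = tax, congruence = p_cong,
       ap_zmeans = c(beautiful = mean(z[beautiful]),
                     ugly = mean(z[!beautiful])))
}

#' Generate a complete synthetic word-beauty study
#'
#' Composes the word-form, frequency and taxonomy generators with the
#' default label sets into a self-contained study: every dataset word is
#' present in both resources (hit rate 1 by construction) and the injected
#' group effects are recorded as ground truth for recovery checks.
#'
#' @param config A [generator_config()].
#' @return An object of class `synthetic_study` with elements
#'   `frequency_table`, `taxonomy`, `valence_labels`, `ap_labels`,
#'   `dataset` (data frame of `word`, `label`), `ground_truth` and
#'   `config`.
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  labels <- default_label_sets()
  seeds <- derive_seeds(config$seed, 3L)
  reserved <- c(labels$valence$positive, labels$valence$negative,
                labels$ap$positive, labels$ap$negative)
  words <- generate_word_forms(config, seed = seeds[1L], reserved = reserved)
  freq <- generate_frequencies(words, config, seed = seeds[2L])
  taxres <- generate_taxonomy(words, labels, config, seed = seeds[3L])
  n_data <- config$n_beautiful + config$n_ugly
  dataset <- data.frame(
    word = words[seq_len(n_data)],
    label = attr(words, "group")[seq_len(n_data)],
    stringsAsFactors = FALSE)
  m1 <- config$ap_effect * config$n_ugly / n_data
  ground_truth <- list(
    ap_effect = config$ap_effect,
    ap_zmean_targets = c(beautiful = m1,
                         ugly = -m1 * config$n_beautiful / config$n_ugly),
    ap_zmeans_realized = taxres$ap_zmeans,
    congruence = taxres$congruence,
    sonority_means = stats::setNames(config$sonority_means,
                                     c("beautiful", "ugly")),
    length_means = c(beautiful = config$length_mean,
                     ugly = config$length_mean))
  structure(list(frequency_table = freq,
                 taxonomy = taxres$taxonomy,
                 valence_labels = labels$valence,
                 ap_labels = labels$ap,
                 dataset = dataset,
                 ground_truth = ground_truth,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic word-beauty study\n")
  print(x$config)
  print(x$frequency_table)
  print(x$taxonomy)
  cat(sprintf("Dataset: %d words; realized AP z-means %.3f / %.3f\n",
              nrow(x$dataset),
              x$ground_truth$ap_zmeans_realized["beautiful"],
              x$ground_truth$ap_zmeans_realized["ugly"]))
  invisible(x)
}

#' Featurize a synthetic study into a beauty dataset
#'
#' Convenience wrapper: filters the study's labeled words through
#' [intersect_targets()] and builds the [beauty_dataset()] from its own
#' resources.
#'
#' @param study A [generate_study()] result.
#' @return A [beauty_dataset()].
#' @export
study_dataset <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  targets <- intersect_targets(study$dataset, study$frequency_table,
                               study$taxonomy)
  build_beauty_dataset(targets, study$frequency_table, study$taxonomy,
                       study$valence_labels, study$ap_labels)
}
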