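# Independent brute-force oracles used to cross-check the implementation.

# All-pairs Hamming scan for orthographic neighborhood density.
oracle_orthographic_n <- function(word, lexicon) {
  lexicon <- setdiff(unique(lexicon), word)
  n <- 0L
  a <- strsplit(word, "")[[1L]]
  for (w in lexicon) {
    if (nchar(w) != nchar(word)) next
    b <- strsplit(w, "")[[1L]]
    if (sum(a != b) == 1L) n <- n + 1L
  }
  n
}

# Concordant-pair (Mann-Whitney) AUC with half credit for ties.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Breadth-first search over the undirected edge list.
oracle_bfs_dist <- function(edges, from, to) {
  nbr <- list()
  for (i in seq_len(nrow(edges))) {
    nbr[[edges$child[i]]] <- c(nbr[[edges$child[i]]], edges$parent[i])
    nbr[[edges$parent[i]]] <- c(nbr[[edges$parent[i]]], edges$child[i])
  }
  if (from == to) return(0)
  frontier <- from
  seen <- from
  d <- 0
  while (length(frontier) > 0L) {
    if (to %in% frontier) return(d)
    d <- d + 1
    frontier <- setdiff(unique(unlist(nbr[frontier])), seen)
    seen <- c(seen, frontier)
  }
  Inf
}

# Relatedness from the BFS oracle: best node pair, depth-normalized.
oracle_relatedness <- function(w1, w2, edges, lemmas, root) {
  nodes <- unique(c(edges$child, edges$parent))
  depth <- max(vapply(nodes, function(v) oracle_bfs_dist(edges, v, root),
                      numeric(1)))
  n1 <- lemmas$node[lemmas$lemma == w1]
  n2 <- lemmas$node[lemmas$lemma == w2]
  d <- min(outer(n1, n2, Vectorize(function(a, b)
    oracle_bfs_dist(edges, a, b))))
  1 - d / (2 * depth)
}

# One-way ANOVA from explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups,
                    function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, r2 = ssb / (ssb + ssw),
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# --- shared fixtures ------------------------------------------------------

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path, useBytes = FALSE)
  path
}

# Small hand-made taxonomy: root r, two branches, five lemma-bearing nodes.
#
#            r
#          /   \
#         n1    n2
#        /  \     \
#      n3    n4    n5
fixture_taxonomy <- function() {
  edges <- data.frame(child = c("n1", "n2", "n3", "n4", "n5"),
                      parent = c("r", "r", "n1", "n1", "n2"),
                      stringsAsFactors = FALSE)
  lemmas <- data.frame(
    lemma = c("alba", "bero", "ceno", "dima", "elka", "alba2"),
    node = c("n3", "n4", "n5", "n1", "n2", "n3"),
    stringsAsFactors = FALSE)
  list(edges = edges, lemmas = lemmas,
       tax = semantic_taxonomy(edges, lemmas))
}

# Random tree taxonomy with one lemma per node, for property tests.
random_fixture_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), integer(1)))
  ids <- c("root", sprintf("v%02d", 2:n_nodes))
  edges <- data.frame(child = ids[2:n_nodes],
                      parent = ids[parent[2:n_nodes]],
                      stringsAsFactors = FALSE)
  lemmas <- data.frame(lemma = sprintf("word%02d", seq_len(n_nodes)),
                       node = ids, stringsAsFactors = FALSE)
  list(edges = edges, lemmas = lemmas,
       tax = semantic_taxonomy(edges, lemmas))
}

# Linearly separable feature fixture for classifier tests.
separable_dataset <- function(n_pos = 20L, n_neg = 16L, seed = 42L,
                              margin = 5) {
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  features <- matrix(rnorm(n * 8), n, 8,
                     dimnames = list(NULL, qna_feature_names()))
  features[, "ap"] <- ifelse(labels == 1L, margin, -margin) + rnorm(n, 0, .2)
  beauty_dataset(sprintf("w%03d", seq_len(n)), labels, features)
}
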