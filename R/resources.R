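#' Construct a word-frequency table
#'
#' A frequency table maps normalized word forms (lowercased, umlauts
#' preserved) to non-negative token counts and stores the total token count.
#' It stands in for a large corpus-derived frequency list and is the source
#' of both surprisal values and the lexicon used for orthographic
#' neighborhood counts.
#'
#' @param counts Named numeric vector of non-negative integer counts; names
#'   are word forms.  Duplicate forms (after normalization) are summed.
#' @return An object of class `frequency_table` with elements `counts`
#'   (named, normalized, deduplicated) and `total_tokens`.
#' @export
frequency_table <- function(counts) {
  if (length(counts) == 0L)
    stop("frequency table is empty")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("all counts must be named by a word form")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  words <- normalize_word(names(counts))
  merged <- tapply(as.numeric(counts), factor(words, levels = unique(words)), sum)
  counts <- as.numeric(merged)
  names(counts) <- names(merged)
  total <- sum(counts)
  if (total <= 0)
    stop("total token count must be positive")
  structure(list(counts = counts, total_tokens = total),
            class = "frequency_table")
}

#' Read a word-frequency table from a TSV file
#'
#' The file holds one `word<TAB>count` row per line, UTF-8, no header.
#' Lines starting with `#` and blank lines are ignored.  Word forms are
#' normalized and duplicate forms summed.
#'
#' @param path Path to the TSV file.
#' @return A [frequency_table()].
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L)
    stop("frequency file is empty: ", path)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("malformed frequency row at line ", rows[bad[1L]],
         ": expected 'word<TAB>count'")
  words <- vapply(parts, `[[`, character(1), 1L)
  count_str <- trimws(vapply(parts, `[[`, character(1), 2L))
  badc <- which(!grepl("^[0-9]+$", count_str))
  if (length(badc) > 0L)
    stop("invalid count at line ", rows[badc[1L]], ": '",
         count_str[badc[1L]], "' is not a non-negative integer")
  counts <- as.numeric(count_str)
  names(counts) <- words
  frequency_table(counts)
}

#' Write a frequency table to TSV
#'
#' @param x A [frequency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "frequency_table"))
  writeLines(sprintf("%s\t%d", names(x$counts), as.integer(x$counts)),
             con = path, useBytes = FALSE)
  invisible(path)
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Frequency table:", length(x$counts), "word forms,",
      format(x$total_tokens, big.mark = ","), "tokens\n")
  invisible(x)
}

freq_words <- function(x) names(x$counts)

#' Construct a semantic taxonomy
#'
#' A rooted is-a hierarchy of concept nodes (a DAG with a unique root) with
#' word forms attached to nodes through a lemma index.  All
#' semantic-relatedness features (word similarity, valence, aesthetic
#' potential) are computed from shortest paths in this graph.
#'
#' @param edges Data frame (or 2-column matrix) of `child`, `parent` node
#'   identifiers, one is-a link per row.
#' @param lemmas Data frame of `lemma`, `node` rows attaching word forms to
#'   concept nodes; a lemma may attach to several nodes.
#' @return An object of class `semantic_taxonomy` with elements `graph`
#'   (directed child-to-parent igraph), `nodes`, `root`, `depth` (maximum
#'   root distance) and `lemma_index` (word form to node-id list).
#' @export
semantic_taxonomy <- function(edges, lemmas) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L || nrow(edges) == 0L)
    stop("edge list must have rows of child, parent")
  names(edges)[1:2] <- c("child", "parent")
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) {
    cyc <- find_cycle(edges)
    stop("taxonomy contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  sinks <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0L]
  if (length(sinks) != 1L)
    stop("taxonomy must have exactly one root, found ",
         length(sinks), ": ", paste(sinks, collapse = ", "))
  root <- sinks
  d_to_root <- igraph::distances(g, to = root, mode = "out")[, 1L]
  if (any(!is.finite(d_to_root)))
    stop("node(s) cannot reach the root: ",
         paste(names(d_to_root)[!is.finite(d_to_root)], collapse = ", "))
  lemmas <- as.data.frame(lemmas, stringsAsFactors = FALSE)
  if (ncol(lemmas) < 2L || nrow(lemmas) == 0L)
    stop("lemma table must have rows of lemma, node")
  names(lemmas)[1:2] <- c("lemma", "node")
  lemmas$lemma <- normalize_word(lemmas$lemma)
  lemmas$node <- as.character(lemmas$node)
  unknown <- setdiff(lemmas$node, igraph::V(g)$name)
  if (length(unknown) > 0L)
    stop("lemma attached to unknown node(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  lemma_index <- split(lemmas$node, lemmas$lemma)
  lemma_index <- lapply(lemma_index, unique)
  structure(list(graph = g,
                 nodes = igraph::V(g)$name,
                 root = root,
                 depth = max(d_to_root),
                 lemma_index = lemma_index,
                 .cache = new.env(parent = emptyenv())),
            class = "semantic_taxonomy")
}

# Locate one directed cycle in an edge list by stripping sinks (Kahn) and
# then walking the remaining subgraph until a node repeats.
find_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  nodes <- unique(c(edges$child, edges$parent))
  repeat {
    has_out <- nodes[nodes %in% names(adj)]
    out_alive <- vapply(adj[has_out],
                        function(p) any(p %in% nodes), logical(1))
    alive <- has_out[out_alive]
    if (length(alive) == length(nodes)) break
    nodes <- alive
    if (length(nodes) == 0L) return(character(0))
  }
  walk <- nodes[1L]
  repeat {
    nxt <- intersect(adj[[walk[length(walk)]]], nodes)[1L]
    if (nxt %in% walk) {
      i <- match(nxt, walk)
      return(c(walk[i:length(walk)], nxt))
    }
    walk <- c(walk, nxt)
  }
}

#' Read a semantic taxonomy from edge-list and lemma TSV files
#'
#' Both files are UTF-8 TSV without header; `#` comment lines and blank
#' lines are ignored.  The edge file holds `child<TAB>parent` rows, the
#' lemma file `lemma<TAB>node` rows.
#'
#' @param edge_path Path to the edge-list file.
#' @param lemma_path Path to the lemma-attachment file.
#' @return A [semantic_taxonomy()].
#' @export
read_taxonomy <- function(edge_path, lemma_path) {
  semantic_taxonomy(read_two_col(edge_path, c("child", "parent")),
                    read_two_col(lemma_path, c("lemma", "node")))
}

read_two_col <- function(path, col_names) {
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L)
    stop("no data rows in ", path)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L)
    stop("malformed row at line ", rows[bad[1L]], " of ", path)
  out <- data.frame(a = vapply(parts, `[[`, character(1), 1L),
                    b = vapply(parts, `[[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  names(out) <- col_names
  out
}

#' Write a taxonomy to edge-list and lemma TSV files
#'
#' @param tax A [semantic_taxonomy()].
#' @param edge_path,lemma_path Output paths.
#' @return The two paths, invisibly.
#' @export
write_taxonomy <- function(tax, edge_path, lemma_path) {
  stopifnot(inherits(tax, "semantic_taxonomy"))
  el <- igraph::as_edgelist(tax$graph)
  writeLines(sprintf("%s\t%s", el[, 1L], el[, 2L]), con = edge_path)
  lemma <- rep(names(tax$lemma_index), lengths(tax$lemma_index))
  node <- unlist(tax$lemma_index, use.names = FALSE)
  writeLines(sprintf("%s\t%s", lemma, node), con = lemma_path)
  invisible(c(edge_path, lemma_path))
}

#' @export
print.semantic_taxonomy <- function(x, ...) {
  cat(sprintf("Semantic taxonomy: %d nodes, root '%s', depth %d, %d lemmas\n",
              length(x$nodes), x$root, x$depth, length(x$lemma_index)))
  invisible(x)
}

# Full undirected node-to-node shortest-path matrix, cached per taxonomy.
node_distances <- function(tax) {
  if (is.null(tax$.cache$D)) {
    tax$.cache$D <- igraph::distances(tax$graph, mode = "all")
  }
  tax$.cache$D
}

resource_words <- function(resource) {
  if (inherits(resource, "frequency_table")) freq_words(resource)
  else if (inherits(resource, "semantic_taxonomy")) names(resource$lemma_index)
  else if (is.character(resource)) normalize_word(resource)
  else stop("unsupported resource type: ", paste(class(resource), collapse = "/"))
}

#' Resource coverage ("hit rate") of a target word list
#'
#' The hit rate is the fraction of target words found in a lexical resource
#' after word-form normalization.
#'
#' @param targets Character vector of target word forms (non-empty).
#' @param resource A [frequency_table()], a [semantic_taxonomy()], or a
#'   plain character vector of word forms.
#' @return An object of class `coverage_report` with `n_targets`, `n_hit`,
#'   `hit_rate` and `missing` (missing forms, input order).
#' @export
coverage <- function(targets, resource) {
  if (length(targets) == 0L)
    stop("target word list is empty")
  targets <- normalize_word(targets)
  present <- targets %in% resource_words(resource)
  structure(list(n_targets = length(targets),
                 n_hit = sum(present),
                 hit_rate = sum(present) / length(targets),
                 missing = targets[!present]),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %d/%d targets (hit rate %.3f), %d missing\n",
              x$n_hit, x$n_targets, x$hit_rate, length(x$missing)))
  invisible(x)
}

#' Restrict labeled targets to words covered by both resources
#'
#' Mirrors the study's filtering step: only target words present in both the
#' frequency table and the semantic taxonomy survive to the analysis.
#'
#' @param targets Data frame with columns `word` and `label`.
#' @param freq A [frequency_table()].
#' @param tax A [semantic_taxonomy()].
#' @return The surviving rows of `targets` (words normalized), with the two
#'   per-resource [coverage()] reports attached as attribute `"coverage"`.
#' @export
intersect_targets <- function(targets, freq, tax) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "label") %in% names(targets)))
  targets$word <- normalize_word(targets$word)
  cov_freq <- coverage(targets$word, freq)
  cov_tax <- coverage(targets$word, tax)
  keep <- !(targets$word %in% cov_freq$missing) &
          !(targets$word %in% cov_tax$missing)
  out <- targets[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    stop("no target word is present in both resources; ",
         "check that the frequency table and taxonomy match the target list")
  attr(out, "coverage") <- list(frequency = cov_freq, taxonomy = cov_tax)
  out
}
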