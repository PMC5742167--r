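test_that("frequency table reads toy counts, normalizes and merges forms", {
  path <- write_tsv_lines(c("# corpus dump", "haus\t10", "baum\t5"))
  ft <- read_frequency_table(path)
  expect_s3_class(ft, "frequency_table")
  expect_equal(ft$total_tokens, 15)
  expect_length(ft$counts, 2L)
  expect_equal(unname(ft$counts["haus"]), 10)

  merged <- read_frequency_table(write_tsv_lines(c("Haus\t4", "haus\t6")))
  expect_length(merged$counts, 1L)
  expect_equal(unname(merged$counts["haus"]), 10)
  expect_equal(merged$total_tokens, 10)
})

test_that("malformed frequency rows are rejected with their line number", {
  expect_error(read_frequency_table(write_tsv_lines("haus\t-3")),
               "line 1")
  expect_error(read_frequency_table(write_tsv_lines(c("haus\t2",
                                                      "baum\tviele"))),
               "line 2")
  expect_error(read_frequency_table(write_tsv_lines(c("# only comments"))),
               "empty")
  expect_error(read_frequency_table(write_tsv_lines("haus 3")), "line 1")
})

test_that("frequency table round-trips through serialization", {
  ft <- frequency_table(c(zug = 7, "mähne" = 2, aal = 31))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_table(ft, path)
  ft2 <- read_frequency_table(path)
  expect_equal(ft2$counts, ft$counts)
  expect_equal(ft2$total_tokens, ft$total_tokens)
})

test_that("taxonomy loads chains and builds the lemma index", {
  edge_path <- write_tsv_lines(c("a\tb", "b\tc"))
  lemma_path <- write_tsv_lines(c("libelle\ta"))
  tax <- read_taxonomy(edge_path, lemma_path)
  expect_length(tax$nodes, 3L)
  expect_equal(tax$root, "c")
  expect_equal(tax$depth, 2)
  expect_equal(tax$lemma_index[["libelle"]], "a")
})

test_that("cycles and multiple roots are rejected", {
  lemmas <- data.frame(lemma = "x", node = "a")
  expect_error(
    semantic_taxonomy(data.frame(child = c("a", "b"), parent = c("b", "a")),
                      lemmas),
    "cycle")
  expect_error(
    semantic_taxonomy(data.frame(child = c("a", "c"), parent = c("b", "d")),
                      lemmas),
    "exactly one root")
  expect_error(
    semantic_taxonomy(data.frame(child = "a", parent = "b"),
                      data.frame(lemma = "x", node = "zzz")),
    "unknown node")
})

test_that("coverage matches a naive membership scan", {
  ft <- frequency_table(c(eins = 1, zwei = 2, drei = 3, vier = 4))
  full <- coverage(c("eins", "zwei", "drei", "vier"), ft)
  expect_equal(full$hit_rate, 1.0)
  expect_length(full$missing, 0L)

  partial <- coverage(c("eins", "zwei", "drei", "acht"), ft)
  expect_equal(partial$hit_rate, 0.75)
  expect_equal(partial$missing, "acht")
  expect_equal(partial$n_hit, 3L)

  expect_error(coverage(character(0), ft), "empty")

  # oracle equivalence on random word lists
  set.seed(7)
  lex <- unique(replicate(50, paste(sample(letters[1:4], 3, TRUE),
                                    collapse = "")))
  ft2 <- frequency_table(stats::setNames(seq_along(lex), lex))
  for (i in 1:10) {
    targets <- replicate(12, paste(sample(letters[1:4], 3, TRUE),
                                   collapse = ""))
    expect_equal(coverage(targets, ft2)$hit_rate,
                 mean(targets %in% lex))
  }
})

test_that("intersect_targets keeps exactly the words covered by both resources", {
  fx <- fixture_taxonomy()
  # tax lemmas: alba bero ceno dima elka; freq covers a different slice
  ft <- frequency_table(c(alba = 5, bero = 2, ceno = 9, dima = 1,
                          fuge = 4))
  targets <- data.frame(
    word = c("alba", "bero", "ceno", "dima", "elka", "fuge"),
    label = c("beautiful", "beautiful", "ugly", "ugly", "beautiful", "ugly"))
  kept <- intersect_targets(targets, ft, fx$tax)
  expect_equal(kept$word, c("alba", "bero", "ceno", "dima"))
  expect_equal(kept$label, c("beautiful", "beautiful", "ugly", "ugly"))
  cov <- attr(kept, "coverage")
  expect_equal(cov$frequency$n_hit, 5L)
  expect_equal(cov$taxonomy$n_hit, 5L)
  # survivors are a subset of the input and members of both resources
  expect_true(all(kept$word %in% targets$word))
  expect_true(all(kept$word %in% names(ft$counts)))
  expect_true(all(kept$word %in% names(fx$tax$lemma_index)))

  ident <- intersect_targets(targets[1:4, ], ft, fx$tax)
  expect_equal(ident$word, targets$word[1:4])

  disjoint <- frequency_table(c(qqq = 1))
  expect_error(intersect_targets(targets, disjoint, fx$tax),
               "no target word")
})
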