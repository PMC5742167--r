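test_that("syllable counting merges diphthongs and counts vowel nuclei", {
  expect_equal(count_syllables("libelle"), 3L)    # li-bel-le
  expect_equal(count_syllables("morgenröte"), 4L) # mor-gen-rö-te
  expect_equal(count_syllables("ei"), 1L)
  expect_equal(count_syllables("baum"), 1L)
  expect_equal(count_syllables("aue"), 2L)        # au + e
  expect_equal(count_syllables("MITTSOMMERNACHT"), 4L)
  expect_error(count_syllables("bcd"), "no vowel")
})

test_that("sonority score is the mean per-letter rank", {
  expect_equal(sonority_score("a"), 5)
  expect_equal(sonority_score("aal"), (5 + 5 + 4) / 3)
  expect_error(sonority_score("ha!"), "unclassifiable character '!'")

  # composition property: word score equals the mean of letter scores
  set.seed(31)
  scale <- default_sonority_scale()
  for (i in 1:20) {
    w <- paste(sample(names(scale$classes), sample(3:10, 1), TRUE),
               collapse = "")
    expect_equal(sonority_score(w),
                 mean(vapply(strsplit(w, "")[[1L]], sonority_score,
                             numeric(1))))
  }

  # custom rank override must stay ordered
  custom <- default_sonority_scale(ranks = c(plosive = 1, fricative = 1.5,
                                             nasal = 2, liquid = 3,
                                             glide = 3.5, vowel = 4))
  expect_equal(sonority_score("a", custom), 4)
  expect_error(default_sonority_scale(ranks = c(plosive = 5, fricative = 2,
                                                nasal = 3, liquid = 4,
                                                glide = 4.5, vowel = 1)),
               "strictly increase")
})

test_that("surprisal is -log2 of relative frequency and monotone", {
  ft <- frequency_table(c(nur = 1024))
  expect_equal(surprisal("nur", ft), 0)
  ft2 <- frequency_table(c(rar = 1, rest = 1048575))
  expect_equal(surprisal("rar", ft2), 20)
  ft3 <- frequency_table(c(acht = 8, rest = 1016))
  expect_equal(surprisal("acht", ft3), 7)
  expect_error(surprisal("fehlt", ft3), "not in frequency table")

  # strictly decreasing in count at fixed total
  counts <- c(a1 = 1, a2 = 5, a3 = 20, a4 = 100)
  ft4 <- frequency_table(counts)
  s <- vapply(names(counts), surprisal, numeric(1), freq = ft4)
  expect_true(all(diff(s) < 0))
  # enlarging the corpus raises every surprisal
  ft5 <- frequency_table(c(counts, filler = 1000))
  expect_true(all(vapply(names(counts), surprisal, numeric(1), freq = ft5) > s))
})

test_that("orthographic neighborhood equals the all-pairs Hamming oracle", {
  expect_equal(orthographic_n("abc", c("abc")), 0L)
  expect_equal(orthographic_n("hand",
                              c("hand", "band", "hund", "hang", "hans")), 4L)
  expect_equal(orthographic_n("xyzzy", c("ab", "abc")), 0L)

  # random lexicon over a small alphabet so neighbors actually occur
  set.seed(11)
  lex <- unique(replicate(400, paste(sample(c("a", "b", "n", "t"),
                                            sample(2:4, 1), TRUE),
                                     collapse = "")))
  for (w in sample(lex, 25)) {
    expect_equal(orthographic_n(w, lex), oracle_orthographic_n(w, lex))
  }
  # symmetry of the neighbor relation
  for (i in 1:50) {
    pair <- sample(lex, 2)
    expect_equal(oracle_orthographic_n(pair[1], pair[2]) == 1L,
                 oracle_orthographic_n(pair[2], pair[1]) == 1L)
  }
})

test_that("relatedness is symmetric, maximal at identity, and matches BFS", {
  fx <- fixture_taxonomy()
  tax <- fx$tax
  expect_equal(relatedness("alba", "alba", tax), 1.0)
  expect_equal(relatedness("alba", "alba2", tax), 1.0) # shared node n3
  expect_equal(relatedness("alba", "bero", tax),
               relatedness("bero", "alba", tax))
  # leaves n3, n4 under common parent n1: BFS distance 2, depth 2
  expect_equal(relatedness("alba", "bero", tax),
               oracle_relatedness("alba", "bero", fx$edges, fx$lemmas, "r"))
  expect_equal(relatedness("alba", "bero", tax), 1 - 2 / 4)
  expect_error(relatedness("alba", "nixda", tax), "unknown lemma")

  # random fixture: symmetry, range, oracle equality
  rfx <- random_fixture_taxonomy(15, seed = 5)
  lem <- rfx$lemmas$lemma
  for (i in 1:15) {
    pair <- sample(lem, 2)
    r12 <- relatedness(pair[1], pair[2], rfx$tax)
    expect_equal(r12, relatedness(pair[2], pair[1], rfx$tax))
    expect_gte(r12, 0)
    expect_lte(r12, 1)
    expect_equal(r12, oracle_relatedness(pair[1], pair[2], rfx$edges,
                                         rfx$lemmas, "root"))
  }
  # path method is an alternative kernel with the same extremes
  expect_equal(relatedness("alba", "alba", tax, method = "path"), 1.0)
  expect_lt(relatedness("alba", "ceno", tax, method = "path"), 1.0)
})

test_that("word similarity is the label-blind mean relatedness to other targets", {
  fx <- fixture_taxonomy()
  tax <- fx$tax
  expect_equal(word_similarity("alba", c("alba", "alba2"), tax), 1.0)
  expect_equal(word_similarity("alba", c("alba", "bero"), tax),
               relatedness("alba", "bero", tax))
  targets <- c("alba", "bero", "ceno", "dima", "elka")
  expected <- mean(vapply(setdiff(targets, "alba"), relatedness, numeric(1),
                          w1 = "alba", tax = tax))
  expect_equal(word_similarity("alba", targets, tax), expected)
  expect_error(word_similarity("alba", "alba", tax), "at least two")
  expect_error(word_similarity("fehlt", targets, tax), "not in the target")
})

test_that("label score is a signed contrast, antisymmetric under label swap", {
  fx <- fixture_taxonomy()
  tax <- fx$tax
  # mirrored labels at equal distance: contrast is zero
  mirror <- label_set("mirror", positive = "alba", negative = "bero")
  expect_equal(label_score("dima", mirror, tax), 0) # n1 equidistant to n3/n4
  # word identical to a positive label, negative farther away
  near <- label_set("near", positive = "alba2", negative = "ceno")
  s <- label_score("alba", near, tax)
  expect_gt(s, 0)
  expect_equal(s, relatedness("alba", "alba2", tax) -
                 relatedness("alba", "ceno", tax))
  # swapping positive and negative flips the sign exactly
  swapped <- label_set("near", positive = "ceno", negative = "alba2")
  expect_equal(label_score("alba", swapped, tax), -s)
  # unresolvable labels are dropped with a warning; empty side errors
  partial <- label_set("partial", positive = c("alba2", "nixda"),
                       negative = "ceno")
  expect_warning(s2 <- label_score("alba", partial, tax), "dropped")
  expect_equal(s2, s)
  lost <- label_set("lost", positive = "nixda", negative = "ceno")
  expect_error(suppressWarnings(label_score("alba", lost, tax)),
               "no resolvable label")
})

# minimal taxonomy containing an extra word plus the fixture lemmas
tax_with_word <- function(word) {
  fx <- fixture_taxonomy()
  semantic_taxonomy(fx$edges,
                    rbind(fx$lemmas, data.frame(lemma = word, node = "n5")))
}
val_libelle <- function() label_set("valence", "dima", "elka")
ap_libelle <- function() label_set("ap", "alba", "bero")

test_that("featurize composes the eight sub-operations deterministically", {
  fx <- fixture_taxonomy()
  tax <- fx$tax
  ft <- frequency_table(c(alba = 8, bero = 4, ceno = 2, dima = 1,
                          alma = 1, arba = 1000))
  targets <- c("alba", "bero", "ceno", "dima")
  val <- label_set("valence", positive = "dima", negative = "elka")
  ap <- label_set("ap", positive = "alba2", negative = "ceno")
  v <- featurize("alba", ft, tax, targets, val, ap)
  expect_named(v, qna_feature_names())
  expect_equal(unname(v["n_syllables"]), count_syllables("alba"))
  expect_equal(unname(v["sonority"]), sonority_score("alba"))
  expect_equal(unname(v["length"]), 4)
  expect_equal(unname(v["surprisal"]), surprisal("alba", ft))
  expect_equal(unname(v["neighborhood_n"]),
               oracle_orthographic_n("alba", names(ft$counts)))
  expect_equal(unname(v["similarity"]), word_similarity("alba", targets, tax))
  expect_equal(unname(v["valence"]), label_score("alba", val, tax))
  expect_equal(unname(v["ap"]), label_score("alba", ap, tax))
  # determinism
  expect_identical(v, featurize("alba", ft, tax, targets, val, ap))
  # failures name the word
  expect_error(featurize("fehlt", ft, tax, targets, val, ap), "fehlt")
  # letter count example
  expect_equal(unname(featurize("libelle", frequency_table(c(libelle = 1)),
                                tax_with_word("libelle"),
                                c("libelle", "alba"),
                                val_libelle(), ap_libelle())["length"]), 7)
})
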