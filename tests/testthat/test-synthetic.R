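test_that("word forms are unique, reproducible and group-calibrated", {
  cfg <- generator_config(seed = 3)
  w1 <- generate_word_forms(cfg)
  w2 <- generate_word_forms(cfg)
  expect_identical(w1, w2)
  expect_length(w1, cfg$lexicon_size)
  expect_false(anyDuplicated(w1) > 0)
  grp <- attr(w1, "group")
  expect_equal(sum(grp == "beautiful"), 75L)
  expect_equal(sum(grp == "ugly"), 55L)
  # every form is pronounceable enough to syllabify and score
  son <- vapply(w1[grp != "none"], sonority_score, numeric(1))
  expect_true(all(vapply(w1[1:50], count_syllables, integer(1)) >= 1L))
  # group sonority means approach the configured targets
  expect_lt(abs(mean(son[grp[grp != "none"] == "beautiful"]) - 3.12), 0.1)
  expect_lt(abs(mean(son[grp[grp != "none"] == "ugly"]) - 2.9), 0.1)
  # mean length close to the configured 12 letters
  expect_lt(abs(mean(nchar(w1[grp != "none"])) - 12), 1)

  expect_error(generator_config(lexicon_size = 100), "lexicon_size")
  expect_error(generator_config(length_mean = 1.5), "infeasible")
})

test_that("frequencies follow the Zipf law and cover every word", {
  cfg <- generator_config(lexicon_size = 130, seed = 5, zipf_exponent = 1)
  words <- sprintf("wort%03d", 1:100)
  ft <- generate_frequencies(words, cfg, seed = 7)
  expect_true(all(ft$counts >= 1))
  expect_setequal(names(ft$counts), words)
  sorted <- sort(ft$counts, decreasing = TRUE)
  expect_equal(unname(sorted[1] / sorted[10]), 10, tolerance = 0.2)
  ft2 <- generate_frequencies(words, cfg, seed = 7)
  expect_identical(ft$counts, ft2$counts)
  expect_error(generate_frequencies(c("a", "a"), cfg), "unique")
})

test_that("zero attachment noise separates the groups perfectly in AP", {
  cfg <- generator_config(seed = 21, ap_noise = 0, lexicon_size = 300)
  st <- generate_study(cfg)
  expect_equal(st$ground_truth$congruence, 1)
  expect_s3_class(st$taxonomy, "semantic_taxonomy") # DAG + unique root held
  ap <- vapply(st$dataset$word, label_score, numeric(1),
               labels = st$ap_labels, tax = st$taxonomy)
  beautiful <- st$dataset$label == "beautiful"
  expect_gt(min(ap[beautiful]), max(ap[!beautiful]))
  expect_true(all(ap[beautiful] > 0) && all(ap[!beautiful] < 0))
})

test_that("calibrated noise hits the reported AP group z-means", {
  st <- generate_study(generator_config(seed = 2))
  zm <- st$ground_truth$ap_zmeans_realized
  expect_lt(abs(zm["beautiful"] - 0.25), 0.1)
  expect_lt(abs(zm["ugly"] - (-0.33)), 0.1)
})

test_that("a generated study is complete, covered and seed-stable", {
  cfg <- generator_config(seed = 4, lexicon_size = 400)
  st <- generate_study(cfg)
  expect_equal(nrow(st$dataset), 130L)
  expect_equal(sum(st$dataset$label == "beautiful"), 75L)
  expect_equal(sum(st$dataset$label == "ugly"), 55L)
  expect_equal(coverage(st$dataset$word, st$frequency_table)$hit_rate, 1.0)
  expect_equal(coverage(st$dataset$word, st$taxonomy)$hit_rate, 1.0)

  st2 <- generate_study(cfg)
  expect_identical(st$dataset, st2$dataset)
  expect_identical(st$frequency_table$counts, st2$frequency_table$counts)
  expect_identical(igraph::as_edgelist(st$taxonomy$graph),
                   igraph::as_edgelist(st2$taxonomy$graph))

  st3 <- generate_study(generator_config(seed = 5, lexicon_size = 400))
  expect_false(identical(st$dataset$word, st3$dataset$word))
  expect_equal(dim(st3$dataset), dim(st$dataset))
})

test_that("study featurization yields a full 130 x 8 dataset", {
  st <- generate_study(generator_config(seed = 6, lexicon_size = 400))
  ds <- study_dataset(st)
  expect_s3_class(ds, "beauty_dataset")
  expect_equal(dim(ds$features), c(130L, 8L))
  expect_equal(colnames(ds$features), qna_feature_names())
  expect_equal(colMeans(ds$z_features), stats::setNames(rep(0, 8),
                                                        qna_feature_names()))
})
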