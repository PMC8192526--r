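test_that("negative slides with zero false-positive rate carry no lesions", {
  cfg <- default_slide_sim_config()
  cfg$fp$rate <- 0
  rec <- simulate_slide("NILM", seed = 1, config = cfg)
  tax <- load_taxonomy()
  cats <- tax$category[match(rec$refined_class, tax$index)]
  expect_true(all(cats == "normal"))  # only background SC remains
})

test_that("simulation is reproducible from the seed", {
  a <- simulate_slide("HSIL", seed = 99)
  b <- simulate_slide("HSIL", seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, simulate_slide("HSIL", seed = 100)))
  expect_error(simulate_slide("NOPE", seed = 1), "unknown truth")
})

test_that("SCC slides carry confident carcinoma-bearing targets", {
  tax <- load_taxonomy()
  hits <- vapply(1:50, function(s) {
    rec <- simulate_slide("SCC", seed = 5000 + s)
    any(rec$refined_class %in% 9:10)
  }, logical(1))
  expect_gt(mean(hits), 0.95)
  # refined probabilities of lesion targets follow the configured Beta(8, 2)
  probs <- unlist(lapply(1:120, function(s) {
    rec <- simulate_slide("SCC", seed = 6000 + s)
    rec$refined_prob[rec$refined_class %in% c(8:10)]
  }))
  expect_gt(length(probs), 1000)
  se <- sd(probs) / sqrt(length(probs))
  expect_lt(abs(mean(probs) - 8 / (8 + 2)), 3 * se)
})

test_that("corpus apportionment follows largest-remainder counting", {
  corpus <- make_corpus(100, class_mix = c(NILM = 0.8, HSIL = 0.2),
                        seed = 1)
  expect_equal(sum(corpus$manifest$truth == "NILM"), 80L)
  expect_equal(sum(corpus$manifest$truth == "HSIL"), 20L)

  # quotas 5.5/2.8/1.7: floors 5/2/1, two leftovers go to the largest
  # remainders (.8 then .7)
  odd <- make_corpus(10, class_mix = c(NILM = 0.55, HSIL = 0.28,
                                       LSIL = 0.17), seed = 1)
  expect_equal(as.vector(table(odd$manifest$truth)[c("NILM", "HSIL", "LSIL")]),
               c(5L, 3L, 2L))

  empty <- make_corpus(0, seed = 1)
  expect_equal(nrow(empty$manifest), 0L)
  expect_length(empty$records, 0L)
  expect_error(make_corpus(10, class_mix = c(NILM = 0.6, HSIL = 0.2),
                           seed = 1), "sum to 1")
})

test_that("a corpus regenerates byte-identically from its manifest", {
  corpus <- make_corpus(12, seed = 77)
  again <- corpus_from_manifest(corpus$manifest)
  expect_identical(again$records, corpus$records)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_corpus(corpus, d1)
  write_corpus(again, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("tile presets perturb the intended quality factor", {
  cfg <- default_image_sim_config()
  cfg$cellularity <- 0
  cfg$noise_sd <- 0  # noise-free background: Otsu has nothing to split
  bare <- simulate_tile("qualified", 3, cfg)
  expect_lt(cell_area_ratio(to_grayscale(bare)), 0.01)
  cfg$noise_sd <- 4

  cfg$cellularity <- 0.30
  planted <- simulate_tile("qualified", 4, cfg)
  expect_lt(abs(cell_area_ratio(to_grayscale(planted)) - 0.30), 0.02)
  expect_lt(abs(attr(planted, "coverage") - 0.30), 0.02)

  sharp <- simulate_tile("qualified", 5)
  blurred <- simulate_tile("defocus", 5)
  expect_lt(focus_score(to_grayscale(blurred)),
            focus_score(to_grayscale(sharp)))

  expect_identical(simulate_tile("poor-stain", 6), simulate_tile("poor-stain", 6))
})

test_that("greater class separation raises downstream member AUC", {
  # isolate the probability knob: positives carry TRI targets (no patch or
  # nucleus channels) at the same Poisson rate as the negatives' TRI false
  # positives, so only the probability distributions differ between classes
  mix <- c(NILM = 0.5, TRI = 0.5)
  auc_at <- function(shape1, shape2, seed) {
    cfg <- default_slide_sim_config()
    cfg$lesions$TRI <- data.frame(class = "TRI", mean_count = 3,
                                  shape1 = shape1, shape2 = shape2,
                                  stringsAsFactors = FALSE)
    cfg$fp$rate <- 3
    cfg$fp$classes <- "TRI"
    corpus <- make_corpus(100, class_mix = mix, seed = seed, config = cfg)
    X <- feature_matrix(lapply(corpus$records, aggregate_slide))
    y <- as.integer(corpus$manifest$truth == "TRI")
    s1 <- train_stage1(X, y, k = 3L, seed = seed, nrounds = 30L)
    sc <- member_scores(s1, X)
    mean(vapply(1:3, function(f)
      rank_auc(sc[s1$folds == f, f], y[s1$folds == f]), numeric(1)))
  }
  seeds <- c(201, 202, 203, 204, 205)
  weak <- mean(vapply(seeds, function(s) auc_at(2, 6, s), numeric(1)))
  strong <- mean(vapply(seeds, function(s) auc_at(8, 2, s), numeric(1)))
  expect_gt(strong, weak)
  expect_gt(strong, 0.75)
})
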