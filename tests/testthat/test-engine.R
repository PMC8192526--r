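test_that("any-positive ensemble rule", {
  expect_false(ensemble_positive(rep(FALSE, 10)))
  expect_true(ensemble_positive(c(rep(FALSE, 9), TRUE)))
  expect_true(ensemble_positive(rep(TRUE, 10)))
  expect_error(ensemble_positive(logical(0)), "at least one")
})

test_that("subtype argmax breaks ties toward the less severe class", {
  expect_equal(subtype_from_probs(c(0.1, 0.2, 0.1, 0.5, 0.1)), "HSIL")
  expect_equal(subtype_from_probs(rep(0.2, 5)), "ASCUS")
  expect_equal(subtype_from_probs(c(0.1, 0.3, 0.3, 0.2, 0.1)), "LSIL")
  m <- rbind(c(0, 0, 0, 0, 1), c(1, 0, 0, 0, 0))
  expect_equal(subtype_from_probs(m), c("SCC", "ASCUS"))
})

test_that("logic tree fires branches on qualifying-count rules", {
  cfg <- default_logic_config()
  tri_rule <- cfg; tri_rule$min_prob[tri_rule$branch == "TRI"] <- 0.9
  tri_rule$min_count[tri_rule$branch == "TRI"] <- 3L
  rec <- target_records("s1",
    box = data.frame(x = (0:4) * 100L, y = 0L, width = 50L, height = 50L),
    det_class = "TRI", det_prob = 0.95, refined_class = 16L,
    refined_prob = 0.95)
  fired <- logic_tree_decide(rec, tri_rule)
  expect_equal(as.character(fired), "TRI")
  expect_equal(attr(fired, "counts")[["TRI"]], 5L)

  expect_length(logic_tree_decide(empty_records(), cfg), 0)

  # merged AGC: AGC_A and AGC_B patterns pool into one branch
  agc <- target_records("s1",
    box = data.frame(x = c(0L, 100L, 200L), y = 0L, width = 50L, height = 50L),
    det_class = "AGC", det_prob = 0.9, refined_class = c(1L, 1L, 2L),
    refined_prob = 0.92)
  cfg3 <- cfg; cfg3$min_count[cfg3$branch == "AGC"] <- 3L
  expect_equal(as.character(logic_tree_decide(agc, cfg3)), "AGC")
  cfg4 <- cfg; cfg4$min_count[cfg4$branch == "AGC"] <- 4L
  expect_length(logic_tree_decide(agc, cfg4), 0)

  bad <- cfg; bad$min_prob[1] <- 1.5
  expect_error(logic_tree_decide(agc, bad), "malformed")
})

test_that("final report keeps one lesion by clinical priority", {
  r <- finalize_report("s1", FALSE)
  expect_equal(r$final_tbs, "NILM")
  expect_false(r$priority_applied)

  r <- finalize_report("s1", TRUE, subtype = "LSIL", other_calls = "TRI")
  expect_equal(r$final_tbs, "LSIL")
  expect_true(r$priority_applied)

  r <- finalize_report("s1", FALSE, other_calls = "CAN")
  expect_equal(r$final_tbs, "CAN")
  expect_false(r$priority_applied)

  r <- finalize_report("s1", TRUE, subtype = "ASCUS",
                       other_calls = c("AGC", "EMC"))
  expect_equal(r$final_tbs, "AGC")  # AGC outranks ASCUS and EMC
})

# small shared training problem for stage-1 unit checks
small_stage1_data <- function(n = 120, seed = 21) {
  corpus <- make_corpus(n, class_mix = c(NILM = 0.5, HSIL = 0.25,
                                         ASCUS = 0.25), seed = seed)
  X <- feature_matrix(lapply(corpus$records, aggregate_slide))
  y <- as.integer(corpus$manifest$truth %in% c("HSIL", "ASCUS"))
  list(X = X, y = y)
}

test_that("stage-1 ensemble trains one member per fold and separates", {
  d <- small_stage1_data()
  s1 <- train_stage1(d$X, d$y, k = 5L, seed = 3L)
  expect_length(s1$members, 5L)
  expect_setequal(unique(s1$folds), 1:5)
  # held-out AUC beats chance for every member
  sc <- member_scores(s1, d$X)
  for (f in 1:5) {
    held <- s1$folds == f
    expect_gt(rank_auc(sc[held, f], d$y[held]), 0.5)
  }
  # reproducible folding from the seed
  expect_equal(train_stage1(d$X, d$y, k = 5L, seed = 3L)$folds, s1$folds)
  expect_error(train_stage1(d$X, rep(1L, nrow(d$X)), k = 5L),
               "both positive and negative")
})

test_that("k = 1 degenerates to a single thresholded model", {
  d <- small_stage1_data(60, seed = 22)
  s1 <- train_stage1(d$X, d$y, k = 1L, seed = 4L)
  expect_length(s1$members, 1L)
  pr <- predict_stage1(s1, d$X)
  expect_equal(pr$positive, pr$scores[, 1] >= s1$thresholds[1])
})

test_that("uninformative features give chance-level held-out AUC", {
  set.seed(13)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(0:1, each = n / 2)  # labels independent of features
  s1 <- train_stage1(X, y, k = 5L, seed = 5L, nrounds = 20L)
  sc <- member_scores(s1, X)
  aucs <- vapply(1:5, function(f)
    rank_auc(sc[s1$folds == f, f], y[s1$folds == f]), numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("sensitivity tuning reaches 1.0 without losing specificity on
           separable data", {
  d <- small_stage1_data(140, seed = 23)
  s1 <- train_stage1(d$X, d$y, k = 5L, seed = 6L)
  before <- predict_stage1(s1, d$X)
  tuned <- tune_sensitivity(s1, d$X, d$y)
  after <- predict_stage1(tuned, d$X)
  expect_equal(mean(after$positive[d$y == 1]), 1)
  expect_gte(mean(!after$positive[d$y == 0]),
             mean(!before$positive[d$y == 0]))
  expect_error(tune_sensitivity(s1, d$X, rep(0L, nrow(d$X))), "no positive")

  # bounds of the threshold space
  zero <- s1; zero$thresholds <- rep(0, 5)
  pz <- predict_stage1(zero, d$X)
  expect_equal(mean(pz$positive[d$y == 1]), 1)
  expect_equal(mean(!pz$positive[d$y == 0]), 0)
  one <- s1; one$thresholds <- rep(1 + 1e-9, 5)
  expect_false(any(predict_stage1(one, d$X)$positive))
})

test_that("stage-2 recovers generated subtypes and validates schema", {
  fix <- engine_fixture()
  rec <- simulate_slide("SCC", seed = 31337, slide_id = "scc1")
  X <- feature_matrix(list(aggregate_slide(rec)))
  pred <- predict_stage2_subtype(X, fix$engine$stage2)
  expect_equal(pred$subtype, "SCC")
  bad <- X[, sample(ncol(X)), drop = FALSE]
  expect_error(predict_stage2_subtype(bad, fix$engine$stage2),
               "schema mismatch")
  expect_error(train_stage2(X, "WRONG"), "subtypes must be")
})

test_that("a trained engine round-trips through its persisted bundle", {
  fix <- engine_fixture()
  dir <- withr::local_tempdir()
  save_engine(fix$engine, dir)
  eng2 <- load_engine(dir)
  sub <- fix$test$records[1:20]
  r1 <- predict_tbs(fix$engine, sub)
  r2 <- predict_tbs(eng2, sub)
  expect_equal(vapply(r1, `[[`, "", "final_tbs"),
               vapply(r2, `[[`, "", "final_tbs"))
  expect_equal(r1[[1]]$squamous_branch$subtype_probs,
               r2[[1]]$squamous_branch$subtype_probs, tolerance = 1e-7)
})

test_that("split-count importance of trained members covers the schema", {
  fix <- engine_fixture()
  counts <- booster_split_counts(fix$engine$stage1$members[[1]],
                                 fix$engine$stage1$feature_names)
  expect_length(counts, 121L)
  imp <- importance_from_splits(counts)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_gt(sum(counts), 0)
})
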