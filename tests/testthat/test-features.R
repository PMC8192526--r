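test_that("the default schema has 121 uniquely named features", {
  sch <- default_feature_schema()
  expect_equal(nrow(sch), 121L)
  expect_false(anyDuplicated(sch$name) > 0)
  expect_true(all(table(sch$source) > 0))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_feature_schema(sch, path)
  expect_equal(read_feature_schema(path), sch)
})

test_that("aggregation handles empty slides and threshold counts", {
  sch <- default_feature_schema()
  fv <- aggregate_slide(empty_records(), sch)
  counts <- sch$statistic %in% c("count", "count-above-threshold")
  expect_true(all(fv$values == 0))
  expect_true(all(fv$missing[!counts]))
  expect_false(any(fv$missing[counts]))

  rec <- target_records("s1",
    box = data.frame(x = c(0L, 10L, 20L), y = 0L, width = 50L, height = 50L),
    det_class = "KC", det_prob = c(0.9, 0.8, 0.2),
    refined_class = 4L, refined_prob = c(0.9, 0.8, 0.2))
  fv <- aggregate_slide(rec, sch)
  expect_equal(unname(fv$values["ref_KC_n_ge50"]), 2)
  expect_equal(unname(fv$values["det_KC_count"]), 3)
  expect_equal(unname(fv$values["total_targets"]), 3)
  # no SCC_R targets: max-prob is 0 with the missing flag set
  expect_equal(unname(fv$values["ref_SCC_R_max_prob"]), 0)
  expect_true(fv$missing[["ref_SCC_R_max_prob"]])
})

test_that("aggregation matches the naive enumeration oracle", {
  sch <- default_feature_schema()
  for (s in 1:6) {
    truth <- c("HSIL", "LSIL", "TRI", "NILM", "SCC", "AGC")[s]
    rec <- simulate_slide(truth, seed = 100 + s)
    got <- aggregate_slide(rec, sch)
    want <- oracle_aggregate(rec, sch)
    expect_equal(got$values, want$values, tolerance = 1e-12)
    expect_equal(got$missing, want$missing)
  }
})

test_that("aggregation is permutation-invariant and counts are additive", {
  sch <- default_feature_schema()
  rec <- simulate_slide("HSIL", seed = 7)
  set.seed(3)
  shuf <- rec[sample(nrow(rec)), , drop = FALSE]
  expect_equal(aggregate_slide(shuf, sch)$values,
               aggregate_slide(rec, sch)$values)

  rec2 <- simulate_slide("LSIL", seed = 8, slide_id = rec$slide_id[1])
  joint <- aggregate_slide(rbind(rec, rec2), sch)$values
  parts <- aggregate_slide(rec, sch)$values + aggregate_slide(rec2, sch)$values
  counts <- sch$statistic %in% c("count", "count-above-threshold")
  expect_equal(joint[counts], parts[counts])
})

test_that("records outside the schema scope are dropped with a warning", {
  rec <- target_records("s1",
    box = data.frame(x = 0L, y = 0L, width = 10L, height = 10L),
    det_class = "NOT_A_CLASS", det_prob = 0.9,
    refined_class = 4L, refined_prob = 0.9)
  expect_warning(fv <- aggregate_slide(rec), "outside the schema")
  expect_equal(unname(fv$values["total_targets"]), 0)
})

test_that("split-count importance normalizes to 1 and keeps order", {
  imp <- importance_from_splits(c(a = 3, b = 1, c = 0))
  expect_equal(imp$importance, c(0.75, 0.25, 0))
  expect_equal(imp$feature, c("a", "b", "c"))
  expect_equal(importance_from_splits(5)$importance, 1)
  expect_equal(importance_from_splits(c(0, 0))$importance, c(0, 0))
  set.seed(9)
  for (k in 1:10) {
    cts <- rpois(20, 3)
    s <- sum(importance_from_splits(cts)$importance)
    expect_equal(s, if (sum(cts) > 0) 1 else 0, tolerance = 1e-9)
  }
  expect_error(importance_from_splits(c(-1, 2)), "non-negative")
})

test_that("feature matrices carry missingness as NA for the booster", {
  fvs <- lapply(c(1, 2), function(s)
    aggregate_slide(simulate_slide("NILM", s, sprintf("n%d", s))))
  X <- feature_matrix(fvs)
  expect_equal(dim(X), c(2L, 121L))
  expect_true(anyNA(X))            # NILM slides lack most lesion stats
  X0 <- feature_matrix(fvs, missing_as_na = FALSE)
  expect_false(anyNA(X0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(X0, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), X0, ignore_attr = TRUE)
})
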