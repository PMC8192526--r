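make_recs <- function() {
  target_records(
    slide_id = "s1",
    box = data.frame(x = c(0L, 100L, 200L), y = c(0L, 50L, 60L),
                     width = c(80L, 90L, 100L), height = c(80L, 90L, 100L)),
    det_class = c("KC", "ASC_H", "TRI"),
    det_prob = c(0.9, 0.7, 0.95),
    refined_class = c(4L, 8L, 16L),
    refined_prob = c(0.85, 0.6, 0.97),
    patch_label = c("True_LSIL", "True_HSIL", NA),
    patch_prob = c(0.8, 0.7, NA),
    nucleus = data.frame(mean_gray = c(NA, 80, NA), area_px = c(NA, 1300, NA),
                         n_components = c(NA, 1L, NA)))
}

test_that("record invariants are enforced", {
  rec <- make_recs()
  expect_equal(nrow(rec), 3L)
  bad <- rec; bad$det_prob[1] <- 1.2
  expect_error(validate_records(bad), "\\[0, 1\\]")
  bad <- rec; bad$patch_label[3] <- "True_HSIL"; bad$patch_prob[3] <- 0.5
  expect_error(validate_records(bad), "squamous")
  bad <- rec; bad$nucleus_mean_gray[1] <- 90  # KC is not segmented
  expect_error(validate_records(bad), "ASC_L_S")
  bad <- rec; bad$width[2] <- 0L
  expect_error(validate_records(bad), "positive")
})

test_that("JSON-lines round-trips records exactly", {
  rec <- make_recs()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_records_jsonl(rec, path)
  back <- read_records_jsonl(path)
  rownames(rec) <- rownames(back) <- NULL
  expect_equal(back, rec)
  # empty stream
  write_records_jsonl(empty_records(), path)
  expect_equal(nrow(read_records_jsonl(path)), 0L)
})

test_that("IoU deduplication suppresses lower-probability duplicates", {
  rec <- target_records(
    slide_id = "s1",
    box = data.frame(x = c(0L, 2L, 500L), y = c(0L, 2L, 500L),
                     width = c(100L, 100L, 100L), height = c(100L, 100L, 100L)),
    det_class = "KC", det_prob = c(0.9, 0.6, 0.5),
    refined_class = 4L, refined_prob = 0.8)
  kept <- dedup_records(rec, iou_threshold = 0.5)
  expect_equal(nrow(kept), 2L)
  expect_true(0.9 %in% kept$det_prob)   # highest prob survives
  expect_false(0.6 %in% kept$det_prob)  # its near-duplicate does not
  expect_equal(nrow(dedup_records(rec, NULL)), 3L)  # disabled by default
})

test_that("ASAP XML round-trips annotation targets exactly", {
  targets <- data.frame(
    slide_id = "sl7", x = c(120L, 4000L), y = c(340L, 5500L),
    width = c(200L, 608L), height = c(150L, 400L), class_index = c(4L, 16L),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".xml")
  write_asap_annotations(targets, path)
  back <- read_asap_annotations(path, slide_id = "sl7")
  expect_equal(back, targets)
  # a KC rectangle resolves to class index 4
  expect_equal(back$class_index[1], 4L)
})

test_that("ASAP reader handles empty and malformed documents", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<ASAP_Annotations><Annotations/></ASAP_Annotations>", path)
  expect_equal(nrow(read_asap_annotations(path)), 0L)
  writeLines("<ASAP_Annotations><Annotations>", path)
  expect_error(read_asap_annotations(path), "malformed")
  writeLines(paste0(
    '<ASAP_Annotations><Annotations>',
    '<Annotation Name="A" Type="Rectangle" PartOfGroup="NOPE">',
    '<Coordinates><Coordinate Order="0" X="0" Y="0"/>',
    '<Coordinate Order="1" X="5" Y="5"/></Coordinates>',
    '</Annotation></Annotations></ASAP_Annotations>'), path)
  expect_error(read_asap_annotations(path), "unknown annotation class")
})
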