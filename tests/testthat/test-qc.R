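test_that("quality-control tiling truncates and flags edge tiles", {
  expect_equal(nrow(tile_image(c(12000, 6000))), 2L)
  one <- tile_image(c(6000, 6000))
  expect_equal(nrow(one), 1L)
  expect_false(one$edge)
  sliver <- tile_image(c(6001, 6000))
  expect_equal(nrow(sliver), 2L)
  expect_equal(sliver$width[2], 1L)
  expect_true(sliver$edge[2])
  # exact cover, never padded
  g <- tile_image(c(13000, 7000), tile_size = 6000L)
  expect_equal(sum(g$width[g$y == 0] ), 13000L)
  expect_true(all(g$x + g$width <= 13000L & g$y + g$height <= 7000L))
})

test_that("focus score equals the direct-convolution oracle", {
  expect_equal(focus_score(matrix(37, 20, 20)), 0)
  # single impulse on zeros, hand-checkable response
  imp <- matrix(0, 9, 9); imp[5, 5] <- 10
  expect_equal(focus_score(imp), oracle_focus(imp))
  set.seed(41)
  for (k in 1:5) {
    m <- matrix(runif(15 * 12, 0, 255), 15, 12)
    expect_equal(focus_score(m), oracle_focus(m), tolerance = 1e-12)
  }
  expect_error(focus_score(matrix(1, 2, 5)), "3x3")
})

test_that("defocus strictly lowers the focus score (property)", {
  set.seed(42)
  for (k in 1:5) {
    img <- matrix(runif(64 * 64, 0, 255), 64, 64)
    blurred <- EBImage::gblur(img, sigma = 1 + k / 2)
    expect_lt(focus_score(blurred), focus_score(img))
  }
  sharp <- matrix(c(0, 255), 32, 32)  # checkerboard stripes
  expect_lt(focus_score(EBImage::gblur(sharp, 2)), focus_score(sharp))
})

test_that("HSI histograms land mass in the expected bins", {
  gray_tile <- array(128, c(8, 8, 3))
  h <- his_features(gray_tile)
  expect_equal(h$s[1], 1)  # zero saturation
  expect_equal(sum(h$h), 1); expect_equal(sum(h$i), 1); expect_equal(sum(h$s), 1)

  black <- array(0, c(8, 8, 3))
  expect_equal(his_features(black)$i[1], 1)

  two <- array(0, c(8, 8, 3))
  two[, 1:4, 1] <- 255  # left half pure red (hue 0)
  two[, 5:8, 2] <- 255  # right half pure green (hue 1/3)
  hh <- his_features(two)$h
  expect_equal(sort(hh[hh > 0]), c(0.5, 0.5))
  expect_equal(hh[1], 0.5)                      # red in the first bin
  expect_equal(hh[floor(32 / 3) + 1], 0.5)      # green at 1/3 of the circle
})

test_that("Otsu cell-area ratio equals brute-force threshold search", {
  set.seed(43)
  # strictly bimodal synthetic: exactly 30% dark pixels
  tile <- matrix(220, 50, 40)
  tile[sample(2000, 600)] <- 40
  expect_equal(otsu_threshold(tile), oracle_otsu(tile))
  expect_equal(cell_area_ratio(tile), 0.30)

  expect_equal(cell_area_ratio(matrix(77, 10, 10)), 0)  # constant convention

  dark <- matrix(0, 10, 10); dark[1, 1] <- 255
  expect_equal(cell_area_ratio(dark), 99 / 100)

  for (k in 1:8) {
    img <- matrix(sample(0:255, 600, replace = TRUE), 30, 20)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
    r <- cell_area_ratio(img)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("the trained gate separates quality presets", {
  fix <- qc_fixture()
  cfg <- default_image_sim_config()
  ok <- qc_gate(list(simulate_tile("qualified", 7070, cfg)), fix$gate, "q")
  expect_equal(ok$verdict, "qualified")
  blur <- qc_gate(list(simulate_tile("defocus", 7071, cfg)), fix$gate, "d")
  expect_equal(blur$verdict, "unqualified")
  expect_gte(ok$verdict_prob, 0); expect_lte(ok$verdict_prob, 1)
  # single-tile slide: verdict defined, no error
  expect_true(blur$verdict %in% c("qualified", "unqualified"))
  expect_error(qc_gate(list(), fix$gate), "at least one tile")
  expect_error(qc_gate(list(simulate_tile("qualified", 1, cfg)),
                       list(booster = NULL)), "untrained")
})
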