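# Digital pathology image quality control (DPIQC): tile a digitized smear,
# compute focus (variance of Laplacian), colour (HSI histograms) and
# cellularity (Otsu foreground ratio) features per tile, and gate the slide
# with a boosted classifier.

#' Tile an image into a quality-control grid
#'
#' @param dims Integer `c(width, height)` of the image in pixels.
#' @param tile_size Nominal tile side, default 6000 px.
#' @return data.frame of tile origins and sizes (`x, y, width, height`,
#'   0-based) covering the image exactly; edge tiles are truncated, never
#'   padded, and flagged with `edge = TRUE`.
#' @export
#' @examples
#' nrow(tile_image(c(12000, 6000)))  # 2
tile_image <- function(dims, tile_size = 6000L) {
  w <- as.integer(dims[1]); h <- as.integer(dims[2])
  stopifnot(w > 0L, h > 0L, tile_size > 0L)
  xs <- seq.int(0L, w - 1L, by = tile_size)
  ys <- seq.int(0L, h - 1L, by = tile_size)
  grid <- expand.grid(x = xs, y = ys)
  grid$width <- pmin(tile_size, w - grid$x)
  grid$height <- pmin(tile_size, h - grid$y)
  grid$edge <- grid$width < tile_size | grid$height < tile_size
  grid
}

#' Variance-of-Laplacian focus score
#'
#' Convolves the tile with the 4-neighbour 3x3 Laplacian stencil
#' (centre -4, N/S/E/W +1) over the valid interior (no padding) and returns
#' the population variance of the response. Zero for constant tiles; larger
#' means sharper.
#'
#' @param gray_tile Numeric matrix of gray values.
#' @return Non-negative scalar.
#' @export
focus_score <- function(gray_tile) {
  if (nrow(gray_tile) < 3L || ncol(gray_tile) < 3L)
    stop("tile smaller than the 3x3 Laplacian kernel")
  nr <- nrow(gray_tile); nc <- ncol(gray_tile)
  c_ <- gray_tile[2:(nr - 1), 2:(nc - 1)]
  up <- gray_tile[1:(nr - 2), 2:(nc - 1)]
  dn <- gray_tile[3:nr, 2:(nc - 1)]
  lf <- gray_tile[2:(nr - 1), 1:(nc - 2)]
  rt <- gray_tile[2:(nr - 1), 3:nc]
  resp <- up + dn + lf + rt - 4 * c_
  mean((resp - mean(resp))^2)
}

#' RGB to HSI (hue, saturation, intensity) conversion
#'
#' Standard geometric HSI: `I = (R+G+B)/3`, `S = 1 - min(R,G,B)/I` (0 when
#' I = 0), and the geometric hue angle, reported in turns in `[0, 1)` (red =
#' 0, green = 1/3, blue = 2/3); hue is 0 by convention for achromatic pixels.
#'
#' @param rgb_tile h x w x 3 array with values in \[0, 255\].
#' @return List of matrices `h` (\[0,1) turns), `s` (\[0,1\]), `i`
#'   (\[0,255\]).
#' @export
rgb_to_hsi <- function(rgb_tile) {
  r <- rgb_tile[, , 1]; g <- rgb_tile[, , 2]; b <- rgb_tile[, , 3]
  i <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  s <- ifelse(i > 0, 1 - mn / i, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1))
  hue <- ifelse(b <= g, theta, 2 * pi - theta) / (2 * pi)
  hue[s == 0] <- 0
  hue[hue >= 1] <- 0
  list(h = hue, s = s, i = i)
}

.norm_hist <- function(v, n_bins, lo, hi) {
  bin <- pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  tab <- tabulate(bin, nbins = n_bins)
  tab / sum(tab)
}

#' HSI histogram features of a tile
#'
#' @param rgb_tile h x w x 3 array, values in \[0, 255\].
#' @param n_bins Bins per channel, default 32.
#' @return List of three normalized histograms (`h`, `i`, `s`), each summing
#'   to 1.
#' @export
his_features <- function(rgb_tile, n_bins = 32L) {
  hsi <- rgb_to_hsi(rgb_tile)
  list(h = .norm_hist(hsi$h, n_bins, 0, 1),
       i = .norm_hist(hsi$i, n_bins, 0, 255 + 1e-9),
       s = .norm_hist(hsi$s, n_bins, 0, 1 + 1e-9))
}

#' Otsu threshold of an 8-bit gray image
#'
#' Maximizes the between-class variance over the 256-level integer histogram.
#' The returned threshold `t` assigns pixels with `gray <= t` to the dark
#' class; ties resolve to the lowest threshold. Returns NA for constant
#' images (no bimodality).
#'
#' @param gray Numeric matrix, values in \[0, 255\].
#' @return Integer threshold in 0..254, or NA.
#' @export
otsu_threshold <- function(gray) {
  g <- pmin(pmax(round(gray), 0), 255)
  hist <- tabulate(g + 1L, nbins = 256L)
  n <- sum(hist)
  if (sum(hist > 0) < 2L) return(NA_integer_)
  levels <- 0:255
  w0 <- cumsum(hist)[1:255]
  sum0 <- cumsum(hist * levels)[1:255]
  tot <- sum(hist * levels)
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- sum0 / w0
  mu1 <- (tot - sum0) / w1
  bcv <- ifelse(valid, w0 * w1 * (mu0 - mu1)^2, -Inf)
  as.integer(which.max(bcv) - 1L)  # first max -> lowest threshold
}

#' Cellular-area ratio of a tile
#'
#' Separates cell from non-cell pixels with the Otsu threshold and returns the
#' foreground fraction. With bright-field Papanicolaou staining cells are dark
#' on a bright background, so the dark class is foreground by default
#' (`polarity = "dark"`). Constant tiles return 0 by convention.
#'
#' @param gray_tile Numeric matrix of gray values in \[0, 255\].
#' @param polarity `"dark"` (default) or `"bright"` foreground.
#' @return Ratio in \[0, 1\].
#' @export
cell_area_ratio <- function(gray_tile, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  t <- otsu_threshold(gray_tile)
  if (is.na(t)) return(0)
  fg <- if (polarity == "dark") sum(round(gray_tile) <= t) else
    sum(round(gray_tile) > t)
  fg / length(gray_tile)
}

#' Quality features of one tile
#'
#' @param rgb_tile h x w x 3 array in \[0, 255\].
#' @param n_bins Histogram bins per HSI channel.
#' @param polarity Foreground polarity for [cell_area_ratio()].
#' @return Named numeric vector: `focus`, `cell_ratio`, then `hue_*`,
#'   `intensity_*`, `saturation_*` histogram bins.
#' @export
qc_tile_features <- function(rgb_tile, n_bins = 32L, polarity = "dark") {
  gray <- to_grayscale(rgb_tile)
  his <- his_features(rgb_tile, n_bins)
  c(focus = focus_score(gray),
    cell_ratio = cell_area_ratio(gray, polarity),
    stats::setNames(his$h, paste0("hue_", seq_len(n_bins))),
    stats::setNames(his$i, paste0("intensity_", seq_len(n_bins))),
    stats::setNames(his$s, paste0("saturation_", seq_len(n_bins))))
}

#' Slide-level quality summary over tiles
#'
#' Quantiles (0.1/0.5/0.9) and means of the tile focus scores and cellular
#' ratios, plus the tile-mean of every HSI histogram bin. Log-scaled focus is
#' used (`log1p`) since focus variance spans orders of magnitude.
#'
#' @param tile_features Matrix (tiles x features) or a single named vector
#'   from [qc_tile_features()].
#' @return Named numeric slide feature vector.
#' @export
qc_slide_features <- function(tile_features) {
  if (is.null(dim(tile_features)))
    tile_features <- matrix(tile_features, nrow = 1,
                            dimnames = list(NULL, names(tile_features)))
  qs <- c(0.1, 0.5, 0.9)
  foc <- log1p(tile_features[, "focus"])
  rat <- tile_features[, "cell_ratio"]
  hist_cols <- setdiff(colnames(tile_features), c("focus", "cell_ratio"))
  c(stats::setNames(stats::quantile(foc, qs, type = 7),
                    c("focus_q10", "focus_q50", "focus_q90")),
    focus_mean = mean(foc),
    stats::setNames(stats::quantile(rat, qs, type = 7),
                    c("ratio_q10", "ratio_q50", "ratio_q90")),
    ratio_mean = mean(rat),
    colMeans(tile_features[, hist_cols, drop = FALSE]))
}

#' Train the boosted quality gate
#'
#' @param features Matrix of slide-level QC feature vectors (rows = slides).
#' @param qualified Binary labels (1 = qualified).
#' @param seed,nrounds Training controls.
#' @return Object of class `tbs_qc_gate`.
#' @export
train_qc_gate <- function(features, qualified, seed = 1L, nrounds = 60L) {
  qualified <- as.integer(qualified)
  if (length(unique(qualified)) < 2L)
    stop("quality-gate training needs both qualified and unqualified slides")
  d <- xgboost::xgb.DMatrix(features, label = qualified)
  booster <- xgboost::xgb.train(
    params = c(.default_xgb_params("binary:logistic"), list(seed = seed)),
    data = d, nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, feature_names = colnames(features)),
            class = "tbs_qc_gate")
}

#' Persist / restore a trained quality gate
#'
#' Stored as a directory: the booster in JSON format plus a YAML of feature
#' names.
#'
#' @param gate A `tbs_qc_gate`.
#' @param dir Directory path.
#' @export
save_qc_gate <- function(gate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(gate$booster, file.path(dir, "gate.json"))
  yaml::write_yaml(list(feature_names = gate$feature_names),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname save_qc_gate
#' @export
load_qc_gate <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  structure(list(booster = xgboost::xgb.load(file.path(dir, "gate.json")),
                 feature_names = unlist(meta$feature_names)),
            class = "tbs_qc_gate")
}

#' Gate a slide on image quality
#'
#' Computes per-tile quality features, summarizes them at slide level, scores
#' the summary with the trained boosted gate and thresholds the qualified
#' probability (default 0.5).
#'
#' @param tiles List of RGB tile arrays (values in \[0, 255\]), or a
#'   precomputed tile-feature matrix.
#' @param model A `tbs_qc_gate`.
#' @param slide_id Identifier carried into the result.
#' @param threshold Qualified-probability cut, default 0.5.
#' @param n_bins,polarity Passed to [qc_tile_features()].
#' @return List: `slide_id`, `tile_features`, `slide_features`,
#'   `verdict_prob`, `verdict` (`"qualified"` or `"unqualified"`).
#' @export
qc_gate <- function(tiles, model, slide_id = NA_character_, threshold = 0.5,
                    n_bins = 32L, polarity = "dark") {
  if (is.null(model$booster)) stop("untrained quality-gate model")
  tf <- if (is.list(tiles)) {
    if (length(tiles) == 0L) stop("qc_gate needs at least one tile")
    do.call(rbind, lapply(tiles, qc_tile_features, n_bins = n_bins,
                          polarity = polarity))
  } else tiles
  sf <- qc_slide_features(tf)
  sf <- sf[model$feature_names]
  p <- predict(model$booster, xgboost::xgb.DMatrix(matrix(sf, nrow = 1,
    dimnames = list(NULL, model$feature_names))))
  list(slide_id = slide_id, tile_features = tf, slide_features = sf,
       verdict_prob = as.numeric(p),
       verdict = if (p >= threshold) "qualified" else "unqualified")
}
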