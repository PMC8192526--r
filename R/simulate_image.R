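# Synthetic smear-tile image generator for the quality-control module:
# dark-stained cell blobs on a bright background, with controllable coverage,
# defocus blur, stain contrast and noise. Emulates preparation and scanning
# variation at the image-statistics level only (no photorealism).

#' Default tile simulation configuration
#'
#' Tile side defaults to 256 px: large enough for stable focus/histogram/Otsu
#' statistics, small enough that corpora of hundreds of tiles generate in
#' seconds. Stain palettes approximate the two routine Papanicolaou
#' counterstains (EA-36 bluish-purple vs EA-50 pinker cytoplasm).
#'
#' @return List of generator knobs (tile size, cellularity range, blob radius,
#'   palette, blur sigma, contrast scale, noise sd, background colour).
#' @export
default_image_sim_config <- function() {
  list(tile_size = 256L,
       cellularity = NULL,              # NULL: draw per preset
       qualified_cellularity = c(0.2, 0.6),
       low_cellularity = c(0.005, 0.04),
       blob_radius = c(mean = 6, sd = 1.5, min = 2),
       palette = "EA36",
       defocus_sigma = 3,
       poor_stain_contrast = 0.25,
       noise_sd = 4,
       background = c(236, 232, 238))
}

.palettes <- list(
  EA36 = rbind(c(110, 60, 150),   # nucleus purple
               c(150, 110, 180),  # cytoplasm mauve
               c(100, 140, 160)), # cyanophilic cytoplasm
  EA50 = rbind(c(120, 60, 140),
               c(205, 120, 160),  # eosinophilic pink
               c(170, 100, 130)))

# paint random disks onto the channel matrices until the covered fraction
# reaches `target`; returns list(r, g, b, mask)
.paint_cells <- function(size, target, cfg, palette) {
  bg <- cfg$background
  r <- matrix(bg[1], size, size); g <- matrix(bg[2], size, size)
  b <- matrix(bg[3], size, size)
  mask <- matrix(FALSE, size, size)
  if (target <= 0)
    return(list(r = r, g = g, b = b, mask = mask))
  npix <- size * size
  guard <- 0L
  while (sum(mask) / npix < target && guard < 100000L) {
    guard <- guard + 1L
    rad <- max(cfg$blob_radius["min"],
               round(stats::rnorm(1, cfg$blob_radius["mean"],
                                  cfg$blob_radius["sd"])))
    cx <- sample.int(size, 1); cy <- sample.int(size, 1)
    col <- palette[sample.int(nrow(palette), 1), ] +
      stats::rnorm(3, 0, 8)
    ii <- max(1, cx - rad):min(size, cx + rad)
    jj <- max(1, cy - rad):min(size, cy + rad)
    dd <- outer((ii - cx)^2, (jj - cy)^2, "+") <= rad^2
    idx <- cbind(rep(ii, length(jj)), rep(jj, each = length(ii)))[as.vector(dd), ,
                                                                  drop = FALSE]
    r[idx] <- col[1]; g[idx] <- col[2]; b[idx] <- col[3]
    mask[idx] <- TRUE
  }
  list(r = r, g = g, b = b, mask = mask)
}

#' Simulate one smear tile
#'
#' Presets perturb exactly one factor relative to `"qualified"` (sharp,
#' well-stained, 20-60% cellularity): `"defocus"` applies Gaussian blur,
#' `"low-cellularity"` drops coverage below 5%, `"poor-stain"` compresses
#' contrast toward the background.
#'
#' @param quality One of `"qualified"`, `"defocus"`, `"low-cellularity"`,
#'   `"poor-stain"`.
#' @param seed Integer seed; same seed, same tile.
#' @param config Config from [default_image_sim_config()]; set
#'   `config$cellularity` to plant an exact coverage fraction.
#' @return h x w x 3 numeric array with values in \[0, 255\]; the planted cell
#'   mask fraction is attached as attribute `coverage`.
#' @export
simulate_tile <- function(quality = c("qualified", "defocus",
                                      "low-cellularity", "poor-stain"),
                          seed = 1L, config = default_image_sim_config()) {
  quality <- match.arg(quality)
  .with_seed(seed, {
    size <- config$tile_size
    target <- config$cellularity
    if (is.null(target)) {
      rng <- if (quality == "low-cellularity") config$low_cellularity else
        config$qualified_cellularity
      target <- stats::runif(1, rng[1], rng[2])
    }
    pal <- .palettes[[config$palette]]
    painted <- .paint_cells(size, target, config, pal)
    img <- array(0, c(size, size, 3))
    img[, , 1] <- painted$r; img[, , 2] <- painted$g; img[, , 3] <- painted$b
    if (quality == "poor-stain") {
      bg <- config$background
      for (k in 1:3)
        img[, , k] <- bg[k] + (img[, , k] - bg[k]) * config$poor_stain_contrast
    }
    if (config$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, config$noise_sd),
                         dim(img))
    if (quality == "defocus" && config$defocus_sigma > 0)
      for (k in 1:3)
        img[, , k] <- EBImage::gblur(img[, , k], sigma = config$defocus_sigma)
    img <- pmin(pmax(img, 0), 255)
    attr(img, "coverage") <- sum(painted$mask) / (size * size)
    img
  })
}

#' Simulate a quality-control corpus of single-tile slides
#'
#' Generates `n` tiles cycling through the four quality presets (balanced
#' two-class labels: qualified vs any defect) and returns the slide-level
#' quality feature matrix ready for [train_qc_gate()]. Tiles are generated one
#' at a time and discarded after feature extraction.
#'
#' @param n Number of tiles.
#' @param seed Master seed; per-tile seeds are derived from it.
#' @param config Tile simulation config.
#' @param n_bins Histogram bins for [qc_tile_features()].
#' @return List: `features` (n x p matrix), `qualified` (0/1), `preset`
#'   (character), `seeds`.
#' @export
simulate_qc_corpus <- function(n, seed = 1L,
                               config = default_image_sim_config(),
                               n_bins = 32L) {
  presets <- rep(c("qualified", "defocus", "qualified", "low-cellularity",
                   "qualified", "poor-stain"), length.out = n)
  seeds <- derive_seeds(seed, n)
  feats <- lapply(seq_len(n), function(i) {
    tile <- simulate_tile(presets[i], seeds[i], config)
    qc_slide_features(qc_tile_features(tile, n_bins = n_bins))
  })
  list(features = do.call(rbind, feats),
       qualified = as.integer(presets == "qualified"),
       preset = presets, seeds = seeds)
}
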