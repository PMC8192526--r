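# Synthetic slide-level target-record generator: emulates, at the statistics
# level, what the detection/classification/patch/segmentation front-ends emit
# for slides of each TBS ground-truth class, so the decision engine and
# metrics are testable without any scanner data.

#' Default slide simulation configuration
#'
#' Study conditions for the synthetic corpus. Per TBS truth class, lesion
#' targets arrive with Poisson counts and Beta-distributed detection/refined
#' probabilities: high-grade and infectious lesions carry many confident
#' targets (Beta(8,2), mean 0.8), ASCUS few equivocal ones (Beta(5,3), mean
#' 0.625), and ASCH intermediate (Beta(6,3)). Every slide carries background
#' normal single cells (SC) with nucleus morphometry, and a low rate of
#' detector false positives with weak probabilities (Beta(2,6), mean 0.25).
#' Nucleus gray decreases and area increases with lesion grade
#' (hyperchromasia and nuclear enlargement). Class imbalance in
#' [default_class_mix()] mirrors clinical screening (rare AGC/EMC/HSV).
#'
#' @return A nested list; see the source for every knob.
#' @export
default_slide_sim_config <- function() {
  comp <- function(class, mean_count, shape1, shape2)
    data.frame(class = class, mean_count = mean_count,
               shape1 = shape1, shape2 = shape2, stringsAsFactors = FALSE)
  list(
    lesions = list(
      NILM  = comp(character(), numeric(), numeric(), numeric()),
      ASCUS = comp(c("ASC_L_S", "ASC_H_S"), c(3, 1.5), 5, 3),
      LSIL  = comp(c("KC", "ASC_L_F", "ASC_L_S", "PH"), c(6, 4, 2, 5), 8, 2),
      ASCH  = comp(c("ASC_H_S", "ASC_H_M"), c(5, 2), 6, 3),
      HSIL  = comp(c("ASC_H_B", "ASC_H_M", "ASC_H_S"), c(4, 4, 5), 8, 2),
      SCC   = comp(c("SCC_R", "SCC_G", "ASC_H_S"), c(5, 4, 3), 8, 2),
      AGC   = comp(c("AGC_A", "AGC_B"), c(4, 2), 8, 2),
      EMC   = comp("EMC", 5, 8, 2),
      TRI   = comp("TRI", 12, 8, 2),
      CAN   = comp("CAN", 12, 8, 2),
      HSV   = comp("HSV", 8, 8, 2),
      ACTINO = comp("ACTINO", 8, 8, 2),
      CC    = comp("CC", 12, 8, 2)),
    background_sc = list(mean_count = 15, shape1 = 6, shape2 = 2),
    fp = list(rate = 1.5, shape1 = 2, shape2 = 6,
              patch_shape1 = 7, patch_shape2 = 3),
    patch_true = c(8, 2),
    nucleus = list(
      SC      = c(gray_mean = 120, gray_sd = 12, area_mean = 480, area_sd = 80),
      ASC_L_S = c(gray_mean = 100, gray_sd = 12, area_mean = 900, area_sd = 150),
      ASC_H_S = c(gray_mean = 75, gray_sd = 12, area_mean = 1400,
                  area_sd = 220)),
    slide_dims = c(50000L, 50000L),
    box_size = c(mean = 200, sd = 40, min = 40, max = 600))
}

#' Default TBS class mix of the synthetic corpus
#'
#' @return Named numeric vector of per-truth-class proportions, summing to 1.
#' @export
default_class_mix <- function() {
  c(NILM = 0.44, ASCUS = 0.08, LSIL = 0.10, ASCH = 0.06, HSIL = 0.10,
    SCC = 0.05, AGC = 0.03, EMC = 0.02, TRI = 0.04, CAN = 0.03, HSV = 0.01,
    ACTINO = 0.015, CC = 0.025)
}

.lsil_family <- c("ASC_L_S", "KC", "ASC_L_F")
.hsil_family <- c("ASC_H_B", "ASC_H_M", "ASC_H_S", "SCC_R", "SCC_G")

.sim_boxes <- function(n, cfg) {
  bs <- cfg$box_size
  w <- pmin(pmax(round(stats::rnorm(n, bs["mean"], bs["sd"])), bs["min"]),
            bs["max"])
  h <- pmin(pmax(round(stats::rnorm(n, bs["mean"], bs["sd"])), bs["min"]),
            bs["max"])
  data.frame(
    x = as.integer(floor(stats::runif(n, 0, cfg$slide_dims[1] - bs["max"]))),
    y = as.integer(floor(stats::runif(n, 0, cfg$slide_dims[2] - bs["max"]))),
    width = as.integer(w), height = as.integer(h))
}

.sim_nucleus <- function(codes, cfg) {
  out <- data.frame(mean_gray = rep(NA_real_, length(codes)),
                    area_px = NA_real_, n_components = NA_integer_)
  for (code in names(cfg$nucleus)) {
    sel <- codes == code
    if (!any(sel)) next
    p <- cfg$nucleus[[code]]
    out$mean_gray[sel] <- pmin(pmax(
      stats::rnorm(sum(sel), p["gray_mean"], p["gray_sd"]), 0), 255)
    out$area_px[sel] <- pmax(round(
      stats::rnorm(sum(sel), p["area_mean"], p["area_sd"])), 50)
    out$n_components[sel] <- 1L
  }
  out
}

.sim_patch <- function(codes, true_target, cfg) {
  lab <- rep(NA_character_, length(codes))
  prob <- rep(NA_real_, length(codes))
  fam_l <- codes %in% .lsil_family
  fam_h <- codes %in% .hsil_family
  if (true_target) {
    lab[fam_l] <- "True_LSIL"; lab[fam_h] <- "True_HSIL"
    sh <- cfg$patch_true
  } else {
    lab[fam_l] <- "False_LSIL"; lab[fam_h] <- "False_HSIL"
    sh <- c(cfg$fp$patch_shape1, cfg$fp$patch_shape2)
  }
  sel <- fam_l | fam_h
  prob[sel] <- stats::rbeta(sum(sel), sh[1], sh[2])
  list(label = lab, prob = prob)
}

.sim_record_block <- function(slide_id, codes, shape1, shape2, true_target,
                              cfg, taxonomy) {
  n <- length(codes)
  if (n == 0L) return(empty_records())
  idx <- annotation_index_of(codes, taxonomy)
  det <- taxonomy$detection_class[match(idx, taxonomy$index)]
  box <- .sim_boxes(n, cfg)
  patch <- .sim_patch(codes, true_target, cfg)
  target_records(
    slide_id = slide_id, box = box, det_class = det,
    det_prob = stats::rbeta(n, shape1, shape2),
    refined_class = idx,
    refined_prob = stats::rbeta(n, shape1, shape2),
    patch_label = patch$label, patch_prob = patch$prob,
    nucleus = .sim_nucleus(codes, cfg))
}

#' Simulate the target-record stream of one slide
#'
#' Given the slide's ground-truth TBS class, draws lesion targets per the
#' configured composition, background normal single cells, and detector false
#' positives, all with the configured probability distributions. Same seed,
#' same records.
#'
#' @param tbs_truth Ground-truth TBS class (one of the names of
#'   [default_class_mix()]).
#' @param seed Integer seed.
#' @param slide_id Slide identifier.
#' @param config Configuration from [default_slide_sim_config()].
#' @param taxonomy Taxonomy table.
#' @return A validated target-record data.frame.
#' @export
simulate_slide <- function(tbs_truth, seed, slide_id = "slide",
                           config = default_slide_sim_config(),
                           taxonomy = load_taxonomy()) {
  if (!tbs_truth %in% names(config$lesions))
    stop("unknown truth class: ", tbs_truth)
  .with_seed(seed, {
    blocks <- list()
    les <- config$lesions[[tbs_truth]]
    if (nrow(les)) {
      counts <- stats::rpois(nrow(les), les$mean_count)
      codes <- rep(les$class, counts)
      sh1 <- rep(les$shape1, counts); sh2 <- rep(les$shape2, counts)
      if (length(codes))
        blocks$lesion <- .sim_record_block(slide_id, codes, sh1, sh2,
                                           TRUE, config, taxonomy)
    }
    nsc <- stats::rpois(1, config$background_sc$mean_count)
    if (nsc > 0)
      blocks$sc <- .sim_record_block(slide_id, rep("SC", nsc),
                                     config$background_sc$shape1,
                                     config$background_sc$shape2,
                                     TRUE, config, taxonomy)
    nfp <- stats::rpois(1, config$fp$rate)
    if (nfp > 0) {
      lesion_codes <- config$fp$classes
      if (is.null(lesion_codes))
        lesion_codes <- taxonomy$code[taxonomy$category %in%
                                        c("squamous-intraepithelial",
                                          "glandular-intraepithelial",
                                          "infectious", "EMC")]
      fp_codes <- sample(lesion_codes, nfp, replace = TRUE)
      blocks$fp <- .sim_record_block(slide_id, fp_codes, config$fp$shape1,
                                     config$fp$shape2, FALSE, config,
                                     taxonomy)
    }
    rec <- if (length(blocks)) do.call(rbind, blocks) else empty_records()
    rownames(rec) <- NULL
    validate_records(rec)
  })
}

# largest-remainder apportionment of n slides to the mix proportions
.apportion <- function(n, mix) {
  quota <- n * mix
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(-(quota - base), seq_along(mix))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Generate a labelled synthetic slide corpus
#'
#' Draws a stratified corpus: class counts follow `class_mix` by
#' largest-remainder rounding; each slide gets a child seed derived from
#' `seed`, recorded in the manifest so any slide (or the whole corpus) can be
#' regenerated byte-identically.
#'
#' @param n_slides Number of slides.
#' @param class_mix Named proportions summing to 1
#'   (default [default_class_mix()]).
#' @param seed Integer master seed.
#' @param config Slide simulation config.
#' @return List with `records` (named list of per-slide record data.frames)
#'   and `manifest` (data.frame `slide_id`, `truth`, `seed`).
#' @export
make_corpus <- function(n_slides, class_mix = default_class_mix(), seed = 42L,
                        config = default_slide_sim_config()) {
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% names(config$lesions)))
    stop("class_mix names unknown to the simulator config")
  counts <- .apportion(n_slides, class_mix)
  truth <- rep(names(counts), counts)
  seeds <- derive_seeds(seed, n_slides)
  ids <- sprintf("S%05d", seq_len(n_slides))
  manifest <- data.frame(slide_id = ids, truth = truth, seed = seeds,
                         stringsAsFactors = FALSE)
  records <- lapply(seq_len(n_slides), function(i)
    simulate_slide(truth[i], seeds[i], ids[i], config))
  names(records) <- ids
  list(records = records, manifest = manifest)
}

#' Regenerate a corpus from its manifest
#'
#' @param manifest Manifest data.frame from [make_corpus()].
#' @param config Slide simulation config (must match the original).
#' @return Corpus list as from [make_corpus()].
#' @export
corpus_from_manifest <- function(manifest,
                                 config = default_slide_sim_config()) {
  records <- lapply(seq_len(nrow(manifest)), function(i)
    simulate_slide(manifest$truth[i], manifest$seed[i],
                   manifest$slide_id[i], config))
  names(records) <- manifest$slide_id
  list(records = records, manifest = manifest)
}

#' Write a corpus to a directory (JSON-lines records + YAML manifest)
#'
#' @param corpus Corpus from [make_corpus()].
#' @param dir Output directory.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(slides = lapply(seq_len(nrow(corpus$manifest)),
                                        function(i)
                                          as.list(corpus$manifest[i, ]))),
                   file.path(dir, "manifest.yaml"))
  for (id in names(corpus$records))
    write_records_jsonl(corpus$records[[id]],
                        file.path(dir, paste0(id, ".jsonl")))
  invisible(dir)
}
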