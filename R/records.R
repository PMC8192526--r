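# Per-target evidence records: the fused output of the detection,
# fine-classification, patch and nucleus-segmentation front-ends for one
# detected target. Any backend (a deployed deep model or the built-in
# simulator) must produce records satisfying these invariants.

.record_cols <- c("slide_id", "x", "y", "width", "height",
                  "det_class", "det_prob", "refined_class", "refined_prob",
                  "patch_label", "patch_prob",
                  "nucleus_mean_gray", "nucleus_area_px",
                  "nucleus_n_components")

.patch_labels <- c("True_HSIL", "False_HSIL", "True_LSIL", "False_LSIL")

# refined classes carrying squamous-lesion evidence (patch model scope)
.squamous_refined <- 3:10
# refined classes routed to nucleus segmentation
.nucleus_refined <- c(3L, 8L, 12L)  # ASC_L_S, ASC_H_S, SC

#' Assemble a target-record table
#'
#' @param slide_id Character slide identifier (recycled).
#' @param box data.frame of bounding boxes (`x,y,width,height`).
#' @param det_class Detection-class code per target.
#' @param det_prob,refined_prob Probabilities in \[0,1\].
#' @param refined_class Annotation class index 1..24 from the fine classifier.
#' @param patch_label,patch_prob Optional patch-model output (squamous targets
#'   only); NA elsewhere.
#' @param nucleus Optional data.frame with `mean_gray`, `area_px`,
#'   `n_components` (NA rows for targets without segmentation).
#' @return A validated target-record `data.frame`.
#' @export
target_records <- function(slide_id, box, det_class, det_prob,
                           refined_class, refined_prob,
                           patch_label = NA_character_, patch_prob = NA_real_,
                           nucleus = NULL) {
  n <- nrow(box)
  rec <- data.frame(
    slide_id = rep_len(as.character(slide_id), n),
    x = box$x, y = box$y, width = box$width, height = box$height,
    det_class = rep_len(as.character(det_class), n),
    det_prob = rep_len(as.numeric(det_prob), n),
    refined_class = rep_len(as.integer(refined_class), n),
    refined_prob = rep_len(as.numeric(refined_prob), n),
    patch_label = rep_len(as.character(patch_label), n),
    patch_prob = rep_len(as.numeric(patch_prob), n),
    stringsAsFactors = FALSE)
  if (is.null(nucleus)) {
    rec$nucleus_mean_gray <- NA_real_
    rec$nucleus_area_px <- NA_real_
    rec$nucleus_n_components <- NA_integer_
  } else {
    rec$nucleus_mean_gray <- as.numeric(nucleus$mean_gray)
    rec$nucleus_area_px <- as.numeric(nucleus$area_px)
    rec$nucleus_n_components <- as.integer(nucleus$n_components)
  }
  validate_records(rec)
}

#' Validate a target-record table
#'
#' Checks the record invariants: probabilities in \[0,1\], positive box
#' extents, refined class in 1..24, patch fields only on squamous-lesion
#' refined classes, nucleus fields only on classes routed to segmentation
#' (ASC_L_S, ASC_H_S, SC).
#'
#' @param rec A target-record data.frame.
#' @return `rec`, invisibly gaining nothing; errors on violation.
#' @export
validate_records <- function(rec) {
  miss <- setdiff(.record_cols, names(rec))
  if (length(miss))
    stop("target records missing columns: ", paste(miss, collapse = ", "))
  if (nrow(rec) == 0L) return(rec)
  probs <- c(rec$det_prob, rec$refined_prob,
             rec$patch_prob[!is.na(rec$patch_prob)])
  if (any(!is.na(probs) & (probs < 0 | probs > 1)))
    stop("record probabilities must lie in [0, 1]")
  if (any(rec$width <= 0 | rec$height <= 0))
    stop("record boxes must have positive extents")
  if (any(rec$refined_class < 1L | rec$refined_class > 24L))
    stop("refined_class must be in 1..24")
  haspatch <- !is.na(rec$patch_label)
  if (any(haspatch & !(rec$patch_label %in% .patch_labels)))
    stop("unknown patch label")
  if (any(haspatch & !(rec$refined_class %in% .squamous_refined)))
    stop("patch fields are only defined for squamous-lesion refined classes")
  hasnuc <- !is.na(rec$nucleus_mean_gray)
  if (any(hasnuc & !(rec$refined_class %in% .nucleus_refined)))
    stop("nucleus fields are only defined for ASC_L_S, ASC_H_S and SC")
  if (any(hasnuc & (rec$nucleus_mean_gray < 0 | rec$nucleus_mean_gray > 255)))
    stop("nucleus_mean_gray must lie in [0, 255]")
  rec
}

#' Empty target-record table
#'
#' @return A zero-row data.frame with the full record schema.
#' @export
empty_records <- function() {
  rec <- data.frame(slide_id = character(), x = integer(), y = integer(),
                    width = integer(), height = integer(),
                    det_class = character(), det_prob = numeric(),
                    refined_class = integer(), refined_prob = numeric(),
                    patch_label = character(), patch_prob = numeric(),
                    nucleus_mean_gray = numeric(), nucleus_area_px = numeric(),
                    nucleus_n_components = integer(),
                    stringsAsFactors = FALSE)
  rec
}

#' Write / read target records as JSON-lines
#'
#' One JSON object per line with the record-schema keys; NA fields are
#' omitted on write and restored as NA on read. Round-trips exactly.
#'
#' @param rec Target-record data.frame.
#' @param path File path.
#' @return `read_records_jsonl` returns the validated record data.frame.
#' @export
write_records_jsonl <- function(rec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(rec) > 0L) {
    for (i in seq_len(nrow(rec))) {
      row <- as.list(rec[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v[1]), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  na = "null"),
                 con, sep = "\n")
    }
  }
  invisible(path)
}

#' @rdname write_records_jsonl
#' @export
read_records_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- empty_records()
  if (length(lines)) {
    rows <- lapply(lines, function(l) {
      v <- jsonlite::fromJSON(l)
      base <- list(slide_id = NA_character_, x = NA_integer_, y = NA_integer_,
                   width = NA_integer_, height = NA_integer_,
                   det_class = NA_character_, det_prob = NA_real_,
                   refined_class = NA_integer_, refined_prob = NA_real_,
                   patch_label = NA_character_, patch_prob = NA_real_,
                   nucleus_mean_gray = NA_real_, nucleus_area_px = NA_real_,
                   nucleus_n_components = NA_integer_)
      base[names(v)] <- v
      as.data.frame(base, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$x <- as.integer(out$x); out$y <- as.integer(out$y)
    out$width <- as.integer(out$width); out$height <- as.integer(out$height)
    out$refined_class <- as.integer(out$refined_class)
    out$nucleus_n_components <- as.integer(out$nucleus_n_components)
  }
  validate_records(out)
}

#' Export target records as CSV
#'
#' @inheritParams write_records_jsonl
#' @export
write_records_csv <- function(rec, path) {
  utils::write.csv(rec, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Deduplicate overlapping detections by IoU
#'
#' Upstream detectors can emit overlapping boxes for one target. Records are
#' sorted by detection probability (descending) and a record is dropped when
#' it overlaps an already-kept record of the same detection class with IoU at
#' or above `iou_threshold`.
#'
#' @param rec Target-record data.frame (one slide or many; deduplication is
#'   per slide).
#' @param iou_threshold IoU at or above which the lower-probability record is
#'   suppressed; `NULL` (default) disables deduplication.
#' @return Filtered record data.frame.
#' @export
dedup_records <- function(rec, iou_threshold = NULL) {
  if (is.null(iou_threshold) || nrow(rec) < 2L) return(rec)
  keep_all <- logical(nrow(rec))
  for (sl in unique(rec$slide_id)) {
    idx <- which(rec$slide_id == sl)
    ord <- idx[order(-rec$det_prob[idx], rec$x[idx], rec$y[idx])]
    kept <- integer(0)
    for (i in ord) {
      dup <- FALSE
      for (j in kept) {
        if (rec$det_class[i] == rec$det_class[j] &&
            box_iou(rec[i, ], rec[j, ]) >= iou_threshold) {
          dup <- TRUE; break
        }
      }
      if (!dup) kept <- c(kept, i)
    }
    keep_all[kept] <- TRUE
  }
  rec[sort(which(keep_all)), , drop = FALSE]
}
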