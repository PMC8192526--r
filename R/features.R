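# Slide-level feature fusion: aggregate a slide's target-record stream into a
# fixed-length named feature vector for the decision engine.

#' Default slide feature schema
#'
#' Builds the shipped 121-feature schema spanning every evidence source:
#'
#' * per detection class (12): target count, max and mean detection
#'   probability (36 features);
#' * per refined annotation class retained by the detector (18): counts of
#'   targets with refined probability >= 0.5 and >= 0.9, and max refined
#'   probability (54);
#' * per squamous-lesion refined class (C3-C10, 8): mean of the top-5 refined
#'   probabilities (8);
#' * per patch label (True/False HSIL/LSIL, 4): mean patch probability (4);
#' * nucleus morphometry for SC, ASC_L_S, ASC_H_S: 0.1/0.5/0.9 quantiles of
#'   mean nucleus gray and of nucleus area (18);
#' * total retained-target count (1).
#'
#' @param taxonomy Taxonomy table from [load_taxonomy()].
#' @return A schema data.frame with columns `name, source, statistic, scope,
#'   threshold, k, q`; 121 rows by default.
#' @export
default_feature_schema <- function(taxonomy = load_taxonomy()) {
  rowdf <- function(name, source, statistic, scope,
                    threshold = NA_real_, k = NA_integer_, q = NA_real_)
    data.frame(name = name, source = source, statistic = statistic,
               scope = scope, threshold = threshold, k = k, q = q,
               stringsAsFactors = FALSE)
  rows <- list()
  for (dc in detection_classes(taxonomy)) {
    rows[[length(rows) + 1L]] <- rowdf(paste0("det_", dc, "_count"),
                                       "detection", "count", dc)
    rows[[length(rows) + 1L]] <- rowdf(paste0("det_", dc, "_max_prob"),
                                       "detection", "max-prob", dc)
    rows[[length(rows) + 1L]] <- rowdf(paste0("det_", dc, "_mean_prob"),
                                       "detection", "mean-prob", dc)
  }
  included <- taxonomy[taxonomy$detection_class != "excluded", ]
  for (code in included$code) {
    rows[[length(rows) + 1L]] <- rowdf(paste0("ref_", code, "_n_ge50"),
                                       "refined", "count-above-threshold",
                                       code, threshold = 0.5)
    rows[[length(rows) + 1L]] <- rowdf(paste0("ref_", code, "_n_ge90"),
                                       "refined", "count-above-threshold",
                                       code, threshold = 0.9)
    rows[[length(rows) + 1L]] <- rowdf(paste0("ref_", code, "_max_prob"),
                                       "refined", "max-prob", code)
  }
  squam <- taxonomy$code[taxonomy$index %in% 3:10]
  for (code in squam)
    rows[[length(rows) + 1L]] <- rowdf(paste0("ref_", code, "_top5_mean"),
                                       "refined", "top-k-mean-prob", code,
                                       k = 5L)
  for (lab in c("True_HSIL", "False_HSIL", "True_LSIL", "False_LSIL"))
    rows[[length(rows) + 1L]] <- rowdf(paste0("patch_", lab, "_mean_prob"),
                                       "patch", "mean-prob", lab)
  for (code in c("SC", "ASC_L_S", "ASC_H_S")) {
    for (qq in c(0.1, 0.5, 0.9)) {
      rows[[length(rows) + 1L]] <- rowdf(
        sprintf("nuc_%s_gray_q%02d", code, round(qq * 100)),
        "nucleus", "nucleus-gray-quantile", code, q = qq)
      rows[[length(rows) + 1L]] <- rowdf(
        sprintf("nuc_%s_area_q%02d", code, round(qq * 100)),
        "nucleus", "nucleus-area-quantile", code, q = qq)
    }
  }
  rows[[length(rows) + 1L]] <- rowdf("total_targets", "detection", "count",
                                     "*")
  schema <- do.call(rbind, rows)
  validate_feature_schema(schema)
}

#' Validate a feature schema
#' @param schema Schema data.frame.
#' @return The schema; errors on duplicated names or unknown statistics.
#' @export
validate_feature_schema <- function(schema) {
  stats_ok <- c("count", "count-above-threshold", "max-prob", "mean-prob",
                "top-k-mean-prob", "quantile", "nucleus-gray-quantile",
                "nucleus-area-quantile")
  if (anyDuplicated(schema$name)) stop("feature names must be unique")
  if (!all(schema$statistic %in% stats_ok))
    stop("unknown feature statistic: ",
         paste(setdiff(schema$statistic, stats_ok), collapse = ", "))
  if (!all(schema$source %in% c("detection", "refined", "patch", "nucleus")))
    stop("unknown feature source")
  schema
}

#' Read / write a feature schema as YAML
#' @param schema Schema data.frame.
#' @param path YAML file path.
#' @export
write_feature_schema <- function(schema, path) {
  feats <- lapply(seq_len(nrow(schema)), function(i) {
    f <- as.list(schema[i, ])
    f[!vapply(f, function(v) is.na(v[1]), logical(1))]
  })
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}

#' @rdname write_feature_schema
#' @export
read_feature_schema <- function(path) {
  feats <- yaml::read_yaml(path)$features
  rows <- lapply(feats, function(f) {
    data.frame(name = f$name, source = f$source, statistic = f$statistic,
               scope = f$scope,
               threshold = if (is.null(f$threshold)) NA_real_ else f$threshold,
               k = if (is.null(f$k)) NA_integer_ else as.integer(f$k),
               q = if (is.null(f$q)) NA_real_ else f$q,
               stringsAsFactors = FALSE)
  })
  validate_feature_schema(do.call(rbind, rows))
}

#' Aggregate a slide's target records into its feature vector
#'
#' Deterministic and order-invariant: records are sorted internally by
#' probability then coordinates. Empty-set statistics (e.g. max probability of
#' a class with no targets) are reported as 0 with the missing flag set, so
#' that missingness stays representable for the boosted model (which routes
#' missing values down a default branch). Records whose detection class is not
#' part of the taxonomy's retained set are dropped with a warning.
#'
#' @param records Target-record data.frame, all rows from one slide.
#' @param schema Feature schema (default [default_feature_schema()]).
#' @param taxonomy Taxonomy table.
#' @return List with `slide_id`, numeric `values` (named, length =
#'   `nrow(schema)`), and logical `missing` flags.
#' @export
aggregate_slide <- function(records, schema = default_feature_schema(),
                            taxonomy = load_taxonomy()) {
  slide_id <- if (nrow(records)) records$slide_id[1] else NA_character_
  if (nrow(records) && length(unique(records$slide_id)) > 1L)
    stop("aggregate_slide expects records from a single slide")
  known <- detection_classes(taxonomy)
  if (nrow(records)) {
    bad <- !(records$det_class %in% known)
    if (any(bad)) {
      warning(sum(bad), " record(s) with detection class outside the schema",
              " scope ignored: ",
              paste(unique(records$det_class[bad]), collapse = ", "))
      records <- records[!bad, , drop = FALSE]
    }
    records <- records[order(-records$det_prob, records$x, records$y), ,
                       drop = FALSE]
  }
  code_of <- taxonomy$code[match(records$refined_class, taxonomy$index)]
  n <- nrow(schema)
  values <- numeric(n); missing <- logical(n)
  for (i in seq_len(n)) {
    st <- schema$statistic[i]; src <- schema$source[i]; sc <- schema$scope[i]
    if (src == "detection") {
      sel <- if (sc == "*") rep(TRUE, nrow(records)) else
        records$det_class == sc
      p <- records$det_prob[sel]
    } else if (src == "refined") {
      sel <- code_of == sc
      p <- records$refined_prob[sel]
    } else if (src == "patch") {
      sel <- !is.na(records$patch_label) & records$patch_label == sc
      p <- records$patch_prob[sel]
    } else { # nucleus
      sel <- code_of == sc & !is.na(records$nucleus_mean_gray)
      p <- if (st == "nucleus-gray-quantile") records$nucleus_mean_gray[sel]
      else records$nucleus_area_px[sel]
    }
    if (st == "count") {
      values[i] <- sum(sel)
    } else if (st == "count-above-threshold") {
      values[i] <- sum(p >= schema$threshold[i])
    } else if (length(p) == 0L) {
      values[i] <- 0; missing[i] <- TRUE
    } else if (st == "max-prob") {
      values[i] <- max(p)
    } else if (st == "mean-prob") {
      values[i] <- mean(p)
    } else if (st == "top-k-mean-prob") {
      k <- min(schema$k[i], length(p))
      values[i] <- mean(sort(p, decreasing = TRUE)[seq_len(k)])
    } else { # quantile statistics
      values[i] <- unname(stats::quantile(p, schema$q[i], type = 7))
    }
  }
  names(values) <- schema$name
  names(missing) <- schema$name
  list(slide_id = slide_id, values = values, missing = missing)
}

#' Stack slide feature vectors into a feature matrix
#'
#' @param fvs List of feature vectors from [aggregate_slide()].
#' @param missing_as_na Replace flagged missing values with `NA` (the boosted
#'   model's native missing representation). Default TRUE.
#' @return Numeric matrix, one row per slide, rownames = slide ids.
#' @export
feature_matrix <- function(fvs, missing_as_na = TRUE) {
  m <- do.call(rbind, lapply(fvs, function(f) {
    v <- f$values
    if (missing_as_na) v[f$missing] <- NA_real_
    v
  }))
  rownames(m) <- vapply(fvs, function(f) f$slide_id, character(1))
  m
}

#' Write a feature matrix as CSV (header = feature names, one row per slide)
#' @param m Feature matrix.
#' @param path CSV path.
#' @export
write_feature_csv <- function(m, path) {
  df <- data.frame(slide_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Normalized feature importance from split counts
#'
#' Boosted-tree feature importance as used here: count the number of splits on
#' each feature across all trees, then normalize to sum 1. With no splits at
#' all the importances are all zero.
#'
#' @param split_counts Non-negative integer vector (optionally named).
#' @return data.frame with `feature`, `splits`, `importance`; importance sums
#'   to 1 when any split exists, row order = decreasing splits.
#' @export
#' @examples
#' importance_from_splits(c(a = 3, b = 1, c = 0))
importance_from_splits <- function(split_counts) {
  if (any(split_counts < 0) || any(split_counts != round(split_counts)))
    stop("split counts must be non-negative integers")
  tot <- sum(split_counts)
  imp <- if (tot == 0) rep(0, length(split_counts)) else split_counts / tot
  nm <- names(split_counts)
  if (is.null(nm)) nm <- paste0("f", seq_along(split_counts))
  out <- data.frame(feature = nm, splits = as.integer(split_counts),
                    importance = unname(imp), stringsAsFactors = FALSE)
  out[order(-out$splits), , drop = FALSE]
}

#' Split counts of a trained booster
#'
#' @param booster An `xgb.Booster`.
#' @param feature_names Full feature-name vector (features never split on get
#'   count 0).
#' @return Named integer vector of per-feature split counts.
#' @export
booster_split_counts <- function(booster, feature_names) {
  tr <- xgboost::xgb.model.dt.tree(model = booster)
  used <- tr$Feature[tr$Feature != "Leaf"]
  counts <- table(factor(used, levels = feature_names))
  stats::setNames(as.integer(counts), feature_names)
}
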