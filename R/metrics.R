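# Screening performance metrics under clinical-group equivalence rules, and
# biopsy-cohort sensitivity arithmetic.

#' Biopsy-cohort sensitivity
#'
#' Sensitivity against histological ground truth: of `n_positive`
#' biopsy-confirmed positive samples, the screen missed `n_missed`, so
#' sensitivity is `(n_positive - n_missed) / n_positive`.
#'
#' @param n_biopsies Total biopsied samples.
#' @param n_positive Biopsy-positive samples (> 0).
#' @param n_missed Positives the screen called negative.
#' @return Sensitivity in \[0, 1\].
#' @export
#' @examples
#' biopsy_sensitivity(180, 145, 8)  # 0.944827586...
biopsy_sensitivity <- function(n_biopsies, n_positive, n_missed) {
  if (any(n_positive <= 0))
    stop("sensitivity undefined: no biopsy-positive samples")
  if (any(n_missed < 0) || any(n_missed > n_positive) ||
      any(n_positive > n_biopsies))
    stop("need 0 <= n_missed <= n_positive <= n_biopsies")
  (n_positive - n_missed) / n_positive
}

.intraepithelial_groups <- c("squamous-intraepithelial",
                             "glandular-intraepithelial")

#' Build a slide-level evaluation table
#'
#' @param truth,pred Character vectors of true and predicted TBS classes
#'   (case-insensitive; the rare glandular diagnoses are merged into AGC).
#' @return data.frame with truth/pred codes and clinical groups.
#' @export
evaluation_table <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  truth <- merge_agc(truth); pred <- merge_agc(pred)
  data.frame(truth = truth, pred = pred,
             truth_group = clinical_group_of(truth),
             pred_group = clinical_group_of(pred),
             stringsAsFactors = FALSE)
}

# correctness under the clinical equivalence rule: confusions within a group
# are not errors, and squamous vs glandular confusion still counts as a
# detected intraepithelial lesion
.group_correct <- function(tg, pg) {
  ifelse(tg %in% .intraepithelial_groups, pg %in% .intraepithelial_groups,
         tg == pg)
}

#' Screening metrics at the clinical-group level
#'
#' Computes the sensitivities and specificity used to summarise screening
#' performance: intraepithelial-lesion sensitivity pools squamous and
#' glandular truths (predicting either intraepithelial group counts as
#' correct); "other lesions" pools infectious and EMC truths (correct when the
#' predicted group matches); specificity is the fraction of truth-negative
#' slides predicted negative. Because ASCUS dominates borderline calls, the
#' intraepithelial sensitivity is also reported with ASCUS truths excluded.
#'
#' @param table Evaluation table from [evaluation_table()].
#' @return Named list: `sensitivity_intraepithelial`,
#'   `sensitivity_intraepithelial_excl_ascus`, `sensitivity_other`,
#'   `specificity`, `n_*` denominators.
#' @export
group_metrics <- function(table) {
  stopifnot(nrow(table) > 0)
  intra <- table$truth_group %in% .intraepithelial_groups
  other <- table$truth_group %in% c("infectious", "EMC")
  neg <- table$truth_group == "negative"
  if (!any(neg)) stop("specificity undefined: no truth-negative slides")
  ok <- .group_correct(table$truth_group, table$pred_group)
  intra_na <- intra & table$truth != "ASCUS"
  list(
    sensitivity_intraepithelial =
      if (any(intra)) mean(ok[intra]) else NA_real_,
    sensitivity_intraepithelial_excl_ascus =
      if (any(intra_na)) mean(ok[intra_na]) else NA_real_,
    sensitivity_other = if (any(other)) mean(ok[other]) else NA_real_,
    specificity = mean(table$pred_group[neg] == "negative"),
    n_intraepithelial = sum(intra), n_other = sum(other),
    n_negative = sum(neg))
}

#' Exact-subtype accuracy among squamous true positives
#'
#' Fraction of truth-squamous slides, among those the system called squamous,
#' whose predicted TBS subtype matches the truth exactly.
#'
#' @param table Evaluation table.
#' @return Proportion in \[0, 1\].
#' @export
subtype_accuracy <- function(table) {
  tp <- table$truth_group == "squamous-intraepithelial" &
    table$pred_group == "squamous-intraepithelial"
  if (!any(tp))
    stop("subtype accuracy undefined: no squamous true positives")
  mean(table$truth[tp] == table$pred[tp])
}

#' Detection-level sensitivity and specificity
#'
#' The binary screening summary: sensitivity is the fraction of truth-positive
#' (non-NILM) slides reported as any lesion; specificity the fraction of
#' truth-NILM slides reported NILM.
#'
#' @param table Evaluation table.
#' @return List with `sensitivity`, `specificity`, `n_positive`, `n_negative`.
#' @export
detection_metrics <- function(table) {
  pos <- table$truth != "NILM"
  list(sensitivity = if (any(pos)) mean(table$pred[pos] != "NILM") else
    NA_real_,
    specificity = if (any(!pos)) mean(table$pred[!pos] == "NILM") else
      NA_real_,
    n_positive = sum(pos), n_negative = sum(!pos))
}

#' Evaluate a trained engine on a labelled corpus
#'
#' Runs [predict_tbs()] on the corpus records and assembles the evaluation
#' table and all metric summaries.
#'
#' @param engine A `tbs_engine`.
#' @param corpus Corpus from [make_corpus()].
#' @return List: `table`, `reports`, `group` ([group_metrics()]), `detection`
#'   ([detection_metrics()]), and `subtype_accuracy` (NA when undefined).
#' @export
evaluate_engine <- function(engine, corpus) {
  reports <- predict_tbs(engine, corpus$records)
  pred <- vapply(reports, function(r) r$final_tbs, character(1))
  tab <- evaluation_table(corpus$manifest$truth, pred)
  sub <- tryCatch(subtype_accuracy(tab), error = function(e) NA_real_)
  list(table = tab, reports = reports, group = group_metrics(tab),
       detection = detection_metrics(tab), subtype_accuracy = sub)
}
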