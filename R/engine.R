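# Slide-level decision engine: stage 1 calls a slide positive or negative for
# squamous intraepithelial lesions with a k-fold boosted ensemble under an
# any-positive rule; stage 2 assigns the squamous subtype; a logical decision
# tree handles infectious, merged-AGC and endometrial findings; the final
# report keeps a single lesion by clinical priority.

.squamous_subtypes <- c("ASCUS", "LSIL", "ASCH", "HSIL", "SCC")  # severity asc

# clinical-treatment priority, most urgent first
.priority_order <- c("SCC", "HSIL", "ASCH", "AGC", "LSIL", "ASCUS",
                     "EMC", "HSV", "TRI", "ACTINO", "CAN", "CC", "NILM")

.default_xgb_params <- function(objective, num_class = NULL) {
  p <- list(objective = objective, max_depth = 3, eta = 0.2,
            min_child_weight = 1, subsample = 1, nthread = 1)
  if (!is.null(num_class)) p$num_class <- num_class
  p
}

# stratified fold assignment, reproducible from seed
.stratified_folds <- function(y, k, seed) {
  .with_seed(seed, {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  })
}

#' Train the stage-1 positive/negative squamous ensemble
#'
#' Trains `k` gradient-boosted members, one per stratified cross-validation
#' fold (each trained on the other k-1 folds, early-stopped on its held-out
#' fold). At prediction time a slide is called positive when one or more
#' members call it positive (the any-positive union rule), which trades
#' specificity for screening sensitivity.
#'
#' @param features Numeric feature matrix (slides x features, NA = missing).
#' @param labels Binary vector (1 = positive squamous lesion).
#' @param k Number of folds/members, default 10.
#' @param seed Integer seed; fold assignment and training are reproducible.
#' @param nrounds Maximum boosting rounds per member.
#' @param params xgboost parameter list.
#' @return An object of class `tbs_stage1`: members, per-member thresholds
#'   (default 0.5), fold assignments, seed.
#' @export
train_stage1 <- function(features, labels, k = 10L, seed = 1L, nrounds = 60L,
                         params = .default_xgb_params("binary:logistic")) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("stage-1 training needs both positive and negative slides")
  if (min(table(labels)) < k)
    stop("each class must appear at least k times for stratified folding")
  folds <- .stratified_folds(labels, k, seed)
  members <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- if (k == 1L) rep(TRUE, length(labels)) else folds != f
    dtr <- xgboost::xgb.DMatrix(features[tr, , drop = FALSE],
                                label = labels[tr])
    dva <- xgboost::xgb.DMatrix(features[!tr, , drop = FALSE],
                                label = labels[!tr])
    members[[f]] <- xgboost::xgb.train(
      params = c(params, list(seed = seed + f)),
      data = dtr, nrounds = nrounds,
      evals = list(val = dva), early_stopping_rounds = 10L, verbose = 0)
  }
  structure(list(members = members, thresholds = rep(0.5, k),
                 folds = folds, seed = seed,
                 feature_names = colnames(features)),
            class = "tbs_stage1")
}

#' Per-member positive-class scores
#'
#' @param stage1 A `tbs_stage1` ensemble.
#' @param features Feature matrix.
#' @return slides x k matrix of member probabilities.
#' @export
member_scores <- function(stage1, features) {
  d <- xgboost::xgb.DMatrix(features[, stage1$feature_names, drop = FALSE])
  vapply(stage1$members, function(m) predict(m, d),
         numeric(nrow(features)))
}

#' Any-positive ensemble rule
#'
#' A slide is positive when one or more ensemble members call it positive.
#'
#' @param member_calls Logical vector of member calls (length >= 1).
#' @return Single logical.
#' @export
#' @examples
#' ensemble_positive(c(FALSE, TRUE, FALSE))  # TRUE
ensemble_positive <- function(member_calls) {
  if (length(member_calls) == 0L || anyNA(member_calls))
    stop("ensemble_positive requires at least one non-missing member call")
  any(as.logical(member_calls))
}

#' Stage-1 ensemble prediction
#'
#' @param stage1 A `tbs_stage1` ensemble.
#' @param features Feature matrix.
#' @return List: `scores` (slides x k), `calls` (logical slides x k, score >=
#'   member threshold), `positive` (logical per slide, union rule).
#' @export
predict_stage1 <- function(stage1, features) {
  sc <- member_scores(stage1, features)
  calls <- sweep(sc, 2, stage1$thresholds, ">=")
  list(scores = sc, calls = calls,
       positive = apply(calls, 1, ensemble_positive))
}

#' Tune member thresholds for maximal screening sensitivity
#'
#' Chooses per-member thresholds so the any-positive ensemble reaches maximal
#' (target 1.0) sensitivity on the tuning set while keeping thresholds as high
#' as possible: each tuning-set positive is assigned to the member scoring it
#' highest, and that member's threshold is lowered to the minimum score over
#' its assigned positives; members covering no positive get a threshold above
#' 1 and never fire. Lowering any member threshold can only add positives, so
#' the contract that it never decreases ensemble sensitivity holds by
#' construction.
#'
#' @param stage1 A `tbs_stage1` ensemble.
#' @param features,labels Tuning set (must contain positives).
#' @return The ensemble with updated `thresholds`.
#' @export
tune_sensitivity <- function(stage1, features, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L))
    stop("tuning set contains no positive slides")
  sc <- member_scores(stage1, features)
  pos <- which(labels == 1L)
  thr <- rep(1 + 1e-9, length(stage1$members))
  best <- max.col(sc[pos, , drop = FALSE], ties.method = "first")
  for (m in unique(best))
    thr[m] <- min(sc[pos[best == m], m])
  stage1$thresholds <- thr
  stage1
}

#' Train the stage-2 squamous subtype model
#'
#' Multiclass boosted model over ASCUS, LSIL, ASCH, HSIL, SCC, applied to
#' slides stage 1 called positive.
#'
#' @param features Feature matrix of positive squamous slides.
#' @param subtypes Character vector of true subtypes.
#' @param seed,nrounds,params As in [train_stage1()].
#' @return Object of class `tbs_stage2`.
#' @export
train_stage2 <- function(features, subtypes, seed = 1L, nrounds = 60L,
                         params = .default_xgb_params("multi:softprob", 5L)) {
  if (!all(subtypes %in% .squamous_subtypes))
    stop("subtypes must be among: ", paste(.squamous_subtypes, collapse = ", "))
  y <- match(subtypes, .squamous_subtypes) - 1L
  d <- xgboost::xgb.DMatrix(features, label = y)
  booster <- xgboost::xgb.train(params = c(params, list(seed = seed)),
                                data = d, nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, classes = .squamous_subtypes,
                 feature_names = colnames(features)),
            class = "tbs_stage2")
}

#' Subtype from a class-probability vector
#'
#' Argmax over subtype probabilities; exact ties break toward the less severe
#' class (false escalation of the reported subtype has clinical-communication
#' cost, and subtype confusion does not change treatment).
#'
#' @param probs Numeric vector or matrix of probabilities in severity order
#'   (ASCUS, LSIL, ASCH, HSIL, SCC).
#' @return Character subtype(s).
#' @export
#' @examples
#' subtype_from_probs(c(0.1, 0.2, 0.1, 0.5, 0.1))  # "HSIL"
subtype_from_probs <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  stopifnot(ncol(probs) == length(.squamous_subtypes))
  .squamous_subtypes[apply(probs, 1, which.max)]  # which.max: first max
}

#' Predict squamous subtype for positive slides
#'
#' @param features Feature matrix.
#' @param stage2 A `tbs_stage2` model.
#' @return List: `subtype` (character) and `probs` (slides x 5 matrix).
#' @export
predict_stage2_subtype <- function(features, stage2) {
  if (!identical(colnames(features), stage2$feature_names))
    stop("feature schema mismatch between features and stage-2 model")
  p <- predict(stage2$booster,
               xgboost::xgb.DMatrix(features))
  if (is.null(dim(p)))
    p <- matrix(p, ncol = length(stage2$classes), byrow = TRUE)
  colnames(p) <- stage2$classes
  list(subtype = subtype_from_probs(p), probs = p)
}

#' Default logical-decision-tree configuration
#'
#' One branch per non-squamous finding. A branch fires when the slide holds at
#' least `min_count` targets of its classes with refined probability at or
#' above `min_prob`. AGC_A and AGC_B feed one merged AGC branch. Defaults were
#' calibrated once on the shipped synthetic corpus; all values can be
#' overridden (or loaded from YAML).
#'
#' @return data.frame with `branch`, `classes` (pipe-separated annotation
#'   codes), `min_prob`, `min_count`.
#' @export
default_logic_config <- function() {
  data.frame(
    branch   = c("TRI", "CAN", "HSV", "ACTINO", "CC", "EMC", "AGC"),
    classes  = c("TRI", "CAN", "HSV", "ACTINO", "CC", "EMC", "AGC_A|AGC_B"),
    min_prob = c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7),
    min_count = c(3L, 3L, 3L, 3L, 3L, 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Read / write a logic-tree configuration as YAML
#' @param config Logic config data.frame.
#' @param path YAML path.
#' @export
write_logic_config <- function(config, path) {
  yaml::write_yaml(list(branches = lapply(seq_len(nrow(config)), function(i)
    as.list(config[i, ]))), path)
  invisible(path)
}

#' @rdname write_logic_config
#' @export
read_logic_config <- function(path) {
  b <- yaml::read_yaml(path)$branches
  do.call(rbind, lapply(b, function(x)
    data.frame(branch = x$branch, classes = x$classes,
               min_prob = as.numeric(x$min_prob),
               min_count = as.integer(x$min_count),
               stringsAsFactors = FALSE)))
}

#' Logical decision tree for infectious, AGC and EMC findings
#'
#' Evaluates each branch rule independently on a slide's target records:
#' `count(refined class in branch classes, refined_prob >= min_prob) >=
#' min_count`.
#'
#' @param records Target records of one slide.
#' @param config Logic config (default [default_logic_config()]).
#' @param taxonomy Taxonomy table.
#' @return Character vector of fired branches (possibly empty), plus a
#'   `counts` attribute with the qualifying-target count per branch.
#' @export
logic_tree_decide <- function(records, config = default_logic_config(),
                              taxonomy = load_taxonomy()) {
  if (any(config$min_prob < 0 | config$min_prob > 1) ||
      any(config$min_count < 1L))
    stop("malformed logic rule: need min_prob in [0,1] and min_count >= 1")
  code_of <- taxonomy$code[match(records$refined_class, taxonomy$index)]
  counts <- integer(nrow(config))
  for (i in seq_len(nrow(config))) {
    cls <- strsplit(config$classes[i], "|", fixed = TRUE)[[1]]
    counts[i] <- sum(code_of %in% cls &
                       records$refined_prob >= config$min_prob[i])
  }
  fired <- config$branch[counts >= config$min_count]
  attr(fired, "counts") <- stats::setNames(counts, config$branch)
  fired
}

#' Final single-lesion TBS report
#'
#' Combines the squamous-branch call with the logic-tree findings and keeps a
#' single reported lesion by clinical-treatment priority
#' (SCC > HSIL > ASCH > AGC > LSIL > ASCUS > EMC > HSV > TRI > ACTINO > CAN >
#' CC > NILM). A slide with no finding reports NILM.
#'
#' @param slide_id Slide identifier.
#' @param squamous_call Logical: stage-1 ensemble positive?
#' @param subtype Stage-2 subtype (ignored unless `squamous_call`).
#' @param other_calls Character vector of fired logic-tree branches.
#' @param member_calls Optional logical vector of stage-1 member votes (kept
#'   as the evidence trail).
#' @param subtype_probs Optional named numeric vector of subtype
#'   probabilities.
#' @return A `tbs_report` list: `slide_id`, `final_tbs`, `squamous_branch`,
#'   `other_branch`, `priority_applied`.
#' @export
finalize_report <- function(slide_id, squamous_call, subtype = NULL,
                            other_calls = character(),
                            member_calls = NULL, subtype_probs = NULL) {
  lesions <- character()
  if (isTRUE(squamous_call)) {
    stopifnot(subtype %in% .squamous_subtypes)
    lesions <- subtype
  }
  lesions <- c(lesions, other_calls)
  final <- if (length(lesions) == 0L) "NILM" else
    .priority_order[min(match(lesions, .priority_order))]
  structure(list(
    slide_id = slide_id,
    final_tbs = final,
    squamous_branch = list(positive = isTRUE(squamous_call),
                           subtype = if (isTRUE(squamous_call)) subtype else NA,
                           member_calls = member_calls,
                           subtype_probs = subtype_probs),
    other_branch = other_calls,
    priority_applied = length(lesions) > 1L), class = "tbs_report")
}

#' Train the full decision engine on a labelled corpus
#'
#' Aggregates slide features, trains the stage-1 ensemble on
#' positive-squamous vs rest, tunes member thresholds for maximal training
#' sensitivity (the screening operating point), and trains the stage-2 subtype
#' model on the positive squamous slides. Non-squamous findings are handled by
#' the logic tree, which needs no training.
#'
#' @param corpus A corpus from [make_corpus()] (list with `records` per slide
#'   and `manifest` holding `slide_id`, `truth`).
#' @param k Folds/members for stage 1.
#' @param seed Integer seed.
#' @param schema Feature schema.
#' @param logic_config Logic-tree configuration.
#' @param tune Tune stage-1 thresholds on the training set (default TRUE).
#' @return Object of class `tbs_engine`.
#' @export
train_engine <- function(corpus, k = 10L, seed = 1L,
                         schema = default_feature_schema(),
                         logic_config = default_logic_config(),
                         tune = TRUE) {
  fvs <- lapply(corpus$records, aggregate_slide, schema = schema)
  X <- feature_matrix(fvs)
  truth <- corpus$manifest$truth
  y <- as.integer(truth %in% .squamous_subtypes)
  stage1 <- train_stage1(X, y, k = k, seed = seed)
  if (tune) stage1 <- tune_sensitivity(stage1, X, y)
  pos <- y == 1L
  stage2 <- train_stage2(X[pos, , drop = FALSE], truth[pos], seed = seed)
  structure(list(schema = schema, stage1 = stage1, stage2 = stage2,
                 logic_config = logic_config, seed = seed,
                 k = k), class = "tbs_engine")
}

#' Diagnose slides with a trained engine
#'
#' Runs the full decision pipeline on per-slide target records: feature
#' aggregation, stage-1 ensemble, stage-2 subtype for positives, logic tree,
#' and priority resolution.
#'
#' @param engine A `tbs_engine`.
#' @param records_list Named list of per-slide target-record data.frames.
#' @return List of `tbs_report` objects, one per slide, in input order.
#' @export
predict_tbs <- function(engine, records_list) {
  fvs <- lapply(records_list, aggregate_slide, schema = engine$schema)
  X <- feature_matrix(fvs)
  s1 <- predict_stage1(engine$stage1, X)
  s2 <- predict_stage2_subtype(X, engine$stage2)
  ids <- names(records_list)
  if (is.null(ids)) ids <- rownames(X)
  lapply(seq_along(records_list), function(i) {
    other <- logic_tree_decide(records_list[[i]], engine$logic_config)
    finalize_report(ids[i], s1$positive[i],
                    subtype = s2$subtype[i],
                    other_calls = as.character(other),
                    member_calls = s1$calls[i, ],
                    subtype_probs = s2$probs[i, ])
  })
}

#' Write TBS reports as JSON-lines
#'
#' One JSON object per report, with the full evidence trail; deterministic
#' byte-for-byte given identical inputs.
#'
#' @param reports List of `tbs_report`s.
#' @param path Output path.
#' @export
write_reports_jsonl <- function(reports, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in reports) {
    obj <- list(slide_id = r$slide_id, final_tbs = r$final_tbs,
                squamous_positive = r$squamous_branch$positive,
                subtype = r$squamous_branch$subtype,
                member_calls = as.logical(r$squamous_branch$member_calls),
                subtype_probs = round(unname(r$squamous_branch$subtype_probs),
                                      10),
                other_calls = r$other_branch,
                priority_applied = r$priority_applied)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10,
                                na = "null", null = "null"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Persist / restore a trained engine
#'
#' The engine is stored as a directory of portable text artifacts: the feature
#' schema and logic config as YAML, each stage-1 member and the stage-2 model
#' in the boosting library's JSON format, thresholds and metadata as YAML.
#'
#' @param engine A `tbs_engine`.
#' @param dir Directory path (created if needed).
#' @export
save_engine <- function(engine, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_schema(engine$schema, file.path(dir, "schema.yaml"))
  write_logic_config(engine$logic_config, file.path(dir, "logic.yaml"))
  for (i in seq_along(engine$stage1$members))
    xgboost::xgb.save(engine$stage1$members[[i]],
                      file.path(dir, sprintf("stage1_member_%02d.json", i)))
  xgboost::xgb.save(engine$stage2$booster, file.path(dir, "stage2.json"))
  yaml::write_yaml(list(
    k = engine$k, seed = engine$seed,
    thresholds = engine$stage1$thresholds,
    folds = engine$stage1$folds,
    feature_names = engine$stage1$feature_names,
    stage2_classes = engine$stage2$classes), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname save_engine
#' @export
load_engine <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  members <- lapply(seq_len(meta$k), function(i)
    xgboost::xgb.load(file.path(dir, sprintf("stage1_member_%02d.json", i))))
  stage1 <- structure(list(members = members,
                           thresholds = as.numeric(meta$thresholds),
                           folds = as.integer(meta$folds), seed = meta$seed,
                           feature_names = unlist(meta$feature_names)),
                      class = "tbs_stage1")
  stage2 <- structure(list(booster = xgboost::xgb.load(
    file.path(dir, "stage2.json")),
    classes = unlist(meta$stage2_classes),
    feature_names = unlist(meta$feature_names)), class = "tbs_stage2")
  structure(list(schema = read_feature_schema(file.path(dir, "schema.yaml")),
                 stage1 = stage1, stage2 = stage2,
                 logic_config = read_logic_config(file.path(dir, "logic.yaml")),
                 seed = meta$seed, k = meta$k), class = "tbs_engine")
}
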