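# Independent oracles and shared fixtures. Oracles are written as plain
# loops/enumerations, deliberately not sharing code paths with the package.

# rank-based AUC (Mann-Whitney)
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# naive per-feature enumeration oracle for slide aggregation
oracle_aggregate <- function(records, schema, taxonomy = load_taxonomy()) {
  code_of <- function(i) taxonomy$code[taxonomy$index == i]
  vals <- numeric(nrow(schema)); miss <- logical(nrow(schema))
  for (i in seq_len(nrow(schema))) {
    sc <- schema$scope[i]; st <- schema$statistic[i]; src <- schema$source[i]
    xs <- numeric(0)
    nsel <- 0L
    for (r in seq_len(nrow(records))) {
      rc <- code_of(records$refined_class[r])
      in_scope <- switch(src,
        detection = sc == "*" || records$det_class[r] == sc,
        refined = rc == sc,
        patch = !is.na(records$patch_label[r]) &&
          records$patch_label[r] == sc,
        nucleus = rc == sc && !is.na(records$nucleus_mean_gray[r]))
      if (!in_scope) next
      nsel <- nsel + 1L
      xs <- c(xs, switch(src,
        detection = records$det_prob[r],
        refined = records$refined_prob[r],
        patch = records$patch_prob[r],
        nucleus = if (st == "nucleus-gray-quantile")
          records$nucleus_mean_gray[r] else records$nucleus_area_px[r]))
    }
    if (st == "count") {
      vals[i] <- nsel
    } else if (st == "count-above-threshold") {
      vals[i] <- sum(xs >= schema$threshold[i])
    } else if (nsel == 0L) {
      vals[i] <- 0; miss[i] <- TRUE
    } else {
      vals[i] <- switch(st,
        "max-prob" = max(xs),
        "mean-prob" = mean(xs),
        "top-k-mean-prob" = mean(sort(xs, decreasing = TRUE)[
          seq_len(min(schema$k[i], length(xs)))]),
        unname(stats::quantile(xs, schema$q[i], type = 7)))
    }
  }
  list(values = stats::setNames(vals, schema$name),
       missing = stats::setNames(miss, schema$name))
}

# brute-force Otsu: try every threshold t in 0..254, class0 = {g <= t},
# minimize the weighted within-class variance
oracle_otsu <- function(gray) {
  g <- pmin(pmax(round(as.vector(gray)), 0), 255)
  if (length(unique(g)) < 2L) return(NA_integer_)
  best_t <- NA_integer_; best_w <- Inf
  for (t in 0:254) {
    a <- g[g <= t]; b <- g[g > t]
    if (!length(a) || !length(b)) next
    pv <- function(x) if (length(x) > 1) mean((x - mean(x))^2) else 0
    wcv <- (length(a) * pv(a) + length(b) * pv(b)) / length(g)
    if (wcv < best_w - 1e-12) { best_w <- wcv; best_t <- t }
  }
  best_t
}

# direct-convolution variance-of-Laplacian oracle (explicit double loop)
oracle_focus <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  resp <- matrix(0, nr - 2, nc - 2)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1))
    resp[i - 1, j - 1] <- gray[i - 1, j] + gray[i + 1, j] +
      gray[i, j - 1] + gray[i, j + 1] - 4 * gray[i, j]
  mean((resp - mean(resp))^2)
}

# brute-force check that boxes exactly tile `box`: paint coverage counts
oracle_tiles_exactly <- function(box, tiles) {
  cover <- matrix(0L, box$height, box$width)
  for (i in seq_len(nrow(tiles))) {
    ri <- (tiles$y[i] - box$y + 1):(tiles$y[i] - box$y + tiles$height[i])
    ci <- (tiles$x[i] - box$x + 1):(tiles$x[i] - box$x + tiles$width[i])
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  all(cover == 1L)
}

# --- memoized heavy fixtures shared across test files ---------------------

.fixtures <- new.env(parent = emptyenv())

engine_fixture <- function() {
  if (is.null(.fixtures$engine)) {
    train <- make_corpus(600, seed = 42L)
    test <- make_corpus(300, seed = derive_seeds(42L, 2)[2])
    engine <- train_engine(train, k = 10L, seed = 42L)
    .fixtures$engine <- list(train = train, test = test, engine = engine)
  }
  .fixtures$engine
}

qc_fixture <- function() {
  if (is.null(.fixtures$qc)) {
    tr <- simulate_qc_corpus(400, seed = 42L)
    te <- simulate_qc_corpus(200, seed = derive_seeds(42L, 2)[2])
    gate <- train_qc_gate(tr$features, tr$qualified, seed = 42L)
    .fixtures$qc <- list(train = tr, test = te, gate = gate)
  }
  .fixtures$qc
}
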