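#' Confusion counts at a score threshold
#'
#' Scores greater than or equal to the threshold are predicted positive
#' (the documented tie rule for scores exactly at the threshold).
#'
#' @param y Binary labels (0/1).
#' @param scores Numeric scores, same length as `y`.
#' @param threshold Decision threshold (default 0.5).
#' @return Object of class `confusion`: list with integer fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y, scores, threshold = 0.5) {
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(scores)) stop("y and scores differ in length")
  if (!all(is.finite(scores))) stop("scores must be finite")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  structure(list(tp = sum(pred == 1L & y == 1L),
                 fp = sum(pred == 1L & y == 0L),
                 tn = sum(pred == 0L & y == 0L),
                 fn = sum(pred == 0L & y == 1L)),
            class = "confusion")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, ": 0/0 denominator, reporting 0")
    return(0)
  }
  num / den
}

#' Classification metrics from a confusion table
#'
#' Computes accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)` and the Matthews
#' correlation coefficient
#' `(TN*TP - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FN)(TN+FP))`.
#' Any 0/0 denominator yields 0 with a warning (for MCC a zero
#' denominator also yields 0).
#'
#' @param cf A [confusion()] object.
#' @return Named numeric vector with elements `acc`, `pr`, `sens`,
#'   `spec`, `mcc` (proportions in `[0, 1]`; `mcc` in `[-1, 1]`).
#' @export
confusion_metrics <- function(cf) {
  stopifnot(inherits(cf, "confusion"))
  tp <- as.numeric(cf$tp); fp <- as.numeric(cf$fp)
  tn <- as.numeric(cf$tn); fn <- as.numeric(cf$fn)
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fn) * (tn + fp))
  mcc <- if (mcc_den == 0) {
    warning("MCC: zero denominator, reporting 0")
    0
  } else (tn * tp - fp * fn) / mcc_den
  c(acc = (tp + tn) / total,
    pr = safe_ratio(tp, tp + fp, "precision"),
    sens = safe_ratio(tp, tp + fn, "sensitivity"),
    spec = safe_ratio(tn, fp + tn, "specificity"),
    mcc = mcc)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping every distinct score as a threshold
#' (predicting positive at `score >= threshold`) and integrates the area
#' under it with the trapezoidal rule. With distinct-threshold sweeping,
#' the trapezoidal area equals the rank statistic
#' `P(score+ > score-) + 0.5 * P(tie)`.
#'
#' @param y Binary labels (0/1); both classes must be present.
#' @param scores Numeric scores.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`,
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(y, scores) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0L || N == 0L)
    stop("ROC needs both classes present (got ", P, " positives, ",
         N, " negatives)")
  if (!all(is.finite(scores))) stop("scores must be finite")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- sum(pred & y == 1L) / P
    fpr[i] <- sum(pred & y == 0L) / N
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

#' Split indices into k cross-validation folds
#'
#' Random, seeded partition of `1:n` into k folds of near-equal size
#' (differing by at most one). With `stratified = TRUE` (default) the
#' per-fold class ratios match the global ratio to within one sample per
#' class.
#'
#' @param labels Binary labels (used for stratification; its length
#'   defines n).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param stratified Stratify on `labels`?
#' @return List of k disjoint integer index vectors covering `1:n`.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be at least 2")
  n <- length(labels)
  if (n < k) stop("need at least k = ", k, " observations, got ", n)
  with_seed(seed, {
    fold_of <- integer(n)
    if (stratified) {
      offset <- 0L
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold_of[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- (offset + length(idx)) %% k
      }
    } else {
      ord <- sample.int(n)
      fold_of[ord] <- ((seq_len(n) - 1L) %% k) + 1L
    }
    lapply(seq_len(k), function(f) which(fold_of == f))
  })
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

#' Sample non-interacting protein pairs from the bipartite complement
#'
#' The candidate space is, by default, all ordered protein pairs
#' (including self-pairs): for p proteins there are p^2 candidates, of
#' which the known interacting pairs are excluded, and n pairs are drawn
#' uniformly without replacement from the remainder and labelled 0. Set
#' `ordered = FALSE` for the stricter convention of unordered distinct
#' pairs (`p * (p - 1) / 2` candidates).
#'
#' @param proteins Character vector of protein identifiers.
#' @param positives data.frame with columns `idA`, `idB` (the known
#'   interacting pairs), or NULL.
#' @param n Number of negative pairs to draw.
#' @param seed Integer seed.
#' @param ordered Use the ordered (with self-pairs) candidate space?
#' @return data.frame with columns `idA`, `idB`, `label` (all 0).
#' @export
sample_negatives <- function(proteins, positives, n, seed = 1L,
                             ordered = TRUE) {
  proteins <- unique(as.character(proteins))
  p <- length(proteins)
  total <- if (ordered) p^2 else p * (p - 1) / 2
  pos_keys <- character(0)
  if (!is.null(positives) && nrow(positives) > 0) {
    a <- as.character(positives$idA); b <- as.character(positives$idB)
    pos_keys <- if (ordered) pair_key(a, b)
                else pair_key(pmin(a, b), pmax(a, b))
    pos_keys <- unique(pos_keys)
    pos_keys <- pos_keys[pos_keys %in% all_keys_check(proteins, pos_keys)]
  }
  avail <- total - length(pos_keys)
  if (n > avail)
    stop("requested ", n, " negative pairs but only ", avail,
         " non-positive candidates exist")
  idx_to_pair <- if (ordered) {
    function(i) c(proteins[(i - 1) %/% p + 1], proteins[(i - 1) %% p + 1])
  } else {
    function(i) {
      # i-th unordered pair (a < b) in row-major order of the upper triangle
      a <- 1L
      skip <- p - 1L
      while (i > skip) { i <- i - skip; a <- a + 1L; skip <- p - a }
      c(proteins[a], proteins[a + i])
    }
  }
  with_seed(seed, {
    out_a <- character(n); out_b <- character(n)
    if (total <= 2e6) {
      keys_all <- if (ordered) {
        pair_key(rep(proteins, each = p), rep(proteins, times = p))
      } else {
        cmb <- utils::combn(proteins, 2L)
        pair_key(pmin(cmb[1L, ], cmb[2L, ]), pmax(cmb[1L, ], cmb[2L, ]))
      }
      pool <- which(!(keys_all %in% pos_keys))
      pick <- pool[sample.int(length(pool), n)]
      for (j in seq_len(n)) {
        pr <- idx_to_pair(pick[j]); out_a[j] <- pr[1]; out_b[j] <- pr[2]
      }
    } else {
      seen <- new.env(hash = TRUE, size = n)
      got <- 0L
      while (got < n) {
        i <- floor(stats::runif(1L, 0, total)) + 1
        pr <- idx_to_pair(i)
        key <- if (ordered) pair_key(pr[1], pr[2])
               else pair_key(min(pr), max(pr))
        if (key %in% pos_keys || !is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        got <- got + 1L
        out_a[got] <- pr[1]; out_b[got] <- pr[2]
      }
    }
    data.frame(idA = out_a, idB = out_b, label = 0L,
               stringsAsFactors = FALSE)
  })
}

# Restrict positive keys to pairs whose both members are in the protein set.
all_keys_check <- function(proteins, keys) {
  parts <- strsplit(keys, "\r", fixed = TRUE)
  ok <- vapply(parts, function(x)
    all(x %in% proteins), logical(1))
  keys[ok]
}

#' Bipartite candidate-space arithmetic
#'
#' For a set of p proteins with `n_positive` known interacting pairs, the
#' all-ordered-pairs bipartite network has `p^2` candidate links, leaving
#' `p^2 - n_positive` possible non-interacting pairs; the balanced
#' benchmark dataset (equal negatives) has `2 * n_positive` pairs. For
#' the 7,437-protein set with 28,110 interactions these are 55,308,969,
#' 55,280,859 and 56,220.
#'
#' @param n_proteins Number of proteins p.
#' @param n_positive Number of known interacting pairs.
#' @return Named numeric vector: `candidate_pairs`,
#'   `negative_candidates`, `balanced_dataset`.
#' @export
bipartite_counts <- function(n_proteins, n_positive) {
  p <- as.numeric(n_proteins); q <- as.numeric(n_positive)
  if (p < 1 || q < 0 || q > p^2) stop("invalid set sizes")
  c(candidate_pairs = p^2,
    negative_candidates = p^2 - q,
    balanced_dataset = 2 * q)
}

#' Five-fold cross-validation of the full pipeline
#'
#' For each fold: an SVD projector is fitted on the descriptors of the
#' proteins appearing in the training pairs (or on all proteins when
#' `svd$paper_mode` is TRUE), all descriptors are projected, pair
#' descriptors are assembled by concatenation, the configured classifier
#' is trained on the training pairs and scored on the held-out fold, and
#' Acc/PR/Sens/Spec/MCC plus the ROC curve and AUC are computed. Fold
#' means and sample standard deviations (n-1) are aggregated. Fully
#' seeded: identical calls produce identical reports.
#'
#' @param records Named character vector of sequences (names = ids).
#' @param pairs data.frame `idA`, `idB`, `label`.
#' @param profiles Named list of `ppi_profile` objects covering every id
#'   in `pairs`.
#' @param config Pipeline configuration, see [default_config()].
#' @return Object of class `cv_report`: list with `folds` (data.frame of
#'   per-fold metrics), `mean`, `sd`, `roc` (per-fold ROC point tables)
#'   and `k`.
#' @export
run_cv <- function(records, pairs, profiles, config = default_config()) {
  config <- merge_config(config)
  ids <- unique(c(pairs$idA, pairs$idB))
  missing <- setdiff(ids, names(profiles))
  if (length(missing))
    stop("no profile for protein id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  desc <- run_features(records, profiles, config)
  k <- config$cv$k
  folds <- kfold_split(pairs$label, k = k, seed = config$cv$seed,
                       stratified = config$cv$stratified)
  fold_rows <- vector("list", k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(nrow(pairs)), test_idx)
    tr <- pairs[train_idx, , drop = FALSE]
    te <- pairs[test_idx, , drop = FALSE]
    fit_ids <- if (isTRUE(config$svd$paper_mode)) rownames(desc)
               else unique(c(tr$idA, tr$idB))
    Xfit <- desc[fit_ids, , drop = FALSE]
    k_svd <- min(config$svd$k, nrow(Xfit), ncol(Xfit))
    proj <- fit_projector(Xfit, k = k_svd)
    Z <- project(proj, desc)
    rownames(Z) <- rownames(desc)
    make_X <- function(pp)
      cbind(Z[pp$idA, , drop = FALSE], Z[pp$idB, , drop = FALSE])
    Xtr <- make_X(tr); ytr <- tr$label
    if (isTRUE(config$pair$symmetrize)) {
      Xtr <- rbind(Xtr, cbind(Z[tr$idB, , drop = FALSE],
                              Z[tr$idA, , drop = FALSE]))
      ytr <- c(ytr, tr$label)
    }
    Xte <- make_X(te)
    fold_seed <- config$cv$seed * 1000L + f
    scores <- switch(config$classifier,
      dnn = {
        cfg <- dnn_config(architecture = config$dnn$architecture,
                          hidden = config$dnn$hidden,
                          dropout = config$dnn$dropout,
                          learning_rate = config$dnn$learning_rate,
                          epochs = config$dnn$epochs,
                          batch_size = config$dnn$batch_size,
                          seed = fold_seed)
        m <- train_dnn(Xtr, ytr, cfg)
        predict(m, Xte)
      },
      knn = predict(train_baseline("knn", Xtr, ytr, k = config$baseline$knn_k,
                                   seed = fold_seed), Xte),
      rf = predict(train_baseline("rf", Xtr, ytr,
                                  trees = config$baseline$rf_trees,
                                  seed = fold_seed), Xte),
      stop("unknown classifier: ", config$classifier))
    cf <- confusion(te$label, scores, threshold = config$threshold)
    met <- confusion_metrics(cf)
    rc <- roc_auc(te$label, scores)
    fold_rows[[f]] <- data.frame(fold = f, t(met), auc = rc$auc)
    rocs[[f]] <- rc$points
  }
  folds_df <- do.call(rbind, fold_rows)
  metr <- c("acc", "pr", "sens", "spec", "mcc", "auc")
  structure(list(folds = folds_df,
                 mean = vapply(metr, function(m) mean(folds_df[[m]]), 0),
                 sd = vapply(metr, function(m) stats::sd(folds_df[[m]]), 0),
                 roc = rocs, k = k, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  writeLines(format_cv_table(x))
  invisible(x)
}
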