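test_that("confusion counts tally predictions at the threshold", {
  cf <- confusion(c(1, 0), c(0.9, 0.1))
  expect_identical(cf[c("tp", "fp", "tn", "fn")],
                   list(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  cf <- confusion(c(1, 0), c(0.1, 0.9))
  expect_identical(cf$fn, 1L)
  expect_identical(cf$fp, 1L)
  # a score exactly at the threshold counts as positive
  expect_identical(confusion(1, 0.5)$tp, 1L)
  expect_error(confusion(numeric(0), numeric(0)), "empty")
  expect_error(confusion(c(1, 0), 0.5), "length")
})

test_that("metrics reproduce hand-evaluated formulas", {
  perfect <- structure(list(tp = 5L, fp = 0L, tn = 5L, fn = 0L),
                       class = "confusion")
  m <- confusion_metrics(perfect)
  expect_equal(unname(m), c(1, 1, 1, 1, 1))
  inverted <- structure(list(tp = 0L, fp = 5L, tn = 0L, fn = 5L),
                        class = "confusion")
  m <- suppressWarnings(confusion_metrics(inverted))
  expect_equal(m[["acc"]], 0)
  expect_equal(m[["mcc"]], -1)
  # tp=3 fp=1 tn=2 fn=2: Acc = 5/8, MCC = 4/sqrt(240)
  cf <- structure(list(tp = 3L, fp = 1L, tn = 2L, fn = 2L),
                  class = "confusion")
  m <- confusion_metrics(cf)
  expect_equal(m[["acc"]], 0.625)
  expect_equal(m[["mcc"]], 4 / sqrt(240), tolerance = 1e-12)
  expect_equal(m[["pr"]], 3 / 4)
  expect_equal(m[["sens"]], 3 / 5)
  expect_equal(m[["spec"]], 2 / 3)
})

test_that("zero denominators yield 0 with a warning", {
  cf <- structure(list(tp = 0L, fp = 0L, tn = 4L, fn = 3L),
                  class = "confusion")
  w <- capture_warnings(m <- confusion_metrics(cf))
  expect_match(w, "precision", all = FALSE)
  expect_match(w, "MCC", all = FALSE)   # (0+0) factor zeroes the denominator
  expect_equal(m[["pr"]], 0)
  all_neg <- structure(list(tp = 0L, fp = 0L, tn = 5L, fn = 0L),
                       class = "confusion")
  m <- suppressWarnings(confusion_metrics(all_neg))
  expect_equal(m[["mcc"]], 0)
})

test_that("metrics agree with independent statistics on all small tables", {
  # exhaustive enumeration of confusion tables with totals <= 20;
  # oracle: accuracy as agreement rate, MCC as the Pearson correlation
  # of the expanded 0/1 prediction and label vectors
  for (total in c(4L, 9L)) {
    parts <- expand.grid(tp = 0:total, fp = 0:total, tn = 0:total)
    parts$fn <- total - parts$tp - parts$fp - parts$tn
    parts <- parts[parts$fn >= 0, ]
    for (i in seq_len(nrow(parts))) {
      tp <- parts$tp[i]; fp <- parts$fp[i]
      tn <- parts$tn[i]; fn <- parts$fn[i]
      y <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
      pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
      cf <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                      class = "confusion")
      m <- suppressWarnings(confusion_metrics(cf))
      expect_equal(m[["acc"]], mean(pred == y), tolerance = 1e-12)
      if (sd(y) > 0 && sd(pred) > 0)
        expect_equal(m[["mcc"]], cor(y, pred), tolerance = 1e-12)
      # Eq identity: Acc == (Sens*P + Spec*N) / (P + N) when defined
      P <- tp + fn; N <- tn + fp
      if (P > 0 && N > 0)
        expect_equal(m[["acc"]], (m[["sens"]] * P + m[["spec"]] * N) / total,
                     tolerance = 1e-12)
    }
  }
})

test_that("MCC magnitude is invariant under class+prediction relabelling", {
  set.seed(1)
  for (i in 1:25) {
    v <- sample(0:8, 4, replace = TRUE)
    if (sum(v) == 0) next
    cf <- structure(list(tp = v[1], fp = v[2], tn = v[3], fn = v[4]),
                    class = "confusion")
    sw <- structure(list(tp = v[3], fp = v[4], tn = v[1], fn = v[2]),
                    class = "confusion")
    expect_equal(suppressWarnings(confusion_metrics(cf))[["mcc"]],
                 suppressWarnings(confusion_metrics(sw))[["mcc"]],
                 tolerance = 1e-12)
  }
})

test_that("ROC handles separation, ties, and the worked example", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  # recomputed by exhaustive pair counting: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("trapezoidal AUC equals the rank-statistic oracle (and pROC)", {
  rank_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(2)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- if (i %% 3 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)
         else runif(n)
    got <- roc_auc(y, s)
    expect_equal(got$auc, rank_auc(y, s), tolerance = 1e-10)
    expect_equal(got$points$fpr[1], 0)
    expect_equal(got$points$tpr[nrow(got$points)], 1)
  }
  # independent library cross-check on one instance
  skip_if_not_installed("pROC")
  y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1); s <- runif(80)
  expect_equal(roc_auc(y, s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("k-fold splits partition the data with near-equal sizes", {
  labels <- rep(c(0, 1), each = 5)
  folds <- kfold_split(labels, k = 5, seed = 1)
  expect_length(folds, 5L)
  expect_true(all(lengths(folds) == 2L))
  expect_identical(sort(unlist(folds)), 1:10)
  # determinism
  expect_identical(folds, kfold_split(labels, k = 5, seed = 1))
  expect_error(kfold_split(labels, k = 1), "at least 2")
  expect_error(kfold_split(labels[1:3], k = 5), "at least k")
})

test_that("stratified folds hold the class ratio to within one sample", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(30:120, 1)
    labels <- rbinom(n, 1, runif(1, 0.3, 0.7))
    if (length(unique(labels)) < 2) next
    k <- sample(2:6, 1)
    folds <- kfold_split(labels, k = k, seed = i)
    expect_identical(sort(unlist(folds)), seq_len(n))
    expect_lte(diff(range(lengths(folds))), 2L)
    per_fold_pos <- vapply(folds, function(f) sum(labels[f]), 0)
    expect_lte(diff(range(per_fold_pos)), 1)
  }
})

test_that("negative sampling draws only from the non-positive complement", {
  prots <- c("a", "b", "c")
  pos <- data.frame(idA = c("a", "b"), idB = c("b", "c"))
  # 9 ordered pairs - 2 positives = 7 available
  neg <- sample_negatives(prots, pos, 7, seed = 1)
  expect_identical(nrow(neg), 7L)
  expect_true(all(neg$label == 0L))
  keys <- paste(neg$idA, neg$idB)
  expect_false(any(keys %in% c("a b", "b c")))
  expect_false(any(duplicated(keys)))
  expect_error(sample_negatives(prots, pos, 8, seed = 1), "only 7")
})

test_that("negative sampling is seeded and respects the unordered option", {
  prots <- sprintf("p%02d", 1:8)
  pos <- data.frame(idA = "p01", idB = "p02")
  n1 <- sample_negatives(prots, pos, 10, seed = 5)
  n2 <- sample_negatives(prots, pos, 10, seed = 5)
  expect_identical(n1, n2)
  # unordered: 8*7/2 - 1 = 27 available, exhaustion draws all
  nu <- sample_negatives(prots, pos, 27, seed = 1, ordered = FALSE)
  expect_identical(nrow(nu), 27L)
  expect_true(all(nu$idA != nu$idB))
  keys <- paste(pmin(nu$idA, nu$idB), pmax(nu$idA, nu$idB))
  expect_false(any(duplicated(keys)))
  expect_false(any(keys == "p01 p02"))
  expect_error(sample_negatives(prots, pos, 28, seed = 1, ordered = FALSE),
               "only 27")
})

test_that("bipartite arithmetic follows the all-ordered-pairs convention", {
  counts <- bipartite_counts(3, 2)
  expect_equal(counts[["candidate_pairs"]], 9)
  expect_equal(counts[["negative_candidates"]], 7)
  expect_equal(counts[["balanced_dataset"]], 4)
  expect_error(bipartite_counts(2, 5), "invalid")
})

test_that("cross-validation is reproducible and reports k fold rows", {
  ds <- tiny_dataset()
  cfg <- fast_config()
  rep1 <- run_cv(ds$records, ds$pairs, ds$profiles, cfg)
  rep2 <- run_cv(ds$records, ds$pairs, ds$profiles, cfg)
  expect_identical(rep1, rep2)
  expect_identical(nrow(rep1$folds), 5L)
  expect_length(rep1$roc, 5L)
  expect_true(all(rep1$folds$auc >= 0 & rep1$folds$auc <= 1))
  expect_equal(rep1$mean[["auc"]], mean(rep1$folds$auc))
  expect_equal(rep1$sd[["acc"]], sd(rep1$folds$acc))
  expect_error(
    run_cv(ds$records, data.frame(idA = "zz", idB = "yy", label = 1L),
           ds$profiles, cfg),
    "no profile")
})
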