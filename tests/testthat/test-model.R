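test_that("random forest separates a trivial problem and is seeded", {
  y <- rep(c("negative", "positive"), each = 10)
  X <- cbind(perfect = as.integer(y == "positive"),
             noise = rbinom(20, 1, 0.5))
  m <- train_random_forest(X, y, n_trees = 100, seed = 3)
  sc <- predict_scores(m, X)
  expect_equal(mean((sc >= 0.5) == (y == "positive")), 1)

  m2 <- train_random_forest(X, y, n_trees = 100, seed = 3)
  expect_identical(predict_scores(m2, X), sc)

  expect_error(train_random_forest(X, rep("positive", 20)), "Both classes")
})

test_that("prediction aligns columns by name and rejects missing features", {
  set.seed(7)
  y <- rep(c("negative", "positive"), each = 25)
  X <- matrix(rbinom(50 * 6, 1, 0.5), nrow = 50,
              dimnames = list(NULL, paste0("V", 1:6)))
  X[, 1] <- as.integer(y == "positive")
  m <- train_random_forest(X, y, n_trees = 100, seed = 1)
  sc <- predict_scores(m, X)
  expect_true(all(sc >= 0 & sc <= 1))
  # column-permuted input with correct names scores identically
  perm <- X[, sample(ncol(X))]
  expect_identical(predict_scores(m, perm), sc)
  # duplicated input row gives identical scores
  expect_equal(predict_scores(m, X[c(1, 1), ]), rep(sc[1], 2))
  expect_error(predict_scores(m, X[, 1:3]), "lacks model features")
})

test_that("confusion counts follow the score >= threshold call rule", {
  labels <- c("positive", "positive", "negative", "negative", "positive",
              "negative")
  scores <- c(0.9, 0.4, 0.6, 0.2, 0.5, 0.5)
  cc <- confusion_counts(scores, labels, 0.5)
  # calls: .9 .6 .5 .5 positive -> TP {.9,.5}, FP {.6,.5}, FN {.4}, TN {.2}
  expect_equal(cc, tibble::tibble(TP = 2L, TN = 1L, FP = 2L, FN = 1L))

  t0 <- confusion_counts(scores, labels, 0)
  expect_equal(t0$FN, 0L); expect_equal(t0$TN, 0L)
  t2 <- confusion_counts(scores, labels, 1.5)
  expect_equal(t2$TP, 0L); expect_equal(t2$FP, 0L)
})

test_that("performance measures match their defining formulas", {
  perfect <- compute_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(SEN = 1, SPE = 1, PRE = 1, ACC = 1,
                                  F_score = 1, MCC = 1))

  coin <- compute_metrics(list(TP = 5, TN = 5, FP = 5, FN = 5))
  expect_equal(coin$ACC, 0.5)
  expect_equal(coin$MCC, 0)

  m <- compute_metrics(list(TP = 3, FN = 1, TN = 2, FP = 2))
  expect_equal(m$SEN, 0.75)
  expect_equal(m$SPE, 0.5)
  expect_equal(m$PRE, 0.6)
  expect_equal(m$ACC, 0.625)
  expect_equal(m$F_score, 2 * 3 / (2 * 3 + 2 + 1))
  expect_equal(m$MCC, (3 * 2 - 2 * 1) / sqrt((3 + 1) * (3 + 2) * (2 + 1) * (2 + 2)))

  # 0/0 ratios are undefined markers, MCC falls back to 0
  degen <- compute_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(degen$SEN))
  expect_true(is.na(degen$PRE))
  expect_equal(degen$MCC, 0)
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "Empty confusion")
})

test_that("metric identities hold over random confusion tables", {
  set.seed(11)
  for (i in 1:200) {
    counts <- as.list(rmultinom(1, sample(4:200, 1), runif(4, 0.05, 1))[, 1])
    names(counts) <- c("TP", "TN", "FP", "FN")
    m <- compute_metrics(counts)
    # recompute from binary vectors: MCC is the Pearson correlation
    truth <- c(rep(1, counts$TP + counts$FN), rep(0, counts$TN + counts$FP))
    pred <- c(rep(1, counts$TP), rep(0, counts$FN),
              rep(0, counts$TN), rep(1, counts$FP))
    expect_equal(m$ACC, mean(truth == pred))
    if (sd(truth) > 0 && sd(pred) > 0) {
      expect_equal(m$MCC, cor(truth, pred), tolerance = 1e-12)
    }
    if (!is.na(m$PRE) && !is.na(m$SEN) && (m$PRE + m$SEN) > 0) {
      expect_equal(m$F_score, 2 * m$PRE * m$SEN / (m$PRE + m$SEN),
                   tolerance = 1e-12)
    }
    # swapping predicted calls negates MCC
    flipped <- compute_metrics(list(TP = counts$FN, TN = counts$FP,
                                    FP = counts$TN, FN = counts$TP))
    expect_equal(flipped$MCC, -m$MCC, tolerance = 1e-12)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
  }
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney statistic", {
  labels <- rep(c("positive", "negative"), each = 4)
  sep <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)
  expect_equal(roc_auc(sep, labels)$auc, 1)

  expect_equal(roc_auc(rep(0.5, 8), labels)$auc, 0.5)

  tied <- c(0.9, 0.7, 0.5, 0.3, 0.8, 0.5, 0.2, 0.1)
  expect_equal(roc_auc(tied, labels)$auc, auc_oracle(tied, labels))

  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    lab <- c(rep("positive", n), rep("negative", n))
    sc <- sample(seq(0, 1, by = 0.1), 2 * n, replace = TRUE)
    rc <- roc_auc(sc, lab)
    expect_equal(rc$auc, auc_oracle(sc, lab), tolerance = 1e-12)
    expect_equal(rc$points$fpr[1], 0)
    expect_equal(rc$points$tpr[nrow(rc$points)], 1)
    expect_true(all(diff(rc$points$fpr) >= 0))
  }
  expect_error(roc_auc(1:3, rep("positive", 3)), "Both classes")
})

test_that("cross-validation partitions cleanly and is reproducible", {
  set.seed(17)
  y <- rep(c("negative", "positive"), each = 30)
  X <- cbind(perfect = as.integer(y == "positive"),
             matrix(rbinom(60 * 5, 1, 0.5), nrow = 60))
  colnames(X) <- paste0("V", 1:6)

  cv <- cross_validate(X, y, folds = 5, repeats = 2, n_trees = 50, seed = 4)
  # every sample in exactly one test fold per repeat, strata balanced
  expect_true(all(cv$folds %in% 1:5))
  for (r in 1:2) {
    expect_equal(as.vector(table(cv$folds[y == "positive", r])), rep(6, 5))
  }
  expect_equal(cv$summary$mean[cv$summary$metric == "ACC"], 1)

  cv2 <- cross_validate(X, y, folds = 5, repeats = 2, n_trees = 50, seed = 4)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$summary, cv2$summary)

  expect_error(cross_validate(X[1:8, ], y[c(1:4, 31:34)], folds = 5),
               "at least")
})

test_that("label-permuted cross-validation hovers at chance", {
  set.seed(19)
  n <- 80
  y <- sample(rep(c("negative", "positive"), each = n / 2))
  X <- matrix(rbinom(n * 20, 1, 0.5), nrow = n,
              dimnames = list(NULL, paste0("V", 1:20)))
  cv <- cross_validate(X, y, folds = 5, repeats = 3, n_trees = 100, seed = 2)
  auc <- cv$summary[cv$summary$metric == "AUC", ]
  expect_lt(abs(auc$mean - 0.5), 3 * max(auc$sd, 0.05))
})

test_that("threshold calibration reaches the target specificity", {
  set.seed(23)
  neg <- runif(1000)
  t99 <- calibrate_threshold(neg, 0.99)
  expect_gte(mean(neg < t99), 0.99)
  expect_lt(abs(t99 - quantile(neg, 0.99)), 0.02)

  t50 <- calibrate_threshold(neg, 0.5)
  expect_lt(abs(t50 - median(neg)), 0.05)

  # degenerate all-zero scores: smallest step above zero
  tz <- suppressWarnings(calibrate_threshold(rep(0, 10), 0.99))
  expect_gt(tz, 0)
  expect_lt(tz, 1e-10)
  expect_error(calibrate_threshold(neg, 1), "target_specificity")

  # specificity >= target by construction for any score sample
  for (i in 1:20) {
    s <- round(runif(50), 2)
    t <- suppressWarnings(calibrate_threshold(s, 0.9))
    expect_gte(mean(s < t), 0.9)
  }
})

test_that("proteome scanning counts substrates and sites consistently", {
  st <- small_study(seed = 31)
  ds <- study_dataset(st)
  lay <- make_layout(sequence_block_sizes())
  fm <- assemble_feature_matrix(ds, lay, blocks = c("AAseq", "DISO"))
  model <- train_random_forest(fm, n_trees = 100, seed = 5)

  sub <- st$proteins[1:12, ]
  tr <- st$structures[st$structures$protein_id %in% sub$protein_id, ]
  scan <- proteome_scan(model, sub, tr, threshold = 0.6)
  expect_equal(scan$summary$n_sites, sum(scan$predictions$call))
  expect_equal(scan$summary$n_substrates,
               length(unique(scan$predictions$protein_id[scan$predictions$call])))
  # MAPKs target S/T only: no tyrosines scanned
  expect_true(all(scan$predictions$residue %in% c("S", "T")))
  expect_true(all(scan$predictions$call == (scan$predictions$score >= 0.6)))

  # threshold above every score calls nothing
  hi <- proteome_scan(model, sub, tr, threshold = 1.01)
  expect_equal(hi$summary$n_sites, 0L)
  expect_equal(hi$summary$n_substrates, 0L)

  # counts invariant under input order permutation
  perm <- sample(nrow(sub))
  scan2 <- proteome_scan(model, sub[perm, ], tr, threshold = 0.6)
  expect_equal(scan2$summary, scan$summary)
  expect_equal(dplyr::arrange(scan2$predictions, protein_id, position),
               dplyr::arrange(scan$predictions, protein_id, position))
})
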