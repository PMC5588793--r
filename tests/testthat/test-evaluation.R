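test_that("confusion counts follow the ERRP-positive convention", {
  y <- rep(c("positive", "negative"), each = 5)
  expect_equal(confusion(y, y), c(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  flip <- ifelse(y == "positive", "negative", "positive")
  expect_equal(confusion(y, flip), c(TP = 0L, TN = 0L, FP = 5L, FN = 5L))
  expect_error(confusion(character(), character()),
               class = "erpred_input_error")
  expect_error(confusion(y, y[1:3]), class = "erpred_input_error")
  expect_error(confusion(y, rep("ERRP", 10)), class = "erpred_input_error")
})

test_that("metrics match their formulas on worked cases", {
  # 47 of 65 positives recovered: sensitivity 72.31% after rounding
  c1 <- c(TP = 47L, TN = 0L, FP = 0L, FN = 18L)
  expect_equal(round(sensitivity(c1), 2), 72.31)
  c2 <- c(TP = 5L, TN = 5L, FP = 5L, FN = 5L)
  expect_equal(mcc(c2), 0)
  expect_equal(accuracy(c2), 50)
  c3 <- c(TP = 10L, TN = 10L, FP = 0L, FN = 0L)
  expect_equal(mcc(c3), 1)
  expect_equal(accuracy(c3), 100)
  # undefined percentages are NA, degenerate MCC is 0
  expect_true(is.na(specificity(c1)))
  expect_equal(mcc(c1), 0)
})

test_that("metrics agree with a brute-force recount on random confusion tables", {
  set.seed(31)
  for (i in 1:1000) {
    k <- sample(0:200, 4, replace = TRUE)
    counts <- c(TP = k[1], TN = k[2], FP = k[3], FN = k[4])
    if (sum(counts) == 0) next
    want <- brute_metrics(k[1], k[2], k[3], k[4])
    expect_identical(is.na(sensitivity(counts)), is.na(want$sens))
    if (!is.na(want$sens)) expect_equal(sensitivity(counts), want$sens)
    if (!is.na(want$spec)) expect_equal(specificity(counts), want$spec)
    expect_equal(accuracy(counts), want$acc)
    expect_equal(mcc(counts), want$mcc, tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the pairwise rank statistic", {
  set.seed(32)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    labels <- c("positive", "negative",
                sample(c("positive", "negative"), n - 2, replace = TRUE))
    scores <- sample(round(rnorm(n), 1))  # coarse grid forces ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, rank_auc(scores, labels), tolerance = 1e-9)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  }
})

test_that("AUC edge behaviour: separation, sign reversal, null scores", {
  y <- rep(c("positive", "negative"), each = 50)
  s <- c(runif(50, 1, 2), runif(50, -2, -1))
  expect_equal(roc_auc(s, y)$auc, 1)
  expect_equal(roc_auc(-s, y)$auc, 0)
  set.seed(33)
  s2 <- rnorm(100)
  expect_equal(roc_auc(s2, y)$auc + roc_auc(-s2, y)$auc, 1, tolerance = 1e-12)
  y2 <- rep(c("positive", "negative"), each = 500)
  expect_equal(roc_auc(rnorm(1000), y2)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:5, rep("positive", 5)), class = "erpred_input_error")
})

test_that("LOOCV holds out each record once and recovers a separable dataset", {
  set.seed(34)
  rec <- generate_dataset(synth_config(n_pos = 25, n_neg = 75,
                                       length_range = c(51, 150),
                                       enrichment_bias = c(F = 3, R = 0.3),
                                       seed = 34))
  ev <- loocv(rec, svm_config("AAC"))
  expect_s3_class(ev, "erpred_eval")
  expect_equal(nrow(ev$predictions), 100L)
  expect_equal(ev$predictions$id, rec$id)
  expect_equal(sum(ev$counts), 100L)
  # strongly separable planted signal: near-perfect leave-one-out recovery
  expect_gte(ev$accuracy, 95)
  expect_gt(ev$roc$auc, 0.95)
  # metrics recompute exactly from the pooled counts
  expect_equal(ev$accuracy, accuracy(ev$counts))
  expect_equal(ev$mcc, mcc(ev$counts))
  expect_error(loocv(rec[rec$label == "negative", ], svm_config("AAC")),
               class = "erpred_input_error")
})

test_that("the non-support-vector shortcut reproduces naive leave-one-out", {
  set.seed(35)
  rec <- generate_dataset(synth_config(n_pos = 15, n_neg = 45,
                                       length_range = c(51, 120), seed = 35))
  fast <- loocv(rec, svm_config("AAC"))
  slow <- loocv(rec, svm_config("AAC"), exact = FALSE)
  expect_equal(fast$predictions$score, slow$predictions$score,
               tolerance = 1e-10)
  expect_identical(fast$counts, slow$counts)
})

test_that("evaluation report round-trips through TSV", {
  set.seed(36)
  rec <- generate_dataset(synth_config(n_pos = 10, n_neg = 20,
                                       length_range = c(51, 80), seed = 36))
  ev <- loocv(rec, svm_config("AAC"))
  f <- tempfile(fileext = ".tsv"); g <- tempfile(fileext = ".tsv")
  write_eval_tsv(ev, f, g)
  metrics <- read.delim(f)
  expect_equal(metrics$value[metrics$metric == "TP"], ev$counts[["TP"]])
  roc <- read.delim(g)
  expect_equal(nrow(roc), nrow(ev$roc$points))
})
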