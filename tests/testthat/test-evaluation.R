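test_that("confusion counts apply the threshold with ties to positive", {
  cc <- confusion_counts(c(1, 0), c(0.9, 0.1))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))

  cc2 <- confusion_counts(c(1, 0, 1), rep(0.5, 3))
  expect_equal(cc2$FP, 1L)          # everything predicted positive
  expect_equal(cc2$TP, 2L)

  cc3 <- confusion_counts(c(1, 1, 0, 0), c(0.4, 0.9, 0.6, 0.2))
  expect_equal(unclass(cc3)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  expect_error(confusion_counts(c(1, 0), 0.5), class = "pepattn_bad_shape")
})

test_that("metric formulas match hand calculations and handle degeneracy", {
  m <- compute_metrics(list(TP = 9, TN = 8, FP = 2, FN = 1))
  expect_equal(m$acc, 0.85)
  expect_equal(m$sens, 0.9)
  expect_equal(m$spec, 0.8)
  expect_equal(m$prec, 9 / 11)
  expect_equal(m$mcc, 70 / sqrt(9900), tolerance = 1e-12)

  perfect <- compute_metrics(list(TP = 5, TN = 7, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("acc", "sens", "spec", "prec", "mcc")]),
               c(acc = 1, sens = 1, spec = 1, prec = 1, mcc = 1))

  ## nothing predicted positive: precision (and mcc) get the 0 sentinel
  deg <- compute_metrics(list(TP = 0, TN = 6, FP = 0, FN = 4))
  expect_equal(deg$prec, 0)
  expect_true(all(c("prec", "mcc") %in% deg$degenerate))
  allpos <- compute_metrics(list(TP = 4, TN = 0, FP = 6, FN = 0))
  expect_true("spec" %in% allpos$degenerate || allpos$spec == 0)
})

test_that("metrics agree with the expanded-vector oracle", {
  set.seed(61)
  for (i in 1:200) {
    tab <- as.list(stats::setNames(sample(0:12, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    if (Reduce(`+`, tab) == 0) tab$TP <- 1
    got <- compute_metrics(tab)
    ref <- oracle_metrics(tab$TP, tab$TN, tab$FP, tab$FN)
    for (nm in c("acc", "sens", "spec", "prec", "mcc"))
      expect_equal(got[[nm]], ref[[nm]], tolerance = 1e-12)
    expect_gte(got$mcc, -1); expect_lte(got$mcc, 1)
  }
})

test_that("trapezoidal AUC matches rank statistics, pROC and invariances", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), class = "pepattn_single_class")

  set.seed(67)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    y <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    s <- if (i %% 2 == 0) round(stats::runif(n), 1) else stats::runif(n)
    r <- roc_auc(y, s)
    expect_equal(r$auc, oracle_auc_rank(y, s), tolerance = 1e-9)
    ## invariant under strictly monotone transforms of the scores
    expect_equal(roc_auc(y, qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)))$auc,
                 r$auc, tolerance = 1e-9)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(71)
    y <- sample(0:1, 80, replace = TRUE, prob = c(0.4, 0.6))
    s <- stats::runif(80) + 0.3 * y
    expect_equal(roc_auc(y, s)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-9)
  }
})

test_that("random balanced scores give MCC near zero on average", {
  set.seed(73)
  mccs <- replicate(300, {
    y <- rep(c(0, 1), 30)
    s <- stats::runif(60)
    compute_metrics(confusion_counts(y, s))$mcc
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("stratified folds preserve class balance and partition the data", {
  labels <- c(rep(1L, 129), rep(0L, 111))   # a 240-peptide benchmark layout
  folds <- stratified_kfold(labels, 5, seed = 3)
  expect_equal(sort(unlist(folds)), 1:240)
  expect_equal(vapply(folds, length, integer(1)), rep(48L, 5))
  pos_per_fold <- vapply(folds, function(f) sum(labels[f] == 1L), integer(1))
  expect_true(all(pos_per_fold %in% 25:26))

  expect_identical(folds, stratified_kfold(labels, 5, seed = 3))
  expect_false(identical(folds, stratified_kfold(labels, 5, seed = 4)))
  expect_error(stratified_kfold(c(1L, 1L, 0L), 2),
               class = "pepattn_small_class")
})

test_that("cross-validation learns the separable fixture and averages folds", {
  ds <- separable_fixture(160, seed = 17)
  cfg <- model_config(max_epochs = 8, patience = 8, val_fraction = 0,
                      seed = 5)
  cv <- cross_validate(ds, cfg, k = 2, seed = 9)
  expect_equal(vapply(cv$folds, function(f) f$fold_index, integer(1)), 1:2)
  expect_gte(cv$mean_metrics[["acc"]], 0.9)

  ## averages are plain arithmetic means over folds
  for (nm in c("acc", "sens", "spec", "prec", "mcc", "auc"))
    expect_equal(cv$mean_metrics[[nm]],
                 mean(vapply(cv$folds, function(f) f$metrics[[nm]],
                             numeric(1))),
                 tolerance = 1e-12)

  ## pooled scores cover every record exactly once
  expect_equal(sum(vapply(cv$folds, function(f) length(f$scores), integer(1))),
               160L)
  tab <- pepattn:::cv_tables(cv)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$fold[3], "Average")
})
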