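#' Confusion counts at a classification threshold
#'
#' Scores at or above the threshold are predicted positive (ties go to the
#' positive class).
#'
#' @param labels Binary vector in `{0, 1}`.
#' @param scores Probability vector of the same length.
#' @param threshold Decision threshold in `(0, 1)`; default 0.5.
#' @return Object of class `confusion_counts`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    pep_stop("labels and scores must have equal length", "pepattn_bad_shape")
  pred <- scores >= threshold
  pos <- labels == 1L
  structure(list(TP = sum(pred & pos), TN = sum(!pred & !pos),
                 FP = sum(pred & !pos), FN = sum(!pred & pos)),
            class = "confusion_counts")
}

#' Confusion-matrix classification metrics
#'
#' Computes accuracy, sensitivity, specificity, precision and the
#' Matthews correlation coefficient:
#' \deqn{Acc = (TP+TN)/(TP+FN+TN+FP)}
#' \deqn{Sens = TP/(TP+FN), \quad Spec = TN/(TN+FP), \quad Prec = TP/(TP+FP)}
#' \deqn{Mcc = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FN)(TN+FP)}}
#' Metrics with a zero denominator (e.g. precision with no predicted
#' positives) are returned as 0 with the `degenerate` field naming them.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return Object of class `metric_set`: list with `acc`, `sens`, `spec`,
#'   `prec`, `mcc`, `auc` (`NA` here; filled by ROC helpers), and
#'   `degenerate` (character vector of zero-denominator metrics).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total <= 0) pep_stop("empty confusion table", "pepattn_bad_shape")
  degenerate <- character()
  safe <- function(num, den, nm) {
    if (den == 0) { degenerate <<- c(degenerate, nm); return(0) }
    num / den
  }
  acc <- (TP + TN) / total
  sens <- safe(TP, TP + FN, "sens")
  spec <- safe(TN, TN + FP, "spec")
  prec <- safe(TP, TP + FP, "prec")
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FN)) * sqrt(as.numeric(TN + FP))
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 }
  else max(-1, min(1, (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den))
  structure(list(acc = acc, sens = sens, spec = spec, prec = prec,
                 mcc = mcc, auc = NA_real_, threshold = NA_real_,
                 degenerate = degenerate),
            class = "metric_set")
}

#' Evaluate scored predictions against labels
#'
#' Convenience wrapper: confusion counts at the threshold, the Eq.-style
#' metrics, and the ROC AUC in one object.
#'
#' @inheritParams confusion_counts
#' @return A `metric_set` with `auc` filled in (NA when only one class is
#'   present).
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  m <- compute_metrics(confusion_counts(labels, scores, threshold))
  m$threshold <- threshold
  if (length(unique(labels)) == 2L) m$auc <- roc_auc(labels, scores)$auc
  m
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Acc %.4f  Sens %.4f  Spec %.4f  Prec %.4f  Mcc %.4f  AUC %s\n",
              x$acc, x$sens, x$spec, x$prec, x$mcc,
              ifelse(is.na(x$auc), "-", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique scores (ties move their
#' points simultaneously) and integrates the ROC curve by the trapezoidal
#' rule.
#'
#' @param labels Binary vector with both classes present.
#' @param scores Numeric score vector.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    pep_stop("labels and scores must have equal length", "pepattn_bad_shape")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    pep_stop("ROC needs both classes present", "pepattn_single_class")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ## cumulative true/false positives at each unique threshold
  cum_tp <- cumsum(y == 1L)
  cum_fp <- cumsum(y == 0L)
  last <- cumsum(rle(s)$lengths)       # last index of each tie group
  tpr <- c(0, cum_tp[last] / npos)
  fpr <- c(0, cum_fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Stratified k-fold partition
#'
#' Shuffles each class separately (seeded) and deals its members
#' round-robin into k folds, so per-fold class proportions are within one
#' record of the global proportions.
#'
#' @param labels Binary label vector (or a `pep_dataset`).
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of `k` disjoint integer index vectors covering
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  if (inherits(labels, "pep_dataset")) labels <- labels$records$label
  k <- as.integer(k)
  for (cl in unique(labels))
    if (sum(labels == cl) < k)
      pep_stop(sprintf("class %s has fewer than k = %d members", cl, k),
               "pepattn_small_class")
  set.seed(seed)
  folds <- vector("list", k)
  totals <- rep(0L, k)
  ## per class: base count per fold, remainders dealt to the currently
  ## smallest folds so overall fold sizes also differ by at most one
  for (cl in unique(labels)) {
    ids <- sample(which(labels == cl))
    n_cl <- length(ids)
    cnt <- rep(n_cl %/% k, k)
    rem <- n_cl %% k
    if (rem > 0L) {
      extra <- order(totals)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    pos <- 0L
    for (f in seq_len(k)) {
      if (cnt[f] > 0L)
        folds[[f]] <- c(folds[[f]], ids[(pos + 1L):(pos + cnt[f])])
      pos <- pos + cnt[f]
    }
    totals <- totals + cnt
  }
  lapply(folds, sort)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' For each fold, trains a fresh model on the remaining k-1 folds (with
#' the configured internal validation split for early stopping) and
#' scores the held-out fold. Reports per-fold metrics, their unweighted
#' arithmetic means, and the pooled ROC over the concatenated held-out
#' scores (the headline AUC).
#'
#' @param dataset A labelled `pep_dataset`.
#' @param config A [model_config()].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold partition and per-fold training seeds.
#' @param max_len Padded length shared by all folds; `"auto"` = dataset
#'   maximum.
#' @return Object of class `pep_cv`: list with `folds` (per-fold
#'   `metric_set` plus scores/labels), `mean_metrics`, `pooled_auc`,
#'   `pooled_roc`, `k`, `seed`.
#' @export
cross_validate <- function(dataset, config, k = 5L, seed = 1L,
                           max_len = "auto") {
  labels <- dataset$records$label
  folds <- stratified_kfold(labels, k, seed)
  full_batch <- batch_encode(dataset, max_len = max_len)
  Lmax <- full_batch$max_len
  fold_results <- vector("list", k)
  pooled_scores <- numeric(0); pooled_labels <- integer(0)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    cfg_f <- config
    cfg_f$seed <- (config$seed + 7919L * f) %% 2147483647L
    model <- build_model(cfg_f, Lmax,
                         structure_available = full_batch$has_structure)
    model <- tryCatch(
      train_model(model, batch_subset(full_batch, train_idx)),
      error = function(e)
        pep_stop(sprintf("fold %d training failed: %s", f, conditionMessage(e)),
                 "pepattn_fold_failure"))
    scores <- predict_proba(model, batch_subset(full_batch, test_idx))
    m <- evaluate_predictions(labels[test_idx], scores)
    fold_results[[f]] <- list(fold_index = f, metrics = m,
                              scores = unname(scores),
                              labels = labels[test_idx])
    pooled_scores <- c(pooled_scores, unname(scores))
    pooled_labels <- c(pooled_labels, labels[test_idx])
  }
  nm <- c("acc", "sens", "spec", "prec", "mcc", "auc")
  mean_metrics <- sapply(nm, function(s)
    mean(vapply(fold_results, function(fr) fr$metrics[[s]], numeric(1))))
  pooled <- roc_auc(pooled_labels, pooled_scores)
  structure(list(folds = fold_results, mean_metrics = mean_metrics,
                 pooled_auc = pooled$auc, pooled_roc = pooled$points,
                 k = k, seed = seed),
            class = "pep_cv")
}

#' @export
print.pep_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("%-8s %7s %7s %7s %7s %7s %7s\n", "Fold", "Acc(%)", "Sens(%)",
              "Spec(%)", "Prec(%)", "Mcc(%)", "AUC"))
  for (fr in x$folds) {
    m <- fr$metrics
    cat(sprintf("%-8d %7.2f %7.2f %7.2f %7.2f %7.2f %7.3f\n", fr$fold_index,
                100 * m$acc, 100 * m$sens, 100 * m$spec, 100 * m$prec,
                100 * m$mcc, m$auc))
  }
  mm <- x$mean_metrics
  cat(sprintf("%-8s %7.2f %7.2f %7.2f %7.2f %7.2f %7.3f\n", "Average",
              100 * mm["acc"], 100 * mm["sens"], 100 * mm["spec"],
              100 * mm["prec"], 100 * mm["mcc"], mm["auc"]))
  cat(sprintf("Pooled held-out AUC: %.3f\n", x$pooled_auc))
  invisible(x)
}

## cross-validation result as data frames (for the CLI exports)
cv_tables <- function(cv) {
  rows <- lapply(cv$folds, function(fr) {
    m <- fr$metrics
    data.frame(fold = as.character(fr$fold_index),
               acc = 100 * m$acc, sens = 100 * m$sens, spec = 100 * m$spec,
               prec = 100 * m$prec, mcc = 100 * m$mcc, auc = m$auc)
  })
  tab <- do.call(rbind, rows)
  mm <- cv$mean_metrics
  tab <- rbind(tab, data.frame(fold = "Average", acc = 100 * mm[["acc"]],
                               sens = 100 * mm[["sens"]],
                               spec = 100 * mm[["spec"]],
                               prec = 100 * mm[["prec"]],
                               mcc = 100 * mm[["mcc"]], auc = mm[["auc"]]))
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, 2))
  tab
}
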