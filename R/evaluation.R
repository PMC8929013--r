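# Evaluation: confusion counts, SN/SP/ACC/MCC, stratified k-fold CV, the
# incremental-feature-selection baseline, and predictor diversity.

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that fold sizes differ by at
#' most one and each class's samples are spread as evenly as possible across
#' folds (class ratio preserved within +/- 1 sample).
#'
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Seed fixing the partition.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (min(table(labels)) < k)
    stopf("smallest class (%d) has fewer samples than k = %d",
          min(table(labels)), k)
  fold_id <- integer(length(labels))
  fold_tot <- integer(k)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n_cl <- length(idx)
      base <- n_cl %/% k
      extra <- n_cl %% k
      # spread the remainder onto the currently smallest folds so overall
      # fold sizes also stay within one of each other
      per_fold <- rep(base, k)
      if (extra > 0) {
        give <- order(fold_tot, seq_len(k))[seq_len(extra)]
        per_fold[give] <- per_fold[give] + 1L
      }
      fold_id[idx] <- rep(seq_len(k), times = per_fold)
      fold_tot <- fold_tot + per_fold
    }
  })
  fold_id
}

#' Confusion counts for binary site predictions
#'
#' @param predicted,truth Equal-length binary vectors (1 = pseudouridine
#'   site).
#' @return Object of class `confusion_counts`: list `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopf("predicted (%d) and truth (%d) lengths differ",
          length(predicted), length(truth))
  if (length(truth) == 0L) stopf("empty prediction vectors")
  structure(list(TP = sum(predicted == 1L & truth == 1L),
                 TN = sum(predicted == 0L & truth == 0L),
                 FP = sum(predicted == 1L & truth == 0L),
                 FN = sum(predicted == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy, and MCC
#'
#' `SN = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `ACC = (TP+TN)/total`, and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`. When any
#' factor of the MCC denominator is zero (one predicted or true class
#' absent), MCC is defined as 0; SN or SP is `NaN` when its own class is
#' absent.
#'
#' @param counts A [confusion_counts()] object (or list with TP/TN/FP/FN).
#' @return List with `SN`, `SP`, `ACC`, `MCC`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total == 0) stopf("all confusion counts are zero")
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  list(SN = tp / (tp + fn), SP = tn / (tn + fp),
       ACC = (tp + tn) / total, MCC = mcc)
}

#' Stratified k-fold cross-validation of a full training procedure
#'
#' Re-runs the supplied training procedure inside every training fold (so
#' label-derived steps such as PSKP fitting — and, if the trainer chooses,
#' BPSO selection — never see held-out windows) and pools the concatenated
#' out-of-fold predictions into one confusion table. Pooling (rather than
#' averaging per-fold metrics) keeps the estimates stable with small folds.
#'
#' @param dataset A `labeled_dataset`.
#' @param trainer Function `labeled_dataset -> function(sequences) -> 0/1
#'   labels`; everything label-dependent must happen inside it.
#' @param k Folds (default 10).
#' @param seed Seed for the partition.
#' @return List with `metrics` (pooled), `counts`, `fold_metrics` (per-fold
#'   list), `predictions` (out-of-fold labels in dataset order), `fold_id`.
#' @export
kfold_cv <- function(dataset, trainer, k = 10L, seed = 1L) {
  labels <- dataset$labels
  fold_id <- make_folds(labels, k, seed)
  pred <- integer(length(labels))
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test <- fold_id == f
    model <- trainer(subset_dataset(dataset, !test))
    p <- model(dataset$sequences[test])
    pred[test] <- p
    fold_metrics[[f]] <- compute_metrics(confusion_counts(p, labels[test]))
  }
  counts <- confusion_counts(pred, labels)
  list(metrics = compute_metrics(counts), counts = counts,
       fold_metrics = fold_metrics, predictions = pred, fold_id = fold_id)
}

# Per-feature one-way F statistic (two groups) for the IFS ranking.
feature_f_stat <- function(x, labels) {
  g1 <- labels == 1L
  n1 <- sum(g1); n0 <- sum(!g1); n <- n1 + n0
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  m <- colMeans(x)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((x[g1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[!g1, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f)] <- 0
  f
}

#' Incremental feature selection (IFS) baseline
#'
#' The greedy comparator to [run_bpso()]: features are ranked by a univariate
#' statistic (default: two-group F statistic), then the nested subsets of the
#' top `1, 2, ..., p` features are each scored by stratified k-fold CV
#' accuracy with `(C, gamma)` grid-searched over the supplied exponents; the
#' best-scoring subset wins.
#'
#' @param matrix Feature matrix.
#' @param labels Binary labels.
#' @param grid_exponents Integer exponents (base 2) searched for both C and
#'   gamma; defaults to a coarse sub-grid of the full `-16..15` range to keep
#'   the quadratic search affordable.
#' @param k CV folds.
#' @param seed Partition seed.
#' @param ranking Function `(matrix, labels) -> scores` (higher = better);
#'   default [feature_f_stat].
#' @return `selection_result` (with `fitness_history` the per-size accuracy
#'   curve) plus element `sizes`.
#' @export
ifs_baseline <- function(matrix, labels, grid_exponents = seq(-8L, 8L, 4L),
                         k = 10L, seed = 1L, ranking = feature_f_stat) {
  fold_id <- make_folds(labels, k, seed)
  fold_data <- build_fold_data(matrix, labels, fold_id)
  ord <- order(ranking(matrix, labels), decreasing = TRUE)
  p <- ncol(matrix)
  acc <- numeric(p)
  best <- vector("list", p)
  for (size in seq_len(p)) {
    mask <- integer(p)
    mask[ord[seq_len(size)]] <- 1L
    combos <- expand.grid(C = 2^grid_exponents, gamma = 2^grid_exponents)
    scores <- mapply(function(C, g) cv_accuracy(fold_data, mask, C, g),
                     combos$C, combos$gamma)
    j <- which.max(scores)
    acc[size] <- scores[j]
    best[[size]] <- list(mask = mask, C = combos$C[j], gamma = combos$gamma[j])
  }
  s <- which.max(acc)
  structure(list(feature_mask = best[[s]]$mask, C = best[[s]]$C,
                 gamma = best[[s]]$gamma, best_fitness = acc[s],
                 fitness_history = acc, n_features = p, position = NULL,
                 sizes = seq_len(p)),
            class = "selection_result")
}

#' Pearson correlation between base predictors
#'
#' Diversity diagnostic for the ensemble: the 6x6 Pearson correlation matrix
#' of the six base predictors' binary predictions on a common evaluation set.
#' Weak pairwise correlation is what makes majority voting effective.
#'
#' @param predictions Matrix or data frame, one column of 0/1 predictions per
#'   base predictor.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
predictor_correlation <- function(predictions) {
  x <- as.matrix(predictions)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stopf("constant predictions (correlation undefined) for: %s",
          paste(nm, collapse = ", "))
  }
  stats::cor(x)
}
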