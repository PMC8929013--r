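# Parallel fusion of the six per-descriptor base predictors by majority
# voting, plus the serial-fusion (feature concatenation) baseline.

#' Majority vote over the six base predictions
#'
#' The label with more than three of the six votes wins. A 3-3 tie is
#' resolved by `tie_rule`: `"margin"` (default) takes the sign of the summed
#' signed margins, falling back to positive when the sum is exactly zero;
#' `"positive"` always calls a tied window a site.
#'
#' @param votes Six binary labels.
#' @param decision_values Six signed margins (needed for `"margin"` ties).
#' @param tie_rule `"margin"` or `"positive"`.
#' @return Single binary label.
#' @export
majority_vote <- function(votes, decision_values = NULL,
                          tie_rule = c("margin", "positive")) {
  tie_rule <- match.arg(tie_rule)
  if (length(votes) != 6L) stopf("expected 6 votes, got %d", length(votes))
  s <- sum(votes)
  if (s > 3L) return(1L)
  if (s < 3L) return(0L)
  if (tie_rule == "positive") return(1L)
  if (is.null(decision_values) || length(decision_values) != 6L)
    stopf("margin tie rule needs the six decision values")
  total <- sum(decision_values)
  if (total > 0) 1L else if (total < 0) 0L else 1L
}

# Per-fold feature encodings for one descriptor: for the label-derived PSKP
# descriptor the propensity table is refitted on each training fold; other
# descriptors are encoded once and sliced.
encode_folds <- function(dataset, descriptor, fold_id, psednc) {
  labels <- dataset$labels
  if (descriptor == "PSKP") {
    lapply(sort(unique(fold_id)), function(f) {
      test <- fold_id == f
      tr <- subset_dataset(dataset, !test)
      tab <- fit_pskp(tr$sequences[tr$labels == 1L],
                      tr$sequences[tr$labels == 0L])
      list(train_x = encode_sequences(tr$sequences, "PSKP", pskp = tab),
           train_y = tr$labels,
           test_x = encode_sequences(dataset$sequences[test], "PSKP",
                                     pskp = tab),
           test_y = labels[test])
    })
  } else {
    x <- encode_sequences(dataset$sequences, descriptor, psednc = psednc)
    build_fold_data(x, labels, fold_id)
  }
}

#' Train the six-descriptor voting ensemble
#'
#' For each of the six descriptors: encode the training windows, run the BPSO
#' joint feature/hyperparameter search (the PSKP propensity table is refitted
#' inside every fitness-CV training fold), and train the base RBF-SVM on the
#' winning subset. The six base predictors are then fused by majority vote.
#' One master seed derives all per-descriptor seeds.
#'
#' @param dataset A `labeled_dataset`.
#' @param bpso A [bpso_config()] shared by the six searches (each gets its
#'   own derived `random_seed`).
#' @param psednc A [psednc_config()].
#' @param descriptors The six descriptor names; exactly six pairwise-distinct
#'   names are required.
#' @param tie_rule Tie policy for [majority_vote()].
#' @param seed Master seed.
#' @return Object of class `ensemble_predictor` with the six
#'   `base_predictors` and their `selections`.
#' @export
train_ensemble <- function(dataset, bpso = bpso_config(),
                           psednc = psednc_config(),
                           descriptors = DESCRIPTORS,
                           tie_rule = c("margin", "positive"), seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  descriptors <- toupper(descriptors)
  if (length(descriptors) != 6L || anyDuplicated(descriptors))
    stopf("exactly six pairwise-distinct descriptors are required")
  seeds <- derive_seeds(seed, length(descriptors))
  base_predictors <- list()
  selections <- list()
  for (i in seq_along(descriptors)) {
    d <- descriptors[i]
    cfg <- bpso
    cfg$random_seed <- seeds[i]
    fold_id <- make_folds(dataset$labels, cfg$cv_folds, cfg$random_seed)
    fold_data <- encode_folds(dataset, d, fold_id, psednc)
    pskp_full <- if (d == "PSKP")
      fit_pskp(dataset$sequences[dataset$labels == 1L],
               dataset$sequences[dataset$labels == 0L])
    x <- encode_sequences(dataset$sequences, d, pskp = pskp_full,
                          psednc = psednc)
    sel <- run_bpso(x, dataset$labels, cfg, fold_data = fold_data)
    selections[[d]] <- sel
    base_predictors[[d]] <- train_base_predictor(dataset, d, sel, psednc)
  }
  structure(list(base_predictors = base_predictors, selections = selections,
                 tie_rule = tie_rule,
                 window_length = dataset$window_length,
                 seed = seed, schema_version = "pseuvote-ensemble-1"),
            class = "ensemble_predictor")
}

#' @export
print.ensemble_predictor <- function(x, ...) {
  cat(sprintf("ensemble_predictor: 6 base predictors, window %d nt, tie rule '%s'\n",
              x$window_length, x$tie_rule))
  for (d in names(x$base_predictors)) {
    bp <- x$base_predictors[[d]]
    cat(sprintf("  %-7s %4d/%4d features, C = 2^%g, gamma = 2^%g\n",
                d, sum(bp$feature_mask), length(bp$feature_mask),
                log2(bp$C), log2(bp$gamma)))
  }
  invisible(x)
}

#' Predict with the voting ensemble
#'
#' @param ensemble An `ensemble_predictor`.
#' @param sequences Named character vector of residue strings of the training
#'   window length.
#' @return Data frame with `seq_id`, the fused `label`, six `vote_*` columns
#'   and six `dv_*` signed-margin columns (one pair per descriptor).
#' @export
predict_ensemble <- function(ensemble, sequences) {
  stopifnot(inherits(ensemble, "ensemble_predictor"))
  descs <- names(ensemble$base_predictors)
  if (length(sequences) == 0L) {
    out <- data.frame(seq_id = character(0), label = integer(0))
    for (d in descs) out[[paste0("vote_", tolower(d))]] <- integer(0)
    for (d in descs) out[[paste0("dv_", tolower(d))]] <- numeric(0)
    return(out)
  }
  base <- lapply(ensemble$base_predictors, predict_base, sequences = sequences)
  votes <- sapply(base, function(b) b$label)
  dvs <- sapply(base, function(b) b$decision_value)
  if (length(sequences) == 1L) {
    votes <- matrix(votes, nrow = 1L, dimnames = list(NULL, descs))
    dvs <- matrix(dvs, nrow = 1L, dimnames = list(NULL, descs))
  }
  label <- vapply(seq_along(sequences), function(i)
    majority_vote(votes[i, ], dvs[i, ], ensemble$tie_rule), integer(1))
  out <- data.frame(seq_id = seq_ids(sequences), label = label,
                    row.names = NULL)
  for (d in descs) out[[paste0("vote_", tolower(d))]] <- votes[, d]
  for (d in descs) out[[paste0("dv_", tolower(d))]] <- dvs[, d]
  out
}

#' Serial-fusion baseline: concatenate the six selected subsets
#'
#' The comparison strategy to parallel fusion: the six masked feature blocks
#' are concatenated into one matrix and a single RBF-SVM is retrained on it,
#' with `(C, gamma)` grid-searched by stratified k-fold CV. Shipped as a
#' baseline only; the voting ensemble is the supported path.
#'
#' @param dataset A `labeled_dataset`.
#' @param selections Named list of six `selection_result`s (names =
#'   descriptors). An empty mask is repaired by activating one random bit.
#' @param psednc A [psednc_config()].
#' @param grid_exponents Exponents (base 2) searched for C and gamma.
#' @param k CV folds.
#' @param seed Partition / repair seed.
#' @return Object of class `serial_predictor`: the fitted SVM, `cv_acc`,
#'   `C`, `gamma`, and the concatenated dimension `dim`.
#' @export
serial_fusion_baseline <- function(dataset, selections,
                                   psednc = psednc_config(),
                                   grid_exponents = seq(-8L, 8L, 4L),
                                   k = 10L, seed = 1L) {
  descs <- names(selections)
  if (length(descs) != 6L) stopf("six selections are required")
  pskp_full <- fit_pskp(dataset$sequences[dataset$labels == 1L],
                        dataset$sequences[dataset$labels == 0L])
  blocks <- lapply(descs, function(d) {
    x <- encode_sequences(dataset$sequences, d, pskp = pskp_full,
                          psednc = psednc)
    mask <- with_seed(seed, repair_mask(selections[[d]]$feature_mask,
                                        ncol(x)))
    x[, which(mask == 1L), drop = FALSE]
  })
  x <- do.call(cbind, blocks)
  fold_id <- make_folds(dataset$labels, k, seed)
  fold_data <- build_fold_data(x, dataset$labels, fold_id)
  combos <- expand.grid(C = 2^grid_exponents, gamma = 2^grid_exponents)
  scores <- mapply(function(C, g)
    cv_accuracy(fold_data, rep(1L, ncol(x)), C, g), combos$C, combos$gamma)
  j <- which.max(scores)
  fit <- e1071::svm(x = x, y = factor(dataset$labels, levels = c(0L, 1L)),
                    kernel = "radial", cost = combos$C[j],
                    gamma = combos$gamma[j], scale = FALSE)
  structure(list(model = fit, cv_acc = scores[j], C = combos$C[j],
                 gamma = combos$gamma[j], dim = ncol(x)),
            class = "serial_predictor")
}

#' Save / load an ensemble archive
#'
#' Single-file persistence of the six base-model payloads, fitted tables,
#' tie rule and schema version.
#'
#' @param ensemble An `ensemble_predictor`.
#' @param path Archive path.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble_predictor"))
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  ensemble <- readRDS(path)
  if (!inherits(ensemble, "ensemble_predictor"))
    stopf("%s is not an ensemble archive", path)
  ensemble
}

#' Cross-validate the ensemble against its six base predictors
#'
#' Stratified k-fold comparison harness: inside every training fold the six
#' base predictors are retrained (the PSKP propensity table refitted on that
#' fold's training windows) with the supplied, fixed selections; out-of-fold
#' predictions are pooled into one confusion table per base predictor and one
#' for the majority-vote ensemble. This is the ensemble-gain experiment:
#' with heterogeneous, weakly correlated base predictors the fused accuracy
#' should sit at or above the middle of the base-predictor field.
#'
#' @param dataset A `labeled_dataset`.
#' @param selections Named list of six `selection_result`s (one per
#'   descriptor).
#' @param psednc A [psednc_config()].
#' @param tie_rule Tie policy for [majority_vote()].
#' @param k Folds.
#' @param seed Partition seed.
#' @return List with `ensemble` (pooled metrics), `base` (named list of
#'   pooled metrics per descriptor), `votes` (out-of-fold 0/1 matrix, one
#'   column per descriptor), `predictions` (fused labels), `fold_id`.
#' @export
ensemble_cv <- function(dataset, selections, psednc = psednc_config(),
                        tie_rule = c("margin", "positive"), k = 10L,
                        seed = 1L) {
  tie_rule <- match.arg(tie_rule)
  descs <- names(selections)
  if (length(descs) != 6L) stopf("six selections are required")
  labels <- dataset$labels
  fold_id <- make_folds(labels, k, seed)
  n <- length(labels)
  votes <- matrix(NA_integer_, n, 6L, dimnames = list(NULL, descs))
  dvs <- matrix(NA_real_, n, 6L, dimnames = list(NULL, descs))
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    train <- subset_dataset(dataset, !test)
    for (d in descs) {
      bp <- train_base_predictor(train, d, selections[[d]], psednc)
      pr <- predict_base(bp, dataset$sequences[test])
      votes[test, d] <- pr$label
      dvs[test, d] <- pr$decision_value
    }
  }
  fused <- vapply(seq_len(n), function(i)
    majority_vote(votes[i, ], dvs[i, ], tie_rule), integer(1))
  list(
    ensemble = compute_metrics(confusion_counts(fused, labels)),
    base = stats::setNames(lapply(descs, function(d)
      compute_metrics(confusion_counts(votes[, d], labels))), descs),
    votes = votes, predictions = fused, fold_id = fold_id)
}
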