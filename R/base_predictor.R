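# One RBF-kernel SVM per feature descriptor, trained on its BPSO-selected
# feature subset. Fitted label-derived artifacts (the PSKP propensity table)
# and the PseDNC configuration travel inside the predictor so that
# prediction-time encoding is self-contained.

# Encode a vector of residue strings with a descriptor and fitted artifacts.
encode_sequences <- function(sequences, descriptor, pskp = NULL,
                             psednc = NULL) {
  enc <- switch(descriptor,
    ONEHOT = encode_one_hot,
    KMER   = encode_kmer,
    KD     = encode_kd,
    NCP    = encode_ncp,
    PSKP   = function(s) encode_pskp(s, pskp),
    PSEDNC = function(s) encode_psednc(s, if (is.null(psednc))
      psednc_config() else psednc))
  x <- do.call(rbind, lapply(sequences, enc))
  rownames(x) <- seq_ids(sequences)
  x
}

#' Train a base predictor for one descriptor
#'
#' Fits an RBF-kernel SVM on the BPSO-selected columns of the descriptor's
#' encoding of the full training set, with the `(C, gamma)` pair decoded from
#' the winning particle. For the PSKP descriptor the propensity table is
#' fitted here, on the supplied (training) dataset.
#'
#' @param dataset A `labeled_dataset` (1 = pseudouridine site).
#' @param descriptor Descriptor name (see [encode_dataset()]).
#' @param selection A `selection_result` produced on the same descriptor and
#'   window length.
#' @param psednc A [psednc_config()] (used by the PSEDNC descriptor).
#' @return Object of class `base_predictor`.
#' @export
train_base_predictor <- function(dataset, descriptor, selection,
                                 psednc = psednc_config()) {
  descriptor <- match.arg(toupper(descriptor), DESCRIPTORS)
  pskp <- if (descriptor == "PSKP")
    fit_pskp(dataset$sequences[dataset$labels == 1L],
             dataset$sequences[dataset$labels == 0L])
  x <- encode_sequences(dataset$sequences, descriptor, pskp, psednc)
  if (length(selection$feature_mask) != ncol(x))
    stopf("mask length %d does not match %s dimensionality %d",
          length(selection$feature_mask), descriptor, ncol(x))
  cols <- which(selection$feature_mask == 1L)
  if (length(cols) == 0L) stopf("selection has an empty feature mask")
  fit <- e1071::svm(x = x[, cols, drop = FALSE],
                    y = factor(dataset$labels, levels = c(0L, 1L)),
                    kernel = "radial", cost = selection$C,
                    gamma = selection$gamma, scale = FALSE)
  structure(list(descriptor = descriptor,
                 feature_mask = selection$feature_mask,
                 C = selection$C, gamma = selection$gamma,
                 model = fit, fitted_pskp = pskp, fitted_psednc = psednc,
                 window_length = dataset$window_length,
                 feature_names = colnames(x)[cols],
                 schema_version = "pseuvote-base-1"),
            class = "base_predictor")
}

#' Predict with one base predictor
#'
#' @param predictor A `base_predictor`.
#' @param sequences Named character vector of residue strings, each of the
#'   predictor's training window length.
#' @return Data frame with `seq_id`, `label` (1 iff the signed margin is
#'   positive toward the pseudouridine class), and `decision_value` (the
#'   margin, oriented so positive means pseudouridine).
#' @export
predict_base <- function(predictor, sequences) {
  stopifnot(inherits(predictor, "base_predictor"))
  if (length(sequences) == 0L)
    return(data.frame(seq_id = character(0), label = integer(0),
                      decision_value = numeric(0)))
  lens <- nchar(sequences)
  if (any(lens != predictor$window_length))
    stopf("sequences with length != training window %d: %s",
          predictor$window_length,
          paste(seq_ids(sequences)[lens != predictor$window_length],
                collapse = ", "))
  x <- encode_sequences(sequences, predictor$descriptor,
                        predictor$fitted_pskp, predictor$fitted_psednc)
  cols <- which(predictor$feature_mask == 1L)
  pred <- stats::predict(predictor$model, x[, cols, drop = FALSE],
                         decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients the margin toward the first class in its own label order;
  # re-orient so positive always means the pseudouridine class ("1").
  positive_class <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  margin <- if (positive_class == "1") dv[, 1L] else -dv[, 1L]
  data.frame(seq_id = seq_ids(sequences), label = as.integer(margin > 0),
             decision_value = unname(margin), row.names = NULL)
}
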