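#!/usr/bin/env Rscript
# Full-scale benchmark harness. Reproducing the published cross-validation
# and independent-test scores requires the externally distributed benchmark
# FASTA files (U-centered windows, positive and negative) and the full-scale
# search (80 particles x 300 iterations, phase switch at 200), i.e. hours of
# compute; nothing here runs as part of the desk-scale tests.
#
# Usage:
#   Rscript scripts/benchmark_fullscale.R \
#     --pos positives.fasta --neg negatives.fasta --out results/ \
#     [--seed 1] [--test-pos t_pos.fasta --test-neg t_neg.fasta]

suppressPackageStartupMessages(library(pseuvote))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
pos <- get_arg("--pos"); neg <- get_arg("--neg")
if (is.null(pos) || is.null(neg))
  stop("--pos and --neg FASTA files are required", call. = FALSE)
out_dir <- get_arg("--out", "results")
seed <- as.integer(get_arg("--seed", "1"))
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

dataset <- read_labeled_fasta(pos, neg)
message(sprintf("loaded %d windows of %d nt",
                length(dataset$sequences), dataset$window_length))

cfg <- bpso_config(random_seed = seed)  # full-scale defaults: 80 x 300 / 200
ens <- train_ensemble(dataset, bpso = cfg, seed = seed)
save_ensemble(ens, file.path(out_dir, "ensemble.rds"))
for (d in names(ens$selections))
  write_selection(ens$selections[[d]],
                  file.path(out_dir, paste0(tolower(d), ".selection.tsv")))

cv <- ensemble_cv(dataset, ens$selections, k = 10, seed = seed)
tab <- rbind(
  data.frame(predictor = "ensemble", t(unlist(cv$ensemble))),
  do.call(rbind, lapply(names(cv$base), function(d)
    data.frame(predictor = d, t(unlist(cv$base[[d]]))))))
utils::write.table(tab, file.path(out_dir, "cv_metrics.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

r <- predictor_correlation(cv$votes)
utils::write.table(round(r, 4), file.path(out_dir, "diversity_corr.tsv"),
                   sep = "\t", quote = FALSE)

test_pos <- get_arg("--test-pos"); test_neg <- get_arg("--test-neg")
if (!is.null(test_pos) && !is.null(test_neg)) {
  test <- read_labeled_fasta(test_pos, test_neg,
                             window_length = dataset$window_length)
  pred <- predict_ensemble(ens, test$sequences)
  m <- compute_metrics(confusion_counts(pred$label, test$labels))
  utils::write.table(data.frame(metric = names(m), value = unlist(m)),
                     file.path(out_dir, "independent_test_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("independent test: ACC %.3f MCC %.3f SN %.3f SP %.3f",
                  m$ACC, m$MCC, m$SN, m$SP))
}
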