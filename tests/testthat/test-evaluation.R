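test_that("confusion counts match a per-element counting oracle", {
  cc <- confusion_counts(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_identical(unlist(cc[c("TP", "TN", "FP", "FN")]),
                   c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(0, 1, 0, 1), c(1, 0, 1, 0))
  expect_identical(cc$TP + cc$TN, 0L)
  set.seed(10)
  for (rep in 1:5) {
    p <- rbinom(50, 1, 0.5); t <- rbinom(50, 1, 0.5)
    cc <- confusion_counts(p, t)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in 1:50) {
      if (p[i] == 1 && t[i] == 1) tp <- tp + 1
      if (p[i] == 0 && t[i] == 0) tn <- tn + 1
      if (p[i] == 1 && t[i] == 0) fp <- fp + 1
      if (p[i] == 0 && t[i] == 1) fn <- fn + 1
    }
    expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
                 c(TP = tp, TN = tn, FP = fp, FN = fn))
    expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 50L)
  }
  expect_error(confusion_counts(c(1, 0), c(1)), "lengths differ")
})

test_that("metric formulas and degenerate conventions are exact", {
  m <- compute_metrics(list(TP = 2, TN = 2, FP = 0, FN = 0))
  expect_identical(unlist(m), c(SN = 1, SP = 1, ACC = 1, MCC = 1))
  m <- compute_metrics(list(TP = 3, TN = 2, FN = 1, FP = 2))
  expect_equal(m$ACC, 5 / 8)
  m <- compute_metrics(list(TP = 0, TN = 4, FP = 0, FN = 0))
  expect_identical(m$SP, 1)
  expect_identical(m$MCC, 0)
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "all confusion counts are zero")

  set.seed(11)
  for (rep in 1:200) {
    cc <- list(TP = rpois(1, 20), TN = rpois(1, 20),
               FP = rpois(1, 10), FN = rpois(1, 10))
    if (sum(unlist(cc)) == 0) next
    m <- compute_metrics(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    if (P > 0 && N > 0) {
      expect_equal(m$ACC, (m$SN * P + m$SP * N) / (P + N))
      expect_true(m$MCC >= -1 && m$MCC <= 1)
      if (cc$FP == 0 && cc$FN == 0) expect_equal(m$MCC, 1)
      if (m$MCC == 1) expect_true(cc$FP == 0 && cc$FN == 0)
    }
  }
})

test_that("stratified folds balance size and class ratio", {
  labels <- c(rep(1, 33), rep(0, 27))
  fid <- make_folds(labels, 10, seed = 2)
  sizes <- table(fid)
  expect_lte(max(sizes) - min(sizes), 1)
  per_class <- table(fid, labels)
  expect_lte(max(per_class[, "1"]) - min(per_class[, "1"]), 1)
  expect_lte(max(per_class[, "0"]) - min(per_class[, "0"]), 1)
  expect_error(make_folds(c(rep(1, 5), rep(0, 20)), 10), "fewer samples")
})

test_that("cross-validation pools out-of-fold predictions correctly", {
  ds <- separable_dataset(n_per_class = 20, lambda = 11)
  sel <- structure(list(feature_mask = rep(1L, descriptor_dim("ONEHOT", 11)),
                        C = 8, gamma = 0.05),
                   class = "selection_result")
  trainer <- function(train_ds) {
    bp <- train_base_predictor(train_ds, "ONEHOT", sel)
    function(seqs) predict_base(bp, seqs)$label
  }
  cv <- kfold_cv(ds, trainer, k = 10, seed = 3)
  expect_equal(cv$metrics$ACC, 1.0)
  expect_identical(cv$counts$TP + cv$counts$TN + cv$counts$FP + cv$counts$FN,
                   40L)
  cv2 <- kfold_cv(ds, trainer, k = 10, seed = 3)
  expect_identical(cv$predictions, cv2$predictions)

  # permutation null: shuffled labels give chance-level pooled accuracy
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    shuffled <- ds
    shuffled$labels <- sample(ds$labels)
    kfold_cv(shuffled, function(tr) {
      bp <- train_base_predictor(tr, "ONEHOT", sel)
      function(seqs) predict_base(bp, seqs)$label
    }, k = 10, seed = s)$metrics$ACC
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("the IFS baseline evaluates nested subsets deterministically", {
  fx <- generate_feature_fixture(n = 50, n_informative = 2, n_noise = 6,
                                 effect_size = 2, seed = 12)
  sel <- ifs_baseline(fx$x, fx$labels, grid_exponents = c(-2, 2), k = 5,
                      seed = 4)
  expect_identical(sel$sizes, 1:8)
  expect_length(sel$fitness_history, 8)
  expect_identical(sum(sel$feature_mask),
                   which.max(sel$fitness_history))
  sel2 <- ifs_baseline(fx$x, fx$labels, grid_exponents = c(-2, 2), k = 5,
                       seed = 4)
  expect_identical(sel$feature_mask, sel2$feature_mask)
  # the strongly informative planted pair should rank at the top
  expect_true(all(fx$informative %in%
                    which(sel$feature_mask == 1L) |
                    sum(sel$feature_mask) < 2))
})

test_that("predictor correlation is Pearson's r with guarded degeneracy", {
  v <- rbinom(40, 1, 0.5)
  m <- cbind(a = v, b = v, c = 1 - v)
  r <- predictor_correlation(m)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))

  set.seed(13)
  x <- rbinom(200, 1, 0.5); y <- rbinom(200, 1, 0.5)
  r <- predictor_correlation(cbind(x = x, y = y))["x", "y"]
  num <- mean(x * y) - mean(x) * mean(y)
  den <- sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(r, num / den, tolerance = 1e-12)
  expect_error(predictor_correlation(cbind(ok = x, flat = rep(1, 200))),
               "flat")
})
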