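# Shared fixtures, built in code at test time.

NUC4 <- c("A", "U", "C", "G")

random_rna <- function(n, lambda, seed = 1, center_u = FALSE) {
  set.seed(seed)
  out <- vapply(seq_len(n), function(i) {
    ch <- sample(NUC4, lambda, replace = TRUE)
    if (center_u) ch[(lambda + 1) %/% 2] <- "U"
    paste(ch, collapse = "")
  }, character(1))
  names(out) <- paste0("r", seq_len(n))
  out
}

# A deterministic, perfectly separable window dataset: positives carry A at
# the first four positions, negatives carry C there; the rest is random
# background with a forced center U.
separable_dataset <- function(n_per_class = 30, lambda = 11, seed = 7) {
  set.seed(seed)
  mk <- function(tag, fill) {
    out <- vapply(seq_len(n_per_class), function(i) {
      ch <- sample(NUC4, lambda, replace = TRUE)
      ch[1:4] <- fill
      ch[(lambda + 1) %/% 2] <- "U"
      paste(ch, collapse = "")
    }, character(1))
    names(out) <- paste0(tag, seq_len(n_per_class))
    out
  }
  validate_dataset(mk("p", "A"), mk("n", "C"), lambda)
}

# Tiny BPSO settings for smoke-scale searches in unit tests.
tiny_bpso <- function(seed = 1, folds = 5) {
  bpso_config(n_particles = 5L, n_iterations = 3L,
              phase_switch_iteration = 2L, cv_folds = folds,
              random_seed = seed)
}

# One small trained ensemble, built once per test session and reused by the
# ensemble, scanner and CLI tests.
.cache <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(.cache$fx)) {
    .cache$fx <- generate_dataset(fixture_spec(
      n_pos = 40L, n_neg = 40L, window_length = 11L,
      signal_positions = c(2L, 4L, 8L, 10L), signal_strength = 0.7,
      seed = 303L))
  }
  .cache$fx
}

tiny_ensemble <- function() {
  if (is.null(.cache$ens)) {
    .cache$ens <- train_ensemble(tiny_fixture()$dataset,
                                 bpso = tiny_bpso(11), seed = 11L)
  }
  .cache$ens
}
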