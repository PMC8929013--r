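# Internal helpers shared across modules.

# Canonical nucleotide order used by every encoder and table: the order the
# bases are enumerated throughout the package is A, U, C, G, and dinucleotides
# are the 16 lexicographic pairs over that order (AA, AU, AC, AG, UA, ..., GG).
NUC <- c("A", "U", "C", "G")
DINUC <- paste0(rep(NUC, each = 4L), rep(NUC, times = 4L))

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (single-knob
# reproducibility for multi-stage pipelines). Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Split residue string into a character vector, with basic validation.
residue_chars <- function(seq) {
  if (is.list(seq)) seq <- seq$residues
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

seq_ids <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  ids
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
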