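#' Read and normalize RNA sequences from a FASTA file
#'
#' Parses a (multi-record, wrapped or single-line) FASTA file and returns the
#' records as a named character vector of normalized RNA residues: uppercase,
#' with `T` mapped to `U` (DNA-alphabet copies of RNA datasets are common).
#' Any residue outside `{A,C,G,U,T}` (either case) is rejected — the feature
#' encoders are defined only over the four-letter RNA alphabet, so ambiguity
#' codes such as `N` are an error, not imputed.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector; names are the FASTA identifiers (first
#'   whitespace-delimited token of each header), values the normalized
#'   residue strings.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "augcu", ">s2", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stopf("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  raw <- as.character(set)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stopf("FASTA record with empty header in %s", path)
  out <- vapply(raw, normalize_sequence, character(1), USE.NAMES = FALSE)
  names(out) <- ids
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param sequences Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(unname(sequences))
  names(set) <- seq_ids(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Normalize a raw RNA/DNA sequence string
#'
#' Strips whitespace, uppercases, and maps `T` to `U`. Characters outside the
#' `{A,C,G,U,T}` alphabet raise an error naming the offending character and
#' its (1-based) position in the cleaned string.
#'
#' @param raw Character scalar.
#' @return Normalized residue string over `{A,C,G,U}`.
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(gsub("\\s+", "", raw))
  if (!nzchar(s)) stopf("empty sequence after whitespace removal")
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGU]", s)
  if (bad > 0L)
    stopf("invalid residue '%s' at position %d (alphabet is A, C, G, U/T)",
          substr(s, bad, bad), bad)
  s
}

#' Assemble a labeled U-centered window dataset
#'
#' Merges positive (pseudouridine site) and negative windows into one labeled
#' dataset, enforcing the structural invariants of the classification unit:
#' every window has the same odd length `window_length` and carries `U` at its
#' center position `(window_length + 1) / 2` (1-based).
#'
#' @param pos,neg Named character vectors of normalized residue strings
#'   (e.g. from [read_fasta()]).
#' @param window_length Odd window length (the benchmark datasets in this
#'   field use 21 or 31 nt).
#' @return An object of class `labeled_dataset`: list with `sequences`
#'   (named character vector), `labels` (integer, 1 = pseudouridine site),
#'   and `window_length`.
#' @export
validate_dataset <- function(pos, neg, window_length) {
  if (length(pos) == 0L || length(neg) == 0L)
    stopf("both positive and negative sets must be non-empty")
  window_length <- as.integer(window_length)
  if (window_length %% 2L == 0L)
    stopf("window_length must be odd (got %d); a window needs a center U",
          window_length)
  sequences <- c(pos, neg)
  names(sequences) <- make.unique(seq_ids(sequences), sep = "_dup")
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))

  lens <- nchar(sequences)
  if (any(lens != window_length))
    stopf("sequences with length != %d: %s", window_length,
          paste(names(sequences)[lens != window_length], collapse = ", "))
  center <- (window_length + 1L) %/% 2L
  ctr <- substr(sequences, center, center)
  if (any(ctr != "U"))
    stopf("sequences without U at center position %d: %s", center,
          paste(names(sequences)[ctr != "U"], collapse = ", "))

  structure(
    list(sequences = sequences, labels = labels, window_length = window_length),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "labeled_dataset: %d windows of %d nt (%d positive / %d negative)\n",
    length(x$sequences), x$window_length, sum(x$labels), sum(1L - x$labels)))
  invisible(x)
}

#' Read a labeled dataset from two FASTA files
#'
#' Convenience wrapper over [read_fasta()] and [validate_dataset()]: one FASTA
#' of pseudouridine-site windows and one of non-site windows.
#'
#' @param pos_path,neg_path FASTA paths for positive and negative windows.
#' @param window_length Expected odd window length; if `NULL`, taken from the
#'   first positive record.
#' @return A `labeled_dataset`.
#' @export
read_labeled_fasta <- function(pos_path, neg_path, window_length = NULL) {
  pos <- read_fasta(pos_path)
  neg <- read_fasta(neg_path)
  if (is.null(window_length)) window_length <- nchar(pos[[1L]])
  validate_dataset(pos, neg, window_length)
}

# Subset a labeled_dataset by index, keeping the class invariants.
subset_dataset <- function(dataset, idx) {
  structure(
    list(sequences = dataset$sequences[idx],
         labels = dataset$labels[idx],
         window_length = dataset$window_length),
    class = "labeled_dataset"
  )
}
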