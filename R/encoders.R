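# Six sequence feature descriptors for U-centered RNA windows.
#
# All encoders share one canonical ordering: nucleotides A, U, C, G and the
# 16 dinucleotides in lexicographic order over that alphabet (AA, AU, AC, AG,
# UA, ..., GG). Dimensionality contracts for a window of length lambda:
#   one-hot 20*lambda - 16; k-mer 20; KD 2*lambda - 1; NCP 3*lambda;
#   PSKP 2*lambda - 1; PseDNC 16 + lambda_pse.

DESCRIPTORS <- c("ONEHOT", "KMER", "KD", "PSEDNC", "PSKP", "NCP")

mono_index <- function(chars) match(chars, NUC)
di_index <- function(chars) {
  n <- length(chars)
  match(paste0(chars[-n], chars[-1L]), DINUC)
}

#' One-hot encoding of a U-centered window
#'
#' Indicator encoding of each mononucleotide (4 bits per position, order
#' A, U, C, G) followed by each overlapping dinucleotide (16 bits per
#' position), giving a `20*lambda - 16` dimensional 0/1 vector for a window
#' of length `lambda`. Exactly one bit is set in every block.
#'
#' @param seq Residue string over `{A,C,G,U}`.
#' @return Named numeric vector of length `20 * nchar(seq) - 16`.
#' @examples
#' encode_one_hot("AU")
#' @export
encode_one_hot <- function(seq) {
  chars <- residue_chars(seq)
  lambda <- length(chars)
  mono <- matrix(0, nrow = 4L, ncol = lambda)
  mono[cbind(mono_index(chars), seq_len(lambda))] <- 1
  out <- as.vector(mono)
  names(out) <- paste0("oh_p", rep(seq_len(lambda), each = 4L), "_", NUC)
  if (lambda >= 2L) {
    di <- matrix(0, nrow = 16L, ncol = lambda - 1L)
    di[cbind(di_index(chars), seq_len(lambda - 1L))] <- 1
    div <- as.vector(di)
    names(div) <- paste0("oh_d", rep(seq_len(lambda - 1L), each = 16L), "_", DINUC)
    out <- c(out, div)
  }
  out
}

#' k-mer nucleotide frequencies (k = 1, 2)
#'
#' The 4 mononucleotide frequencies (counts / lambda) followed by the 16
#' dinucleotide frequencies (counts / (lambda - 1)); always 20-dimensional.
#'
#' @param seq Residue string, length >= 2.
#' @return Named numeric vector of length 20; each of the two frequency
#'   groups sums to 1.
#' @export
encode_kmer <- function(seq) {
  chars <- residue_chars(seq)
  lambda <- length(chars)
  if (lambda < 2L) stopf("k-mer encoding needs length >= 2 (got %d)", lambda)
  mono <- tabulate(mono_index(chars), 4L) / lambda
  di <- tabulate(di_index(chars), 16L) / (lambda - 1L)
  stats::setNames(c(mono, di), c(paste0("kmer_", NUC), paste0("kmer_", DINUC)))
}

#' k-nucleotide density (k = 1, 2)
#'
#' Prefix density of the residue observed at each position: the value at
#' mononucleotide position `i` is the count of that residue within positions
#' `1..i`, divided by `i`; dinucleotide positions are treated analogously over
#' dinucleotide indices. This couples each position with the running
#' frequency of its own symbol; dimension `2*lambda - 1`.
#'
#' @param seq Residue string, length >= 2.
#' @return Named numeric vector in `(0, 1]` of length `2 * nchar(seq) - 1`.
#' @examples
#' encode_kd("AUAU")  # mono densities 1, 1/2, 2/3, 1/2
#' @export
encode_kd <- function(seq) {
  chars <- residue_chars(seq)
  lambda <- length(chars)
  if (lambda < 2L) stopf("k-density encoding needs length >= 2 (got %d)", lambda)
  prefix_density <- function(idx) {
    vapply(seq_along(idx), function(i) sum(idx[1:i] == idx[i]) / i, numeric(1))
  }
  mono <- prefix_density(mono_index(chars))
  di <- prefix_density(di_index(chars))
  stats::setNames(c(mono, di),
                  c(paste0("kd_m", seq_len(lambda)),
                    paste0("kd_d", seq_len(lambda - 1L))))
}

#' Nucleotide chemical property encoding
#'
#' Each residue maps to a 3-bit chemical descriptor (ring structure,
#' functional group, hydrogen-bond strength): A -> (1,1,1), U -> (0,0,1),
#' C -> (0,1,0), G -> (1,0,0). Dimension `3 * lambda`.
#'
#' @param seq Residue string.
#' @return Named numeric vector of length `3 * nchar(seq)`.
#' @export
encode_ncp <- function(seq) {
  chars <- residue_chars(seq)
  ncp <- matrix(c(1, 1, 1,   # A: purine ring, amino group, weak H-bond
                  0, 0, 1,   # U
                  0, 1, 0,   # C
                  1, 0, 0),  # G
                nrow = 3L, dimnames = list(c("ring", "func", "hbond"), NUC))
  out <- as.vector(ncp[, mono_index(chars), drop = FALSE])
  names(out) <- paste0("ncp_p", rep(seq_along(chars), each = 3L), "_",
                       c("ring", "func", "hbond"))
  out
}

#' Fit a position-specific k-nucleotide propensity table
#'
#' For every window position, the difference between the frequency of each
#' nucleotide (and, over positions `1..lambda-1`, each dinucleotide) in the
#' pseudouridine-site set and in the non-site set. Entries lie in `[-1, 1]`
#' and each position's entries sum to zero; identical sets give the all-zero
#' table. The table is label-derived, so it must be fitted on training
#' sequences only (the cross-validation harnesses in this package refit it
#' inside every training fold).
#'
#' @param pos,neg Character vectors of residue strings, all the same length.
#' @return Object of class `propensity_table` with elements `mono`
#'   (`lambda x 4`), `di` (`(lambda-1) x 16`), `window_length`.
#' @export
fit_pskp <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L) stopf("both sets must be non-empty")
  lens <- unique(nchar(c(pos, neg)))
  if (length(lens) != 1L)
    stopf("heterogeneous sequence lengths: %s", paste(lens, collapse = ", "))
  lambda <- lens

  pos_freq <- function(seqs, index_fun, nlev, npos) {
    m <- matrix(0, nrow = npos, ncol = nlev)
    for (s in seqs) {
      idx <- index_fun(residue_chars(s))
      m[cbind(seq_len(npos), idx)] <- m[cbind(seq_len(npos), idx)] + 1
    }
    m / length(seqs)
  }
  mono <- pos_freq(pos, mono_index, 4L, lambda) -
    pos_freq(neg, mono_index, 4L, lambda)
  di <- pos_freq(pos, di_index, 16L, lambda - 1L) -
    pos_freq(neg, di_index, 16L, lambda - 1L)
  dimnames(mono) <- list(paste0("p", seq_len(lambda)), NUC)
  dimnames(di) <- list(paste0("d", seq_len(lambda - 1L)), DINUC)
  structure(list(mono = mono, di = di, window_length = lambda),
            class = "propensity_table")
}

#' Position-specific k-nucleotide propensity encoding
#'
#' Looks up, for each position of the window, the fitted propensity of the
#' residue (and dinucleotide) actually observed there; dimension
#' `2*lambda - 1`.
#'
#' @param seq Residue string of length `table$window_length`.
#' @param table A [fit_pskp()] table.
#' @return Named numeric vector of length `2 * lambda - 1`.
#' @export
encode_pskp <- function(seq, table) {
  stopifnot(inherits(table, "propensity_table"))
  chars <- residue_chars(seq)
  lambda <- length(chars)
  if (lambda != table$window_length)
    stopf("sequence length %d does not match propensity table length %d",
          lambda, table$window_length)
  mono <- table$mono[cbind(seq_len(lambda), mono_index(chars))]
  di <- table$di[cbind(seq_len(lambda - 1L), di_index(chars))]
  stats::setNames(c(mono, di),
                  c(paste0("pskp_m", seq_len(lambda)),
                    paste0("pskp_d", seq_len(lambda - 1L))))
}

#' Configuration for pseudo dinucleotide composition
#'
#' Bundles the PseDNC tuning parameters and the dinucleotide physicochemical
#' property table (free energy, stacking energy, hydrophilicity), which is
#' standardized to zero mean and unit variance over the 16 dinucleotides.
#'
#' @param lambda_pse Number of sequence-order correlation tiers (default 2);
#'   must satisfy `lambda_pse < lambda - 1` for the windows encoded.
#' @param w Weight of the correlation tiers relative to the dinucleotide
#'   composition, in `(0, 1]` (default 0.1).
#' @param properties Optional data frame with columns `dinucleotide` plus one
#'   column per property; defaults to the table shipped with the package.
#' @return Object of class `psednc_config` with the standardized property
#'   matrix (`16 x n_properties`).
#' @export
psednc_config <- function(lambda_pse = 2L, w = 0.1, properties = NULL) {
  lambda_pse <- as.integer(lambda_pse)
  if (lambda_pse < 0L) stopf("lambda_pse must be non-negative")
  if (!(w > 0 && w <= 1)) stopf("w must be in (0, 1]")
  if (is.null(properties)) {
    path <- system.file("extdata", "rna_dinucleotide_properties.tsv",
                        package = "pseuvote", mustWork = TRUE)
    properties <- utils::read.delim(path, comment.char = "#")
  }
  stopifnot("dinucleotide" %in% names(properties))
  rownames(properties) <- properties$dinucleotide
  pm <- as.matrix(properties[DINUC, setdiff(names(properties), "dinucleotide")])
  # population standardization across the 16 dinucleotides
  pm <- apply(pm, 2L, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  rownames(pm) <- DINUC
  structure(list(lambda_pse = lambda_pse, w = w, properties = pm),
            class = "psednc_config")
}

#' Pseudo dinucleotide composition encoding
#'
#' The 16 dinucleotide frequencies augmented with `lambda_pse` sequence-order
#' correlation factors. Tier `j`'s factor `theta_j` is the mean, over all
#' dinucleotide pairs `j` positions apart, of the mean squared difference of
#' the standardized physicochemical properties; the full vector is normalized
#' so its `16 + lambda_pse` non-negative components sum to 1: the first 16 are
#' `f_k / (1 + w * sum(theta))`, the rest `w * theta_j / (1 + w * sum(theta))`.
#'
#' @param seq Residue string with `nchar(seq) - 1 > lambda_pse`.
#' @param config A [psednc_config()].
#' @return Named numeric vector of length `16 + lambda_pse`, summing to 1.
#' @export
encode_psednc <- function(seq, config = psednc_config()) {
  stopifnot(inherits(config, "psednc_config"))
  chars <- residue_chars(seq)
  n_di <- length(chars) - 1L
  lp <- config$lambda_pse
  if (n_di <= lp)
    stopf("lambda_pse = %d requires sequence length > %d (got %d)",
          lp, lp + 1L, length(chars))
  di <- di_index(chars)
  f <- tabulate(di, 16L) / n_di
  theta <- numeric(lp)
  if (lp > 0L) {
    P <- config$properties
    for (j in seq_len(lp)) {
      i <- seq_len(n_di - j)
      d2 <- (P[di[i], , drop = FALSE] - P[di[i + j], , drop = FALSE])^2
      theta[j] <- mean(rowMeans(d2))
    }
  }
  denom <- 1 + config$w * sum(theta)
  out <- c(f / denom, config$w * theta / denom)
  names(out) <- c(paste0("psednc_", DINUC),
                  if (lp > 0L) paste0("psednc_theta", seq_len(lp)))
  out
}

#' Encode every window of a dataset with one descriptor
#'
#' @param dataset A `labeled_dataset`.
#' @param descriptor One of `"ONEHOT"`, `"KMER"`, `"KD"`, `"PSEDNC"`,
#'   `"PSKP"`, `"NCP"`.
#' @param fitted For `"PSKP"`, a [fit_pskp()] table (required); for
#'   `"PSEDNC"`, a [psednc_config()] (defaults to `psednc_config()`).
#' @return Numeric matrix, one row per window in dataset order, with feature
#'   names as column names, row names the sequence ids, and attributes
#'   `descriptor` and `labels`.
#' @export
encode_dataset <- function(dataset, descriptor, fitted = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  descriptor <- match.arg(toupper(descriptor), DESCRIPTORS)
  if (length(dataset$sequences) == 0L) stopf("empty dataset")
  enc <- switch(descriptor,
    ONEHOT = encode_one_hot,
    KMER   = encode_kmer,
    KD     = encode_kd,
    NCP    = encode_ncp,
    PSKP   = {
      if (!inherits(fitted, "propensity_table"))
        stopf("PSKP encoding requires a fitted propensity table")
      function(s) encode_pskp(s, fitted)
    },
    PSEDNC = {
      cfg <- if (is.null(fitted)) psednc_config() else fitted
      if (!inherits(cfg, "psednc_config"))
        stopf("PSEDNC encoding requires a psednc_config")
      function(s) encode_psednc(s, cfg)
    })
  rows <- lapply(dataset$sequences, enc)
  x <- do.call(rbind, rows)
  rownames(x) <- seq_ids(dataset$sequences)
  attr(x, "descriptor") <- descriptor
  attr(x, "labels") <- dataset$labels
  x
}

#' Descriptor dimensionality for a window length
#'
#' @param descriptor Descriptor name.
#' @param lambda Window length.
#' @param lambda_pse PseDNC correlation tiers (only used for `"PSEDNC"`).
#' @return Integer feature count.
#' @export
descriptor_dim <- function(descriptor, lambda, lambda_pse = 2L) {
  descriptor <- match.arg(toupper(descriptor), DESCRIPTORS)
  lambda <- as.integer(lambda)
  switch(descriptor,
         ONEHOT = 20L * lambda - 16L,
         KMER = 20L,
         KD = 2L * lambda - 1L,
         NCP = 3L * lambda,
         PSKP = 2L * lambda - 1L,
         PSEDNC = 16L + as.integer(lambda_pse))
}

#' Write / read a feature matrix as TSV
#'
#' Plain-text round trip for encoded datasets: a header row of feature names,
#' one row per sequence, with the sequence id in the first column and, when
#' labels are attached, a final `label` column.
#'
#' @param x Matrix from [encode_dataset()].
#' @param path Output TSV path.
#' @return `path` invisibly; `read_feature_tsv()` returns the matrix with
#'   `labels` attribute restored when present.
#' @export
write_feature_tsv <- function(x, path) {
  df <- data.frame(seq_id = rownames(x), x, check.names = FALSE)
  if (!is.null(attr(x, "labels"))) df$label <- attr(x, "labels")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  x <- as.matrix(df[, setdiff(names(df), "seq_id"), drop = FALSE])
  rownames(x) <- df$seq_id
  attr(x, "labels") <- labels
  x
}

#' Write a propensity table as TSV (position, symbol, value)
#'
#' @param table A `propensity_table`.
#' @param path Output path.
#' @export
write_propensity_tsv <- function(table, path) {
  long <- rbind(
    data.frame(kind = "mono",
               position = rep(seq_len(nrow(table$mono)), times = 4L),
               symbol = rep(NUC, each = nrow(table$mono)),
               value = as.vector(table$mono)),
    data.frame(kind = "di",
               position = rep(seq_len(nrow(table$di)), times = 16L),
               symbol = rep(DINUC, each = nrow(table$di)),
               value = as.vector(table$di)))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
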