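# Synthetic fixtures with planted, tunable signal. The planted signal is a
# position-specific composition bias (not a fixed motif): at each designated
# signal position, positives draw one designated nucleotide with an excess
# probability on top of the background. Position-sensitive descriptors
# (one-hot, NCP, PSKP) see the bias directly and compositional descriptors
# (k-mer, KD, PseDNC) see its aggregate, giving all six partially independent
# signal, as in real heterogeneous-descriptor ensembles.

#' Specification of a synthetic window dataset
#'
#' Defaults mirror the structure of the independent benchmark sets in this
#' field (100 pseudouridine-site and 100 non-site windows of 21 nt) with a
#' clearly separable planted bias: four signal positions with an excess
#' probability of 0.6 for the designated nucleotide in positives.
#'
#' @param n_pos,n_neg Class sizes.
#' @param window_length Odd window length.
#' @param signal_positions Positions carrying the planted bias; must exclude
#'   the center (which is always U in both classes). Default: four flank
#'   positions spread around the center (6, 9, 14, 17 for a 21 nt window).
#' @param signal_nucleotides Designated nucleotide per signal position
#'   (recycled; default cycles A, C, G).
#' @param signal_strength Excess probability, in `[0, 1]`, of the designated
#'   nucleotide at each signal position in positives.
#' @param background Length-4 nucleotide probabilities in A, U, C, G order
#'   (default uniform).
#' @param seed Seed; fixtures are bit-reproducible from it.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pos = 100L, n_neg = 100L, window_length = 21L,
                         signal_positions = NULL,
                         signal_nucleotides = NULL,
                         signal_strength = 0.6,
                         background = c(0.25, 0.25, 0.25, 0.25),
                         seed = 1L) {
  window_length <- as.integer(window_length)
  if (window_length %% 2L == 0L) stopf("window_length must be odd")
  center <- (window_length + 1L) %/% 2L
  if (is.null(signal_positions)) {
    # four flank positions spread around the center (6, 9, 14, 17 at 21 nt),
    # clipped into range for short windows
    cand <- pmin(pmax(center + c(-5L, -2L, 3L, 6L), 1L), window_length)
    cand[cand == center] <- cand[cand == center] + 1L
    signal_positions <- unique(pmin(cand, window_length))
  }
  if (center %in% signal_positions)
    stopf("signal positions must exclude the center (%d)", center)
  if (any(signal_positions < 1L | signal_positions > window_length))
    stopf("signal positions must lie in 1..%d", window_length)
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-9,
            signal_strength >= 0, signal_strength <= 1)
  names(background) <- NUC
  if (is.null(signal_nucleotides))
    signal_nucleotides <- rep_len(c("A", "C", "G"), length(signal_positions))
  signal_nucleotides <- rep_len(signal_nucleotides, length(signal_positions))
  if (any(signal_strength + background[signal_nucleotides] > 1))
    stopf("signal_strength + background probability exceeds 1")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 window_length = window_length,
                 signal_positions = as.integer(signal_positions),
                 signal_nucleotides = signal_nucleotides,
                 signal_strength = signal_strength,
                 background = background, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Draw one window; positive windows get the biased composition at signal
# positions. Center is forced to U in both classes.
draw_window <- function(spec, positive) {
  lambda <- spec$window_length
  chars <- sample(NUC, lambda, replace = TRUE, prob = spec$background)
  chars[(lambda + 1L) %/% 2L] <- "U"
  if (positive && spec$signal_strength > 0) {
    for (i in seq_along(spec$signal_positions)) {
      p <- spec$signal_positions[i]
      nt <- spec$signal_nucleotides[i]
      probs <- spec$background
      rest <- 1 - spec$background[nt] - spec$signal_strength
      probs[setdiff(NUC, nt)] <-
        spec$background[setdiff(NUC, nt)] * rest /
          sum(spec$background[setdiff(NUC, nt)])
      probs[nt] <- spec$background[nt] + spec$signal_strength
      chars[p] <- sample(NUC, 1L, prob = probs)
    }
  }
  paste(chars, collapse = "")
}

#' Generate a labeled synthetic window dataset
#'
#' @param spec A [fixture_spec()].
#' @return List with `dataset` (a `labeled_dataset`) and `truth`: the planted
#'   signal positions/nucleotides plus, per position-sensitive descriptor,
#'   the indices of the directly informative encoder columns (for
#'   planted-signal recovery experiments).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    pos <- vapply(seq_len(spec$n_pos), function(i) draw_window(spec, TRUE),
                  character(1))
    neg <- vapply(seq_len(spec$n_neg), function(i) draw_window(spec, FALSE),
                  character(1))
  })
  names(pos) <- paste0("pos", seq_along(pos))
  names(neg) <- paste0("neg", seq_along(neg))
  dataset <- validate_dataset(pos, neg, spec$window_length)

  lambda <- spec$window_length
  sp <- spec$signal_positions
  di_touch <- sort(unique(c(sp[sp > 1L] - 1L, sp[sp < lambda])))
  truth <- list(
    signal_positions = sp,
    signal_nucleotides = spec$signal_nucleotides,
    onehot_columns = sort(c(as.vector(outer(1:4, (sp - 1L) * 4L, `+`)),
                            4L * lambda +
                              as.vector(outer(1:16, (di_touch - 1L) * 16L, `+`)))),
    ncp_columns = sort(as.vector(outer(1:3, (sp - 1L) * 3L, `+`))),
    pskp_columns = sort(c(sp, lambda + di_touch)))
  list(dataset = dataset, truth = truth)
}

#' Generate a planted-feature numeric matrix
#'
#' A direct fixture for feature-selection experiments: `n_informative`
#' columns whose class means differ by `effect_size` (in units of the unit
#' within-class SD) and `n_noise` pure-noise columns, with balanced labels.
#' The defaults (100 samples, shift 0.8) are chosen so the fitness landscape
#' of a feature-selection search is informative rather than degenerate: the
#' informative-only subset cross-validates clearly better than the full
#' feature set, so including noise columns measurably dilutes the RBF
#' distances. With a much larger effect or sample size, accuracy saturates
#' for nearly every mask and selection has no gradient to follow.
#'
#' @param n Total samples (balanced classes).
#' @param n_informative,n_noise Column counts.
#' @param effect_size Class mean shift of informative columns.
#' @param seed Seed.
#' @return List with `x` (`n x (n_informative + n_noise)` matrix), `labels`,
#'   and `informative` (column indices of the planted features).
#' @export
generate_feature_fixture <- function(n = 100L, n_informative = 10L,
                                     n_noise = 90L, effect_size = 0.8,
                                     seed = 1L) {
  p <- n_informative + n_noise
  labels <- rep(c(1L, 0L), length.out = n)
  with_seed(seed, {
    informative <- sort(sample.int(p, n_informative))
    x <- matrix(stats::rnorm(n * p), nrow = n)
    x[, informative] <- x[, informative] + labels * effect_size
  })
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, labels = labels, informative = informative)
}

#' Generate a long RNA with planted positive-class windows
#'
#' Splices class-generated windows into a background sequence at stated
#' (1-based) start positions, for end-to-end scanner recovery experiments.
#'
#' @param length Total sequence length.
#' @param planted_windows Data frame or list of lists with `position`
#'   (window start) and `window` (residue string); windows must fit and not
#'   overlap.
#' @param background Length-4 nucleotide probabilities (A, U, C, G order).
#' @param seed Seed.
#' @return List with `sequence` (residue string) and `truth` (data frame of
#'   `start` and `center` positions of the planted windows).
#' @export
generate_long_rna <- function(length, planted_windows = list(),
                              background = c(0.25, 0.25, 0.25, 0.25),
                              seed = 1L) {
  if (is.data.frame(planted_windows))
    planted_windows <- split(planted_windows, seq_len(nrow(planted_windows)))
  starts <- vapply(planted_windows, function(w) as.integer(w$position),
                   integer(1))
  wins <- vapply(planted_windows, function(w) as.character(w$window),
                 character(1))
  lens <- nchar(wins)
  if (any(starts < 1L) || any(starts + lens - 1L > length))
    stopf("planted window out of range for a %d nt sequence", length)
  if (length(starts) > 1L) {
    ord <- order(starts)
    if (any(starts[ord][-1L] <= (starts + lens - 1L)[ord][-length(starts)]))
      stopf("planted windows overlap")
  }
  chars <- with_seed(seed,
                     sample(NUC, length, replace = TRUE, prob = background))
  for (i in seq_along(starts))
    chars[starts[i]:(starts[i] + lens[i] - 1L)] <- residue_chars(wins[i])
  truth <- data.frame(start = starts, center = starts + (lens - 1L) %/% 2L)
  list(sequence = paste(chars, collapse = ""),
       truth = truth[order(truth$start), , drop = FALSE])
}
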