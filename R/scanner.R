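# Sliding-window identification of candidate pseudouridine sites in
# arbitrary-length RNA: every U whose full training-length window fits inside
# the input is classified by the ensemble; U's too close to either end are
# reported as skipped (encoders are undefined over padded symbols, so partial
# windows are never padded). All positions are 1-based.

#' Scan an RNA sequence for pseudouridine sites
#'
#' @param seq Residue string (length >= the ensemble's window length) or a
#'   single named element of a sequence vector.
#' @param ensemble An `ensemble_predictor`.
#' @param seq_id Identifier used in the output (defaults to the name of
#'   `seq`, or `"seq1"`).
#' @return Object of class `site_scan`: list with `calls` (data frame:
#'   `seq_id`, `position` of the center U, `window`, fused `label`, six
#'   `vote_*` and six `dv_*` columns, ordered by position) and `skipped`
#'   (integer positions of U's whose window would overrun an end).
#' @export
scan_sequence <- function(seq, ensemble, seq_id = NULL) {
  stopifnot(inherits(ensemble, "ensemble_predictor"))
  if (is.null(seq_id))
    seq_id <- if (!is.null(names(seq))) names(seq)[1L] else "seq1"
  seq <- unname(seq[[1L]])
  lambda <- ensemble$window_length
  n <- nchar(seq)
  if (n < lambda)
    stopf("sequence '%s' (%d nt) is shorter than the %d nt window",
          seq_id, n, lambda)
  flank <- (lambda - 1L) %/% 2L
  chars <- residue_chars(seq)
  u_pos <- which(chars == "U")
  eligible <- u_pos[u_pos > flank & u_pos <= n - flank]
  skipped <- setdiff(u_pos, eligible)

  if (length(eligible) == 0L) {
    calls <- predict_ensemble(ensemble, character(0))
    calls <- cbind(data.frame(seq_id = character(0), position = integer(0),
                              window = character(0)),
                   calls[, setdiff(names(calls), "seq_id"), drop = FALSE])
    return(structure(list(calls = calls, skipped = skipped),
                     class = "site_scan"))
  }
  windows <- substring(seq, eligible - flank, eligible + flank)
  names(windows) <- paste0(seq_id, "_pos", eligible)
  pred <- predict_ensemble(ensemble, windows)
  calls <- cbind(data.frame(seq_id = seq_id, position = eligible,
                            window = unname(windows)),
                 pred[, setdiff(names(pred), "seq_id"), drop = FALSE])
  structure(list(calls = calls[order(calls$position), ], skipped = skipped),
            class = "site_scan")
}

#' @export
print.site_scan <- function(x, ...) {
  cat(sprintf("site_scan: %d candidate windows (%d called positive), %d skipped U\n",
              nrow(x$calls), sum(x$calls$label), length(x$skipped)))
  invisible(x)
}

#' Scan every record of a FASTA file
#'
#' @param path FASTA path (records must be at least the window length).
#' @param ensemble An `ensemble_predictor`.
#' @return Named list of `site_scan` objects, one per record.
#' @export
scan_fasta <- function(path, ensemble) {
  seqs <- read_fasta(path)
  out <- lapply(seq_along(seqs), function(i)
    scan_sequence(seqs[[i]], ensemble, seq_id = names(seqs)[i]))
  names(out) <- names(seqs)
  out
}

#' Write scan results as TSV / BED
#'
#' `write_scan_tsv()` writes the calls table (seq_id, position, label, votes,
#' margins) and a companion `<path>.skipped.tsv` of skipped U positions.
#' `write_scan_bed()` writes positive calls in BED-like 0-based half-open
#' coordinates (`seq_id`, `position - 1`, `position`, name, score = summed
#' margin).
#'
#' @param scans A `site_scan` or list of them.
#' @param path Output path.
#' @export
write_scan_tsv <- function(scans, path) {
  if (inherits(scans, "site_scan")) scans <- list(scans)
  calls <- do.call(rbind, lapply(scans, function(s)
    s$calls[, setdiff(names(s$calls), "window"), drop = FALSE]))
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  skipped <- do.call(rbind, lapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    if (length(s$skipped) == 0L) return(NULL)
    data.frame(seq_id = if (nrow(s$calls) > 0L) s$calls$seq_id[1L]
               else names(scans)[i] %||% paste0("seq", i),
               position = s$skipped)
  }))
  if (is.null(skipped))
    skipped <- data.frame(seq_id = character(0), position = integer(0))
  utils::write.table(skipped, paste0(path, ".skipped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_scan_tsv
#' @export
write_scan_bed <- function(scans, path) {
  if (inherits(scans, "site_scan")) scans <- list(scans)
  rows <- do.call(rbind, lapply(scans, function(s) {
    pos <- s$calls[s$calls$label == 1L, , drop = FALSE]
    if (nrow(pos) == 0L) return(NULL)
    dv <- rowSums(pos[, grep("^dv_", names(pos)), drop = FALSE])
    data.frame(chrom = pos$seq_id, start = pos$position - 1L,
               end = pos$position,
               name = paste0("psi_", pos$seq_id, "_", pos$position),
               score = dv)
  }))
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), name = character(0),
                       score = numeric(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
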