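# Independent brute-force oracles, written with explicit loops and counting
# so they share no code path with the package encoders.

ORACLE_NUC <- c("A", "U", "C", "G")
ORACLE_DI <- as.vector(t(outer(ORACLE_NUC, ORACLE_NUC, paste0)))

oracle_chars <- function(seq) strsplit(seq, "")[[1]]

oracle_onehot <- function(seq) {
  ch <- oracle_chars(seq)
  out <- numeric(0)
  for (c in ch) out <- c(out, as.numeric(ORACLE_NUC == c))
  if (length(ch) >= 2) {
    for (i in 1:(length(ch) - 1)) {
      d <- paste0(ch[i], ch[i + 1])
      out <- c(out, as.numeric(ORACLE_DI == d))
    }
  }
  out
}

oracle_kmer <- function(seq) {
  ch <- oracle_chars(seq)
  L <- length(ch)
  mono <- vapply(ORACLE_NUC, function(n) sum(ch == n) / L, numeric(1))
  dis <- character(L - 1)
  for (i in 1:(L - 1)) dis[i] <- paste0(ch[i], ch[i + 1])
  di <- vapply(ORACLE_DI, function(d) sum(dis == d) / (L - 1), numeric(1))
  unname(c(mono, di))
}

oracle_kd <- function(seq) {
  ch <- oracle_chars(seq)
  L <- length(ch)
  mono <- numeric(L)
  for (i in 1:L) {
    cnt <- 0
    for (j in 1:i) if (ch[j] == ch[i]) cnt <- cnt + 1
    mono[i] <- cnt / i
  }
  dis <- character(L - 1)
  for (i in 1:(L - 1)) dis[i] <- paste0(ch[i], ch[i + 1])
  di <- numeric(L - 1)
  for (i in 1:(L - 1)) {
    cnt <- 0
    for (j in 1:i) if (dis[j] == dis[i]) cnt <- cnt + 1
    di[i] <- cnt / i
  }
  c(mono, di)
}

oracle_ncp <- function(seq) {
  ch <- oracle_chars(seq)
  out <- numeric(0)
  for (c in ch) {
    x <- if (c %in% c("A", "G")) 1 else 0
    y <- if (c %in% c("A", "C")) 1 else 0
    z <- if (c %in% c("A", "U")) 1 else 0
    out <- c(out, x, y, z)
  }
  out
}

oracle_pskp_table <- function(pos, neg) {
  L <- nchar(pos[1])
  freq <- function(seqs, p, sym) {
    hits <- 0
    for (s in seqs)
      if (substr(s, p, p + nchar(sym) - 1) == sym) hits <- hits + 1
    hits / length(seqs)
  }
  mono <- matrix(0, L, 4)
  for (p in 1:L) for (k in 1:4)
    mono[p, k] <- freq(pos, p, ORACLE_NUC[k]) - freq(neg, p, ORACLE_NUC[k])
  di <- matrix(0, L - 1, 16)
  for (p in 1:(L - 1)) for (k in 1:16)
    di[p, k] <- freq(pos, p, ORACLE_DI[k]) - freq(neg, p, ORACLE_DI[k])
  list(mono = mono, di = di)
}

oracle_pskp <- function(seq, pos, neg) {
  tab <- oracle_pskp_table(pos, neg)
  ch <- oracle_chars(seq)
  L <- length(ch)
  out <- numeric(0)
  for (p in 1:L) out <- c(out, tab$mono[p, which(ORACLE_NUC == ch[p])])
  for (p in 1:(L - 1)) {
    d <- paste0(ch[p], ch[p + 1])
    out <- c(out, tab$di[p, which(ORACLE_DI == d)])
  }
  out
}

# Direct PseDNC evaluation from the standardized property matrix.
oracle_psednc <- function(seq, lambda_pse, w, props) {
  ch <- oracle_chars(seq)
  L <- length(ch)
  dis <- character(L - 1)
  for (i in 1:(L - 1)) dis[i] <- paste0(ch[i], ch[i + 1])
  f <- vapply(ORACLE_DI, function(d) sum(dis == d) / (L - 1), numeric(1))
  theta <- numeric(lambda_pse)
  if (lambda_pse > 0) {
    for (j in 1:lambda_pse) {
      acc <- 0
      for (i in 1:(L - 1 - j))
        acc <- acc + mean((props[dis[i], ] - props[dis[i + j], ])^2)
      theta[j] <- acc / (L - 1 - j)
    }
  }
  denom <- sum(f) + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

oracle_vote <- function(votes, dvs = NULL) {
  ones <- 0
  for (v in votes) if (v == 1) ones <- ones + 1
  if (ones >= 4) return(1L)
  if (ones <= 2) return(0L)
  if (is.null(dvs)) return(1L)
  s <- sum(dvs)
  if (s < 0) 0L else 1L
}
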