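## Independent oracles used across the suite.  These deliberately use
## naive loop-based implementations, separate from the package's code
## paths.

## base-wise identity of two equal-length strings, by explicit loop
oracleIdentity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- 0L
  for (i in seq_along(ca)) if (ca[i] == cb[i]) n <- n + 1L
  n / length(ca)
}

oracleRevComp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

## brute-force all-pairs k-mer self-match scan -> maximal exact diagonal
## runs (no gap merging), sense and antisense, canonical pairs only
oracleDotplot <- function(seq, k) {
  n <- nchar(seq)
  km <- substring(seq, 1:(n - k + 1), k:n)
  rc <- vapply(km, oracleRevComp, character(1), USE.NAMES = FALSE)
  sense <- list()
  anti <- list()
  for (i in seq_along(km)) {
    for (j in seq_along(km)) {
      if (j > i && km[i] == km[j])
        sense[[length(sense) + 1L]] <- c(i, j)
      if (j >= i && km[i] == rc[j])
        anti[[length(anti) + 1L]] <- c(i, j)
    }
  }
  toRuns <- function(pairs, antisense) {
    if (!length(pairs)) return(NULL)
    m <- do.call(rbind, pairs)
    key <- if (antisense) m[, 1] + m[, 2] else m[, 2] - m[, 1]
    out <- NULL
    for (kk in sort(unique(key))) {
      q <- sort(m[key == kk, 1])
      brk <- c(0L, which(diff(q) > 1L), length(q))
      for (b in seq_len(length(brk) - 1L)) {
        qs <- q[brk[b] + 1L]; qe <- q[brk[b + 1L]] + k - 1L
        if (antisense) {
          out <- rbind(out, data.frame(
            q_start = qs, q_end = qe, t_start = kk - qe + k - 1L,
            t_end = kk - qs + k - 1L, orientation = "antisense",
            length = qe - qs + 1L))
        } else {
          out <- rbind(out, data.frame(
            q_start = qs, q_end = qe, t_start = qs + kk, t_end = qe + kk,
            orientation = "sense", length = qe - qs + 1L))
        }
      }
    }
    out
  }
  rbind(toRuns(sense, FALSE), toRuns(anti, TRUE))
}

## dynamic-programming longest common substring length (forward only)
oracleLCSubstring <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  prev <- integer(length(cb))
  best <- 0L
  for (i in seq_along(ca)) {
    cur <- integer(length(cb))
    for (j in seq_along(cb)) {
      if (ca[i] == cb[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

## best tandem period of a subsequence by autocorrelation score
oraclePeriod <- function(seq, offsets = 5:1000) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sc <- vapply(offsets, function(d) {
    if (d >= n) return(-Inf)
    sum(ch[1:(n - d)] == ch[(d + 1):n])
  }, numeric(1))
  offsets[which.max(sc)]
}

## difference-array pileup of alignment blocks
oraclePileup <- function(starts, ends, L) {
  d <- integer(L + 1L)
  for (i in seq_along(starts)) {
    d[starts[i]] <- d[starts[i]] + 1L
    d[ends[i] + 1L] <- d[ends[i] + 1L] - 1L
  }
  cumsum(d[seq_len(L)])
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
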