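#' @import data.table
NULL

## Merge sorted 1-based intervals on a shared diagonal, bridging gaps of at
## most `gap` bases (substitutions break exact k-mer runs into collinear
## pieces separated by 1..~2k bases).
.mergeIntervals <- function(st, en, gap) {
  o <- order(st)
  st <- st[o]; en <- en[o]
  outS <- st[1]; outE <- en[1]
  res <- list()
  for (i in seq_along(st)[-1]) {
    if (st[i] <= outE + gap + 1L) {
      outE <- max(outE, en[i])
    } else {
      res[[length(res) + 1L]] <- c(outS, outE)
      outS <- st[i]; outE <- en[i]
    }
  }
  res[[length(res) + 1L]] <- c(outS, outE)
  do.call(rbind, res)
}

#' Self dot-plot: maximal diagonal runs of exact k-mer self-matches
#'
#' Compares a sequence against itself in both orientations and reports
#' maximal merged diagonal runs of exact k-mer matches, the machine-readable
#' equivalent of a self-identity dot plot (sense matches appear as
#' off-main-diagonal runs, inverted repeats as antidiagonal runs).  The
#' trivial main diagonal is excluded and the output is symmetric: every
#' \code{(q, t)} segment is also reported as \code{(t, q)}.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param k Word size (>= 4).
#' @param minRun Minimal merged run length in bp to report.
#' @param mergeGap Maximal base gap bridged when merging collinear runs
#'   (tolerates isolated substitutions between repeat copies).
#' @return data.frame with columns \code{q_start, q_end, t_start, t_end}
#'   (1-based inclusive), \code{orientation} (\code{"sense"} or
#'   \code{"antisense"}) and \code{length}.
#' @export
selfDotplot <- function(seq, k = 12L, minRun = 20L, mergeGap = 25L) {
  seqc <- asChar(seq)
  n <- nchar(seqc)
  stopifnot(k >= 4L, n >= k)
  starts <- seq_len(n - k + 1L)
  km <- substring(seqc, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", km)
  dt <- data.table(kmer = km[ok], pos = starts[ok])
  rc <- as.character(reverseComplement(DNAStringSet(dt$kmer)))
  rcdt <- data.table(kmer = rc, tpos = dt$pos)

  emptyOut <- data.frame(q_start = integer(0), q_end = integer(0),
                         t_start = integer(0), t_end = integer(0),
                         orientation = character(0), length = integer(0))

  ## ---- sense pairs (q < t), grouped by diagonal t - q ----
  setkey(dt, kmer)
  sj <- dt[dt, on = "kmer", allow.cartesian = TRUE]
  sense <- sj[pos < i.pos, .(q = pos, t = i.pos)]
  senseRuns <- NULL
  if (nrow(sense)) {
    sense[, diag := t - q]
    senseRuns <- sense[, {
      m <- .mergeIntervals(q, q + k - 1L, mergeGap)
      .(qs = m[, 1], qe = m[, 2])
    }, by = diag]
    senseRuns <- senseRuns[qe - qs + 1L >= minRun]
  }

  ## ---- antisense pairs (canonical q <= t), grouped by antidiagonal ----
  aj <- dt[rcdt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  anti <- aj[pos <= tpos, .(q = pos, t = tpos)]
  antiRuns <- NULL
  if (nrow(anti)) {
    anti[, s := q + t]
    antiRuns <- anti[, {
      m <- .mergeIntervals(q, q + k - 1L, mergeGap)
      .(qs = m[, 1], qe = m[, 2])
    }, by = s]
    antiRuns <- antiRuns[qe - qs + 1L >= minRun]
  }

  out <- list()
  if (!is.null(senseRuns) && nrow(senseRuns)) {
    out[[1L]] <- data.frame(
      q_start = senseRuns$qs, q_end = senseRuns$qe,
      t_start = senseRuns$qs + senseRuns$diag,
      t_end = senseRuns$qe + senseRuns$diag,
      orientation = "sense",
      length = senseRuns$qe - senseRuns$qs + 1L)
  }
  if (!is.null(antiRuns) && nrow(antiRuns)) {
    ## q interval [qs, qe]; matching revcomp interval [s - qe, s - qs + k - 1]
    ## (merged in base space, so recover t from the antidiagonal)
    out[[length(out) + 1L]] <- data.frame(
      q_start = antiRuns$qs, q_end = antiRuns$qe,
      t_start = antiRuns$s - antiRuns$qe + k - 1L,
      t_end = antiRuns$s - antiRuns$qs + k - 1L,
      orientation = "antisense",
      length = antiRuns$qe - antiRuns$qs + 1L)
  }
  if (!length(out)) return(emptyOut)
  res <- do.call(rbind, out)
  for (cc in c("q_start", "q_end", "t_start", "t_end", "length"))
    res[[cc]] <- as.integer(res[[cc]])
  ## symmetric closure: add the mirrored segment (t, q)
  mirror <- data.frame(q_start = res$t_start, q_end = res$t_end,
                       t_start = res$q_start, t_end = res$q_end,
                       orientation = res$orientation, length = res$length)
  res <- rbind(res, mirror)
  res <- unique(res)
  res[order(res$q_start, res$t_start), , drop = FALSE]
}

#' Plot a self dot-plot
#'
#' Simple base-graphics rendering of \code{\link{selfDotplot}} output:
#' sense runs in red, antisense in blue.
#'
#' @param matches data.frame from \code{selfDotplot}.
#' @param main Plot title.
#' @return Invisibly, \code{matches}.
#' @importFrom graphics plot segments
#' @export
plotDotplot <- function(matches, main = "self dot-plot") {
  lim <- range(c(matches$q_start, matches$q_end,
                 matches$t_start, matches$t_end))
  plot(NA, xlim = lim, ylim = lim, xlab = "position (bp)",
       ylab = "position (bp)", main = main)
  sense <- matches$orientation == "sense"
  segments(matches$q_start[sense], matches$t_start[sense],
           matches$q_end[sense], matches$t_end[sense], col = "red")
  segments(matches$q_start[!sense], matches$t_end[!sense],
           matches$q_end[!sense], matches$t_start[!sense], col = "blue")
  invisible(matches)
}
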