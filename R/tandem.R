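## Outward edge refinement of a tandem array candidate: step past the run
## boundaries while each new base matches its partner one period inward,
## bridging an isolated mismatch when at least one of the two bases beyond
## it matches; edges end on a matching base.
.extendPeriodic <- function(ch, S, E, period, maxExt = 50L) {
  n <- length(ch)
  ## left edge: compare candidate bases to their partner one period inward
  ## and keep the extension maximizing a +1/-1 score (ties: shortest), so
  ## isolated substitutions at a true edge are bridged while random
  ## flanking sequence (expected score drift -0.5/base) is not entered
  d <- seq_len(min(maxExt, S - 1L, n - S + 1L - period))
  if (length(d)) {
    p <- S - d
    sc <- cumsum(ifelse(ch[p] == ch[p + period], 1L, -1L))
    best <- which.max(sc)
    if (sc[best] >= 3L) S <- S - best
  }
  d <- seq_len(min(maxExt, n - E, E - period))
  if (length(d)) {
    p <- E + d
    sc <- cumsum(ifelse(ch[p] == ch[p - period], 1L, -1L))
    best <- which.max(sc)
    if (sc[best] >= 3L) E <- E + best
  }
  c(S, E)
}

## mean pairwise identity over all ordered unit pairs of a decomposed array
.meanPairwiseIdentity <- function(seqc, boundaries, period, arrayEnd) {
  full <- boundaries[boundaries + period - 1L <= arrayEnd]
  if (length(full) < 2L) return(NA_real_)
  units <- substring(seqc, full, full + period - 1L)
  mat <- do.call(rbind, strsplit(units, ""))
  idx <- utils::combn(length(full), 2L)
  mean(vapply(seq_len(ncol(idx)), function(i)
    mean(mat[idx[1, i], ] == mat[idx[2, i], ]), numeric(1)))
}

#' Decompose tandem direct-repeat arrays from self dot-plot matches
#'
#' Clusters of sense off-diagonal runs with consistent offsets identify
#' direct-repeat arrays.  The repeat period is taken as the smallest offset
#' whose aggregated run support reaches 95\% of the best offset (so a
#' 5-copy array reports its unit length, not a multiple), unit boundaries
#' are phased to maximize cross-unit identity, and the mean pairwise unit
#' identity is computed by direct ungapped comparison.
#'
#' @param seq The sequence the matches were computed from.
#' @param matches Optional \code{\link{selfDotplot}} output.
#' @param minCopies Minimal copy number to report.
#' @param unitRange Allowed period range in bp, e.g. \code{c(5, 1000)}.
#' @param k Word size when matches are computed here.
#' @param minRun Minimal run length when matches are computed here.
#' @return data.frame with columns \code{start, end, unit_length, copies,
#'   identity} and a comma-separated \code{boundaries} column of 1-based
#'   unit start positions.
#' @export
findTandemArrays <- function(seq, matches = NULL, minCopies = 2L,
                             unitRange = c(5L, 1000L), k = 12L,
                             minRun = 20L) {
  stopifnot(unitRange[1] >= 5L, unitRange[2] <= 5000L)
  seqc <- asChar(seq)
  ch <- strsplit(seqc, "")[[1]]
  if (is.null(matches))
    matches <- selfDotplot(seqc, k = k, minRun = minRun)
  empty <- data.frame(start = integer(0), end = integer(0),
                      unit_length = integer(0), copies = integer(0),
                      identity = numeric(0), boundaries = character(0))
  s <- matches[matches$orientation == "sense" &
                 matches$q_start < matches$t_start, , drop = FALSE]
  if (nrow(s) == 0L) return(empty)
  s$diag <- s$t_start - s$q_start
  s <- s[order(s$q_start), , drop = FALSE]

  ## sweep-cluster runs whose [q_start, t_end] footprints overlap by more
  ## than a few bases (1-2 bp chance extensions across the boundary of two
  ## adjacent but unrelated arrays must not merge them)
  minOverlap <- 5L
  cl <- integer(nrow(s))
  cur <- 1L; maxEnd <- s$t_end[1]; cl[1] <- 1L
  for (i in seq_len(nrow(s))[-1]) {
    if (s$q_start[i] <= maxEnd - minOverlap + 1L) {
      cl[i] <- cur
      maxEnd <- max(maxEnd, s$t_end[i])
    } else {
      cur <- cur + 1L
      cl[i] <- cur
      maxEnd <- s$t_end[i]
    }
  }

  calls <- list()
  for (g in split(seq_len(nrow(s)), cl)) {
    runs <- s[g, , drop = FALSE]
    ## aggregate run support per offset, with +/- 3 bp offset tolerance
    cand <- sort(unique(runs$diag))
    score <- vapply(cand, function(d)
      sum(runs$length[abs(runs$diag - d) <= 3L]), numeric(1))
    okPeriod <- cand >= unitRange[1] & cand <= unitRange[2]
    if (!any(okPeriod)) next
    best <- max(score[okPeriod])
    period <- min(cand[okPeriod & score >= 0.95 * best])
    S <- min(runs$q_start); E <- max(runs$t_end)
    ## refine array edges: exact k-mer runs lose up to k-1 bases at a
    ## mutated edge, so extend outward comparing each base to its
    ## period-shifted partner, bridging isolated mismatches
    ref <- .extendPeriodic(ch, S, E, period)
    S <- ref[1]; E <- ref[2]
    copies <- as.integer(round((E - S + 1L) / period))
    if (copies < minCopies) next
    ## phase boundaries to maximize cross-unit identity
    phases <- sort(unique((runs$q_start - S) %% period))
    phases <- phases[phases < period]
    bestPhase <- phases[1]; bestId <- -1
    for (ph in phases) {
      b <- S + ph + (seq_len(copies) - 1L) * period
      b <- b[b <= E]
      id <- .meanPairwiseIdentity(seqc, b, period, E)
      if (!is.na(id) && id > bestId) {
        bestId <- id; bestPhase <- ph
      }
    }
    b <- S + bestPhase + (seq_len(copies) - 1L) * period
    b <- b[b <= E]
    calls[[length(calls) + 1L]] <- data.frame(
      start = S, end = E, unit_length = as.integer(period),
      copies = copies, identity = bestId,
      boundaries = paste(b, collapse = ","))
  }
  if (!length(calls)) return(empty)
  res <- do.call(rbind, calls)
  res[order(res$start), , drop = FALSE]
}
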