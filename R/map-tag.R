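#' Map 3'-tag RNA reads with annotation-guided splice awareness
#'
#' Reads are anchored by exact 20-mer seeds at their 5' end, then placed
#' either contiguously or as two blocks separated by a reference gap.
#' Annotated candidate introns are tried first (which also resolves the
#' usual donor/acceptor shift ambiguity); a de novo two-block split by
#' exact suffix search is the fallback.  Untemplated 3' A-runs are
#' soft-clipped before mapping and re-assigned base by base where the
#' reference itself continues with A, so the recorded tail length counts
#' genuinely untemplated adenosines only.
#'
#' @param reads A \code{\linkS4class{ReadSet}} of tag reads (or a named
#'   character vector).
#' @param ref Reference chromosome sequence.
#' @param introns Candidate introns: a \code{GRanges} (with an \code{ID}
#'   metadata column) or data.frame with \code{start}, \code{end},
#'   \code{ID}.
#' @param minAnchor Minimal block length on each side of a junction (>= 6).
#' @param maxMismatchRate Maximal tolerated mismatch fraction of a placement.
#' @param deNovoWindow Maximal de novo gap searched downstream of a donor.
#' @return data.frame with one row per aligned block: \code{read_id, stage,
#'   strand, block, q_start, q_end, t_start, t_end, spliced, intron_start,
#'   intron_end, clip3, n_mismatch}.
#' @export
mapTagReads <- function(reads, ref, introns = NULL, minAnchor = 8L,
                        maxMismatchRate = 0.1, deNovoWindow = 5000L) {
  stopifnot(minAnchor >= 6L)
  refc <- asChar(ref)
  refLen <- nchar(refc)
  if (is(reads, "ReadSet")) {
    rseq <- as.character(readSequences(reads))
    stage <- if ("stage" %in% names(readInfo(reads)))
      readInfo(reads)$stage else rep(NA_character_, length(rseq))
  } else {
    rseq <- setNames(as.character(reads), names(reads))
    stage <- rep(NA_character_, length(rseq))
  }
  ids <- names(rseq)
  if (is.null(ids)) ids <- sprintf("tag_%06d", seq_along(rseq))

  intronDf <- NULL
  if (!is.null(introns)) {
    intronDf <- if (is(introns, "GRanges"))
      data.frame(start = start(introns), end = end(introns),
                 ID = mcols(introns)$ID, stringsAsFactors = FALSE)
    else as.data.frame(introns)
  }

  ## soft-clip trailing A-runs (candidate untemplated tails); runs shorter
  ## than 5 nt cannot support a poly(A) call and are far more likely to be
  ## templated, so they are left in place
  core <- sub("A{5,}$", "", rseq)
  nStrip <- nchar(rseq) - nchar(core)

  aK <- 20L
  idx <- .refKmerIndex(setNames(refc, "ref"), aK)

  anchorFor <- function(sq, offsets = c(1L, 11L, 31L, 51L)) {
    ## candidate reference start positions of read base 1
    for (off in offsets) {
      if (nchar(sq) < off + aK - 1L) break
      kk <- substr(sq, off, off + aK - 1L)
      hit <- idx[.(kk), nomatch = NULL]
      if (nrow(hit)) return(hit$rpos - off + 1L)
    }
    integer(0)
  }

  nmis <- function(a, b) {
    if (nchar(a) != nchar(b) || nchar(a) == 0L) return(Inf)
    countMismatches(a, b)
  }

  rows <- vector("list", length(rseq))
  for (i in seq_along(rseq)) {
    sq <- core[i]
    Lc <- nchar(sq)
    if (Lc < aK) next
    strand <- "+"
    cand <- anchorFor(sq)
    endOffs <- unique(pmax(1L, c(Lc - aK + 1L, Lc - aK - 9L)))
    candEnd <- anchorFor(sq, offsets = endOffs)
    if (!length(cand) && !length(candEnd)) {
      sq2 <- revComp(sq)
      cand <- anchorFor(sq2)
      candEnd <- anchorFor(sq2, offsets = endOffs)
      if (length(cand) || length(candEnd)) {
        strand <- "-"
        sq <- sq2
      } else next
    }
    cand <- cand[cand >= 1L & cand + Lc - 1L <= refLen + deNovoWindow]
    ## 3'-end anchors give candidate positions of the last read base
    candQe <- candEnd + Lc - 1L
    candQe <- candQe[candQe >= Lc & candQe <= refLen]
    best <- NULL
    consider <- function(cfg) {
      if (is.null(best) || cfg$mis < best$mis) best <<- cfg
    }
    evalSplice <- function(L1, j) {
      ## two-block placement: L1 read bases up to the donor, the rest from
      ## the acceptor on
      d <- intronDf$start[j]
      a2 <- intronDf$end[j] + 1L
      L2 <- Lc - L1
      p <- d - L1
      if (p < 1L || a2 + L2 - 1L > refLen) return()
      m <- nmis(substr(sq, 1L, L1), substr(refc, p, d - 1L)) +
        nmis(substr(sq, L1 + 1L, Lc), substr(refc, a2, a2 + L2 - 1L))
      consider(list(p = p, mis = m, spliced = TRUE, L1 = L1,
                    iStart = d, iEnd = intronDf$end[j]))
    }
    for (p in cand) {
      if (p + Lc - 1L <= refLen)
        consider(list(p = p, mis = nmis(sq, substr(refc, p, p + Lc - 1L)),
                      spliced = FALSE))
      if (!is.null(intronDf))
        for (j in seq_len(nrow(intronDf))) {
          L1 <- intronDf$start[j] - p
          if (L1 >= minAnchor && L1 <= Lc - minAnchor) evalSplice(L1, j)
        }
    }
    for (qe in candQe) {
      p <- qe - Lc + 1L
      if (p >= 1L)
        consider(list(p = p, mis = nmis(sq, substr(refc, p, qe)),
                      spliced = FALSE))
      if (!is.null(intronDf))
        for (j in seq_len(nrow(intronDf))) {
          L2 <- qe - intronDf$end[j]
          L1 <- Lc - L2
          if (L1 >= minAnchor && L1 <= Lc - minAnchor) evalSplice(L1, j)
        }
    }
    if (is.null(best)) next
    ## de novo two-block fallback: exact suffix search downstream
    if (best$mis > ceiling(maxMismatchRate * Lc) && !best$spliced) {
      p <- best$p
      win <- substr(refc, p, min(p + Lc - 1L, refLen))
      cmp <- charToRaw(substr(sq, 1L, nchar(win))) != charToRaw(win)
      L1 <- if (any(cmp)) which(cmp)[1] - 1L else nchar(win)
      L2 <- Lc - L1
      if (L1 >= minAnchor && L2 >= minAnchor) {
        sfx <- substr(sq, L1 + 1L, Lc)
        to <- min(p + L1 + deNovoWindow, refLen)
        hit <- regexpr(sfx, substr(refc, p + L1 + 1L, to), fixed = TRUE)
        if (hit != -1L) {
          a2 <- p + L1 + as.integer(hit)
          best <- list(p = p, mis = 0L, spliced = TRUE, L1 = L1,
                       iStart = p + L1, iEnd = a2 - 1L)
        }
      }
    }
    ## soft-trim mismatching overhangs of an imperfect contiguous
    ## placement (e.g. a junction read whose second block is shorter than
    ## the anchor requirement): keep the maximal-scoring subsegment
    qOff <- 0L
    if (!best$spliced && best$mis > 0L) {
      win <- substr(refc, best$p, min(best$p + Lc - 1L, refLen))
      sc <- ifelse(charToRaw(substr(sq, 1L, nchar(win))) ==
                     charToRaw(win), 1L, -1L)
      bestSum <- 0L; curSum <- 0L; curStart <- 1L
      b1 <- 1L; b2 <- 0L
      for (ii in seq_along(sc)) {
        if (curSum <= 0L) {
          curSum <- sc[ii]; curStart <- ii
        } else curSum <- curSum + sc[ii]
        if (curSum > bestSum ||
            (curSum == bestSum && ii - curStart > b2 - b1)) {
          bestSum <- curSum; b1 <- curStart; b2 <- ii
        }
      }
      if (bestSum > 0L && (b1 > 1L || b2 < Lc)) {
        qOff <- b1 - 1L
        best$p <- best$p + qOff
        best$mis <- sum(sc[b1:b2] == -1L)
        best$sufTrim <- b2 < Lc
        Lc <- b2 - b1 + 1L
      }
    }
    if (best$mis > ceiling(maxMismatchRate * Lc)) next
    p <- best$p
    if (best$spliced) {
      tEnd <- best$iEnd + 1L + (Lc - best$L1) - 1L
    } else {
      tEnd <- p + Lc - 1L
    }
    ## re-assign stripped A's that are templated in the reference (not
    ## applicable when the alignment's 3' side was mismatch-trimmed)
    give <- 0L
    avail <- nStrip[i]
    if (strand == "+" && !isTRUE(best$sufTrim)) {
      while (avail > 0L && tEnd + 1L <= refLen &&
             substr(refc, tEnd + 1L, tEnd + 1L) == "A") {
        tEnd <- tEnd + 1L
        avail <- avail - 1L
        give <- give + 1L
      }
    }
    Ltot <- Lc + give
    if (best$spliced) {
      L1 <- best$L1
      rows[[i]] <- data.frame(
        read_id = ids[i], stage = stage[i], strand = strand,
        block = c(1L, 2L),
        q_start = c(1L, L1 + 1L), q_end = c(L1, Ltot),
        t_start = c(p, best$iEnd + 1L),
        t_end = c(best$iStart - 1L, tEnd),
        spliced = TRUE, intron_start = best$iStart,
        intron_end = best$iEnd, clip3 = avail,
        n_mismatch = best$mis, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        read_id = ids[i], stage = stage[i], strand = strand, block = 1L,
        q_start = qOff + 1L, q_end = qOff + Ltot, t_start = p,
        t_end = tEnd, spliced = FALSE, intron_start = NA_integer_,
        intron_end = NA_integer_,
        clip3 = if (isTRUE(best$sufTrim)) 0L else avail,
        n_mismatch = best$mis, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(read_id = character(0), stage = character(0),
                      strand = character(0), block = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      spliced = logical(0), intron_start = integer(0),
                      intron_end = integer(0), clip3 = integer(0),
                      n_mismatch = integer(0))
  rownames(out) <- NULL
  out
}
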