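#' @importFrom Biostrings matchPattern
NULL

.motifCoverage <- function(regionSeq, motifs) {
  n <- nchar(regionSeq)
  cov <- matrix(FALSE, nrow = length(motifs), ncol = n,
                dimnames = list(motifs, NULL))
  for (m in motifs) {
    hits <- gregexpr(m, regionSeq, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      for (h in hits) cov[m, h:(h + nchar(m) - 1L)] <- TRUE
    }
  }
  cov
}

#' Detect telomeric repeat arrays at the chromosome ends
#'
#' Scans a terminal window at each end for the maximal prefix/suffix whose
#' motif purity (fraction of bases covered by exact motif copies) reaches
#' the threshold.  On the forward strand a left telomere is expected to be a
#' CCCTAA array and a right telomere a TTAGGG array.  Terminal partial motif
#' copies are counted fractionally.
#'
#' @param seq The chromosome sequence.
#' @param motifs Telomeric motifs to search for on the forward strand.
#' @param window Maximal terminal window scanned, in bp.
#' @param purityThreshold Minimal motif purity of a reported array.
#' @param minCopies Minimal (fractional) motif copy number of a call.
#' @return data.frame with columns \code{end} (\code{"left"}/\code{"right"}),
#'   \code{start}, \code{stop} (1-based interval), \code{motif},
#'   \code{repeat_count} and \code{purity}.
#' @export
detectTelomeres <- function(seq, motifs = c("TTAGGG", "CCCTAA"),
                            window = 2000L, purityThreshold = 0.8,
                            minCopies = 3L) {
  stopifnot(length(motifs) > 0L)
  seqc <- asChar(seq)
  n <- nchar(seqc)
  w <- min(window, n)
  calls <- list()
  for (side in c("left", "right")) {
    region <- if (side == "left") substr(seqc, 1L, w) else
      substr(seqc, n - w + 1L, n)
    cov <- .motifCoverage(region, motifs)
    any_cov <- colSums(cov) > 0
    ## orient so index 1 is the chromosome terminus
    term <- if (side == "left") any_cov else rev(any_cov)
    purity <- cumsum(term) / seq_along(term)
    Lstar <- if (any(purity >= purityThreshold))
      max(which(purity >= purityThreshold)) else 0L
    if (Lstar == 0L) next
    ## trim the window back to the outermost motif-covered base, so the
    ## reported array does not bleed into adjacent non-telomeric sequence
    covIdx <- which(term[seq_len(Lstar)])
    if (!length(covIdx)) next
    Lstar <- max(covIdx)
    covered <- sum(term[seq_len(Lstar)])
    ## dominant motif within the called window
    covWin <- if (side == "left") cov[, seq_len(Lstar), drop = FALSE] else
      cov[, (w - Lstar + 1L):w, drop = FALSE]
    byMotif <- rowSums(covWin)
    motif <- motifs[which.max(byMotif)]
    ## an eroded terminal copy (suffix of the motif at a left end, prefix
    ## at a right end) counts fractionally
    partial <- 0L
    j <- min(covIdx) - 1L
    if (j > 0L && j < nchar(motif)) {
      termBases <- if (side == "left") substr(region, 1L, j) else
        substr(region, w - j + 1L, w)
      okPart <- if (side == "left")
        termBases == substr(motif, nchar(motif) - j + 1L, nchar(motif))
      else termBases == substr(motif, 1L, j)
      if (okPart) partial <- j
    }
    covered <- covered + partial
    count <- covered / nchar(motif)
    if (count < minCopies) next
    iv <- if (side == "left") c(1L, Lstar) else c(n - Lstar + 1L, n)
    calls[[length(calls) + 1L]] <- data.frame(
      end = side, start = iv[1], stop = iv[2], motif = motif,
      repeat_count = count, purity = covered / Lstar,
      stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(end = character(0), start = integer(0),
                      stop = integer(0), motif = character(0),
                      repeat_count = numeric(0), purity = numeric(0)))
  res <- do.call(rbind, calls)
  ## a sequence that is one telomeric array end to end yields the same
  ## interval from both sides; report it once
  res <- res[!duplicated(res[, c("start", "stop")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}
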