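#' @importFrom IRanges coverage Views viewMeans
NULL

.refKmerIndex <- function(refs, k) {
  idx <- lapply(names(refs), function(rn) {
    L <- nchar(refs[[rn]])
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    data.table(kmer = substring(refs[[rn]], st, st + k - 1L),
               ref = rn, rpos = st)
  })
  idx <- rbindlist(idx)
  setkey(idx, kmer)
  idx
}

#' Map long reads by exact-seed chaining
#'
#' A deliberately simple substitution-tolerant mapper: strided exact k-mer
#' seeds from each read (both orientations) are looked up in a reference
#' k-mer index, seeds voting for the same (reference, strand, diagonal) are
#' chained, and each read is placed at the diagonal with maximal seed
#' support.  Since reads carry substitutions only, an alignment is a single
#' gapless block.  Ties are broken deterministically towards the leftmost
#' reference coordinate.
#'
#' @param reads A \code{\linkS4class{ReadSet}} (or named character vector).
#' @param refs Named character vector / \code{DNAStringSet} of references.
#' @param seedK Seed k-mer size (>= 11).
#' @param minSeedChain Minimal number of chained seeds to accept a mapping.
#' @param stride Seed stride along the read in bp.
#' @return data.frame of alignments: \code{read_id, ref, strand, t_start,
#'   t_end, q_len, n_seeds, n_mismatch}.
#' @export
mapLongReads <- function(reads, refs, seedK = 15L, minSeedChain = 3L,
                         stride = 20L) {
  stopifnot(seedK >= 11L)
  if (!is.character(refs)) refs <- as.character(refs)
  if (length(refs) == 0L) stop("empty reference set")
  if (is.null(names(refs))) stop("refs must be named")
  rseq <- if (is(reads, "ReadSet")) as.character(readSequences(reads)) else
    setNames(as.character(reads), names(reads))
  ids <- names(rseq)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(rseq))
  idx <- .refKmerIndex(refs, seedK)
  refLens <- nchar(refs)

  seedTab <- function(sq, strand) {
    lens <- nchar(sq)
    offs <- lapply(lens, function(L)
      if (L >= seedK) seq(1L, L - seedK + 1L, by = stride) else integer(0))
    nOff <- lengths(offs)
    ri <- rep(seq_along(sq), nOff)
    qoff <- unlist(offs)
    data.table(readi = ri, qoff = qoff,
               kmer = substring(sq[ri], qoff, qoff + seedK - 1L),
               strand = strand)
  }
  fw <- seedTab(rseq, "+")
  rc <- seedTab(revComp(rseq), "-")
  seeds <- rbind(fw, rc)
  hits <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L)
    return(data.frame(read_id = character(0), ref = character(0),
                      strand = character(0), t_start = integer(0),
                      t_end = integer(0), q_len = integer(0),
                      n_seeds = integer(0), n_mismatch = integer(0)))
  hits[, diag := rpos - qoff]
  chains <- hits[, .(n_seeds = .N), by = .(readi, ref, strand, diag)]
  setorder(chains, readi, -n_seeds, ref, diag)
  best <- chains[, .SD[1], by = readi]
  best <- best[n_seeds >= minSeedChain]
  if (nrow(best) == 0L)
    return(data.frame(read_id = character(0), ref = character(0),
                      strand = character(0), t_start = integer(0),
                      t_end = integer(0), q_len = integer(0),
                      n_seeds = integer(0), n_mismatch = integer(0)))

  qlen <- nchar(rseq)[best$readi]
  tS <- pmax(best$diag + 1L, 1L)
  tE <- pmin(best$diag + qlen, refLens[best$ref])
  ## count mismatches of the placed (oriented) read against the reference
  placed <- ifelse(best$strand == "+", rseq[best$readi],
                   revComp(rseq[best$readi]))
  refWin <- substring(refs[best$ref], tS, tE)
  ## clip the read to the reference window (reads shouldn't overhang, but be
  ## safe at reference edges)
  clipL <- tS - (best$diag + 1L)
  placedClip <- substring(placed, 1L + clipL, clipL + (tE - tS + 1L))
  nmis <- vapply(seq_len(nrow(best)), function(i)
    countMismatches(placedClip[i], refWin[i]), numeric(1))
  out <- data.frame(read_id = ids[best$readi], ref = best$ref,
                    strand = best$strand, t_start = tS, t_end = tE,
                    q_len = qlen, n_seeds = best$n_seeds,
                    n_mismatch = as.integer(nmis),
                    stringsAsFactors = FALSE)
  out[order(match(out$read_id, ids)), , drop = FALSE]
}

#' Per-base and binned depth profile of one reference
#'
#' @param alignments data.frame of alignments with \code{ref, t_start,
#'   t_end} columns (one row per aligned block).
#' @param refLengths Named integer vector of reference lengths.
#' @param binSize Bin width in bp for the binned track; the median depth is
#'   computed per base (bin size 1), which is robust at the low background
#'   depths used for desk-scale copy-number estimation.
#' @return Named list of \code{\linkS4class{DepthProfile}} objects, one per
#'   reference in \code{refLengths}.
#' @export
depthProfile <- function(alignments, refLengths, binSize = 100L) {
  stopifnot(binSize >= 1L)
  out <- list()
  for (rn in names(refLengths)) {
    L <- as.integer(refLengths[[rn]])
    al <- alignments[alignments$ref == rn, , drop = FALSE]
    cov <- if (nrow(al) == 0L) Rle(0L, L) else
      coverage(IRanges(al$t_start, al$t_end), width = L)
    nb <- L %/% binSize
    binMeans <- if (nb > 0L) {
      v <- Views(cov, start = (seq_len(nb) - 1L) * binSize + 1L,
                 width = binSize)
      as.numeric(viewMeans(v))
    } else numeric(0)
    med <- .rleMedian(cov)
    out[[rn]] <- new("DepthProfile", refName = rn,
                     binSize = as.integer(binSize), depth = binMeans,
                     medianDepth = med, perBase = cov)
  }
  out
}

## weighted median of an Rle (median per-base depth without expansion)
.rleMedian <- function(x) {
  v <- runValue(x); w <- runLength(x)
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w)
  n <- cw[length(cw)]
  if (n %% 2L == 1L) {
    v[which(cw >= (n + 1) / 2)[1]]
  } else {
    lo <- v[which(cw >= n / 2)[1]]
    hi <- v[which(cw >= n / 2 + 1)[1]]
    (lo + hi) / 2
  }
}

#' Estimate rDNA copy number from median depth ratio
#'
#' The copy number of a multicopy element per haploid genome is the median
#' read depth of the element divided by the pooled median depth of
#' single-copy background references.
#'
#' @param targetProfile \code{DepthProfile} of the multicopy target.
#' @param backgroundProfiles List of background \code{DepthProfile}s.
#' @return A \code{\linkS4class{CopyNumberEstimate}}.
#' @export
estimateCopyNumber <- function(targetProfile, backgroundProfiles) {
  if (length(backgroundProfiles) == 0L)
    stop("at least one background profile required")
  pooled <- do.call(c, unname(lapply(backgroundProfiles,
                                     function(p) p@perBase)))
  bg <- .rleMedian(pooled)
  if (bg <= 0) stop("background median depth is zero")
  tg <- targetProfile@medianDepth
  new("CopyNumberEstimate", targetMedian = tg, backgroundMedian = bg,
      ratio = tg / bg, nBackground = length(backgroundProfiles))
}
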