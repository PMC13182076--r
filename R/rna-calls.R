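#' Call splice junctions from spliced tag-read alignments
#'
#' One call per distinct reference gap (donor = first intron base,
#' acceptor = first exon base after the intron, 1-based), with read
#' support.  A junction is flagged \code{perfect_ligation} when its gap
#' matches an annotated intron exactly, i.e. the flanking exon sequences
#' are ligated precisely at the annotated boundaries.
#'
#' @param alignments Output of \code{\link{mapTagReads}}.
#' @param introns Annotated candidate introns (\code{GRanges} with
#'   \code{ID}, or data.frame with \code{start}, \code{end}, \code{ID}).
#' @return data.frame: \code{donor, acceptor, width, support,
#'   perfect_ligation, intron_id}.
#' @export
callJunctions <- function(alignments, introns = NULL) {
  sp <- alignments[alignments$spliced & alignments$block == 1L, ,
                   drop = FALSE]
  if (nrow(sp) == 0L)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      width = integer(0), support = integer(0),
                      perfect_ligation = logical(0),
                      intron_id = character(0)))
  key <- paste(sp$intron_start, sp$intron_end)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  donor <- as.integer(parts[, 1])
  accEnd <- as.integer(parts[, 2])
  out <- data.frame(donor = donor, acceptor = accEnd + 1L,
                    width = accEnd - donor + 1L,
                    support = as.integer(tab),
                    perfect_ligation = FALSE,
                    intron_id = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(introns)) {
    idf <- if (is(introns, "GRanges"))
      data.frame(start = start(introns), end = end(introns),
                 ID = mcols(introns)$ID, stringsAsFactors = FALSE)
    else as.data.frame(introns)
    m <- match(paste(out$donor, out$acceptor - 1L),
               paste(idf$start, idf$end))
    out$perfect_ligation <- !is.na(m)
    out$intron_id[!is.na(m)] <- idf$ID[m[!is.na(m)]]
  }
  out[order(out$donor), , drop = FALSE]
}

#' Call poly(A) sites from soft-clipped untemplated A-tails
#'
#' Alignment 3' ends carrying at least \code{minA} untemplated adenosines
#' are clustered (radius \code{radius} bp); clusters with support below
#' \code{minSupport} are discarded.  The reported position is the most
#' supported last-templated-base position in the cluster.
#'
#' @param alignments Output of \code{\link{mapTagReads}}.
#' @param minA Minimal untemplated tail length in nt.
#' @param radius Clustering radius in bp.
#' @param minSupport Minimal reads per reported site.
#' @return data.frame: \code{position, support, mean_tail_len}.
#' @export
callPolyA <- function(alignments, minA = 10L, radius = 5L,
                      minSupport = 2L) {
  last <- alignments[order(alignments$read_id, -alignments$block), ,
                     drop = FALSE]
  last <- last[!duplicated(last$read_id), , drop = FALSE]
  tails <- last[last$clip3 >= minA, , drop = FALSE]
  empty <- data.frame(position = integer(0), support = integer(0),
                      mean_tail_len = numeric(0))
  if (nrow(tails) == 0L) return(empty)
  o <- order(tails$t_end)
  pos <- tails$t_end[o]
  clip <- tails$clip3[o]
  cl <- cumsum(c(1L, diff(pos) > radius))
  res <- lapply(split(seq_along(pos), cl), function(ix) {
    tb <- table(pos[ix])
    data.frame(position = as.integer(names(tb)[which.max(tb)]),
               support = length(ix), mean_tail_len = mean(clip[ix]))
  })
  res <- do.call(rbind, res)
  res <- res[res$support >= minSupport, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.regionOf <- function(truth, id) {
  i <- which(mcols(truth)$ID == id)
  if (!length(i)) NULL else c(start(truth)[i[1]], end(truth)[i[1]])
}

#' Classify tag reads into transcript species
#'
#' Reads are partitioned by their defining evidence: the I51 exon-exon
#' junction marks the mature homing-endonuclease mRNA (RNA3); unspliced
#' coverage of the I51 interior marks the unprocessed polyadenylated HEG
#' transcript (RNA2); the S956 exon-exon junction (or SSU exon placement)
#' marks the ligated SSU rRNA (RNA1); L1949/L2449 junctions or 26S exon
#' placement mark the ligated 26S rRNA; 5.8S and ETS placements mark the
#' remaining species.  HEG reads carrying no I51-informative evidence
#' cannot distinguish RNA2 from RNA3 and are counted as ambiguous, as are
#' reads with conflicting evidence.
#'
#' @param alignments Output of \code{\link{mapTagReads}}.
#' @param truth Annotation \code{GRanges} carrying the gene model (IDs
#'   \code{SSU_exon1/2}, \code{5.8S}, \code{26S_exon1..3}, \code{HEG},
#'   \code{I51}, \code{ETS}).
#' @param polya Optional \code{\link{callPolyA}} output (species-level
#'   presence of the polyadenylated species requires a called site).
#' @param minA Minimal untemplated tail to treat a read as polyadenylated.
#' @param minOverlap Minimal overlap (bp) with the I51 interior for a read
#'   to count as evidence of intron retention; grazing overlaps shorter
#'   than an anchor are uninformative.
#' @return List with \code{counts} (species x stage matrix, including an
#'   \code{ambiguous} row), \code{present} (named logical vector of
#'   species-level presence) and \code{reads} (per-read labels).
#' @export
classifySpecies <- function(alignments, truth, polya = NULL, minA = 10L,
                            minOverlap = 8L) {
  i51 <- .regionOf(truth, "I51")
  heg <- .regionOf(truth, "HEG")
  e58 <- .regionOf(truth, "5.8S")
  ets <- .regionOf(truth, "ETS")
  ssu <- rbind(.regionOf(truth, "SSU_exon1"), .regionOf(truth, "SSU_exon2"))
  l26 <- rbind(.regionOf(truth, "26S_exon1"), .regionOf(truth, "26S_exon2"),
               .regionOf(truth, "26S_exon3"))
  inReg <- function(s, e, reg) {
    if (is.null(reg)) return(rep(FALSE, length(s)))
    ok <- rep(FALSE, length(s))
    for (r in seq_len(nrow(reg)))
      ok <- ok | (s <= reg[r, 2] & e >= reg[r, 1])
    ok
  }
  dt <- as.data.table(alignments)
  span <- as.data.frame(dt[, .(
    stage = stage[1], s = min(t_start), e = max(t_end),
    intron_id_start = intron_start[1], intron_id_end = intron_end[1],
    spliced = any(spliced), clip3 = max(clip3)), by = read_id])
  jName <- rep(NA_character_, nrow(span))
  if (!is.null(i51))
    jName[span$spliced & span$intron_id_start == i51[1] &
            span$intron_id_end == i51[2]] <- "I51"
  for (id in c("S956-1", "L1949", "L2449")) {
    reg <- .regionOf(truth, id)
    if (!is.null(reg))
      jName[span$spliced & span$intron_id_start == reg[1] &
              span$intron_id_end == reg[2]] <- id
  }
  coversI51interior <- if (is.null(i51)) rep(FALSE, nrow(span)) else
    !span$spliced & span$s <= i51[2] - (minOverlap - 1L) &
    span$e >= i51[1] + (minOverlap - 1L)

  lab <- rep("unassigned", nrow(span))
  lab[inReg(span$s, span$e, l26)] <- "rRNA_26S"
  lab[inReg(span$s, span$e, rbind(e58))] <- "rRNA_5.8S"
  lab[inReg(span$s, span$e, rbind(ets))] <- "ETS_fragment"
  lab[inReg(span$s, span$e, ssu)] <- "RNA1"
  if (!is.null(heg)) {
    inHeg <- span$s >= heg[1] & span$e <= heg[2]
    lab[inHeg] <- "ambiguous"          # RNA2/RNA3 indistinguishable
    lab[inHeg & coversI51interior] <- "RNA2"
  }
  lab[!is.na(jName) & jName == "S956-1"] <- "RNA1"
  lab[!is.na(jName) & jName %in% c("L1949", "L2449")] <- "rRNA_26S"
  lab[!is.na(jName) & jName == "I51"] <- "RNA3"
  ## conflicting evidence: an I51 junction read must not also cover the
  ## I51 interior
  lab[!is.na(jName) & jName == "I51" & coversI51interior] <- "ambiguous"

  species <- c("RNA1", "RNA2", "RNA3", "rRNA_5.8S", "rRNA_26S",
               "ETS_fragment", "ambiguous", "unassigned")
  stages <- unique(span$stage)
  counts <- matrix(0L, nrow = length(species), ncol = length(stages),
                   dimnames = list(species, stages))
  tb <- table(factor(lab, levels = species), factor(span$stage,
                                                    levels = stages))
  counts[rownames(tb), colnames(tb)] <- as.integer(tb)

  hasPolyA <- !is.null(polya) && nrow(polya) > 0L
  present <- c(
    RNA1 = sum(counts["RNA1", ]) > 0L,
    RNA2 = hasPolyA && sum(counts["RNA2", ]) > 0L,
    RNA3 = hasPolyA && sum(counts["RNA3", ]) > 0L,
    rRNA_5.8S = sum(counts["rRNA_5.8S", ]) > 0L,
    rRNA_26S = sum(counts["rRNA_26S", ]) > 0L,
    ETS_fragment = sum(counts["ETS_fragment", ]) > 0L)
  list(counts = counts, present = present,
       reads = data.frame(read_id = span$read_id, stage = span$stage,
                          label = lab, stringsAsFactors = FALSE))
}

#' Per-stage and pooled coverage tracks
#'
#' Per-base coverage of aligned blocks, per life stage and pooled, with a
#' log10(x + 1) display transform (RNA coverage spans orders of magnitude
#' between rRNA and mRNA species).
#'
#' @param alignments Output of \code{\link{mapTagReads}}.
#' @param refLength Reference length in bp.
#' @return Named list (one element per stage plus \code{"pooled"}), each
#'   with \code{coverage} (an \code{Rle}) and \code{log10} (numeric).
#' @export
coverageTracks <- function(alignments, refLength) {
  refLength <- as.integer(refLength)
  stages <- unique(alignments$stage)
  stages <- stages[!is.na(stages)]
  out <- list()
  covOf <- function(d) {
    if (nrow(d) == 0L) Rle(0L, refLength) else
      coverage(IRanges(d$t_start, pmin(d$t_end, refLength)),
               width = refLength)
  }
  for (stg in stages) {
    cov <- covOf(alignments[!is.na(alignments$stage) &
                              alignments$stage == stg, , drop = FALSE])
    out[[stg]] <- list(coverage = cov,
                       log10 = log10(as.numeric(cov) + 1))
  }
  pooled <- covOf(alignments)
  out[["pooled"]] <- list(coverage = pooled,
                          log10 = log10(as.numeric(pooled) + 1))
  out
}

#' Descriptive coverage peaks
#'
#' Maximal runs where coverage reaches \code{fold} times the local median
#' (median over a centered window), reported descriptively without a
#' species label.
#'
#' @param cov Coverage \code{Rle}.
#' @param fold Enrichment factor over the local median.
#' @param flank Half-width of the local-median window in bp.
#' @return data.frame of \code{start, end, max_cov}.
#' @export
enrichedPeaks <- function(cov, fold = 5, flank = 500L) {
  v <- as.numeric(cov)
  n <- length(v)
  k <- min(2L * flank + 1L, if (n %% 2L == 1L) n else n - 1L)
  loc <- stats::runmed(v, k, endrule = "median")
  hot <- v >= fold * pmax(loc, 1)
  if (!any(hot))
    return(data.frame(start = integer(0), end = integer(0),
                      max_cov = numeric(0)))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             max_cov = vapply(which(keep), function(i)
               max(v[starts[i]:ends[i]]), numeric(1)))
}
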