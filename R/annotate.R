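#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

## type compatibility used when matching detector calls against truth:
## a call of a given type may recover truth features of these types
.TYPE_COMPAT <- list(
  telomere = "telomere",
  tandem_array = c("tandem_array", "UPR", "telomere"),
  palindrome = "palindrome",
  motif_hit = c("PRO", "motif_hit"),
  exon = "exon", intron = "intron",
  spliceosomal_intron = "spliceosomal_intron",
  polyA_site = "polyA_site",
  transcription_start = "transcription_start",
  transcription_terminator = "transcription_terminator",
  ETS = "ETS", ITS1 = "ITS1", ITS2 = "ITS2", trailer = "trailer",
  gene = "gene", UPR = "UPR", PRO = "PRO"
)

.DEFAULT_COMPARE_TYPES <- c(
  "telomere", "palindrome", "tandem_array", "UPR", "PRO", "exon", "intron",
  "spliceosomal_intron", "polyA_site", "transcription_start",
  "transcription_terminator", "ETS", "ITS1", "ITS2", "trailer", "gene")

#' Assemble detector and RNA-evidence calls into a feature annotation
#'
#' Merges blind repeat-architecture calls (telomeres, palindromes, tandem
#' arrays, motif hits) with RNA processing evidence into one coherent
#' annotation: introns are inferred from perfect-ligation junctions, exons
#' as their complement within the gene spans of the supplied gene model,
#' the transcription start from the 5'-most RNA coverage onset, and the
#' transcribed spacers (ETS/ITS1/ITS2/trailer) as the remaining gaps of the
#' transcription unit.  Overlapping repeat calls are kept nested, not
#' merged.
#'
#' @param chromLength Chromosome length in bp.
#' @param telomeres Output of \code{\link{detectTelomeres}}.
#' @param palindromes Output of \code{\link{callPalindromes}}.
#' @param arrays Output of \code{\link{findTandemArrays}}.
#' @param motifHits data.frame of motif hits (\code{start, end, strand},
#'   optional \code{name}), e.g. replication-origin matches from
#'   \code{\link{longestExactMatch}} lifted to chromosome coordinates.
#' @param junctions Output of \code{\link{callJunctions}}.
#' @param polya Output of \code{\link{callPolyA}}.
#' @param geneModel \code{GRanges} of gene spans (type \code{"gene"}), e.g.
#'   the gene-level rows of the truth annotation or an external homology-
#'   based model.
#' @param coverage Pooled RNA coverage \code{Rle} (used for the
#'   transcription start).
#' @param tt Transcription terminator position; when \code{NULL}, the 3'
#'   end of RNA coverage is used and flagged as inferred.
#' @param spliceosomalIds Intron ids (of \code{junctions$intron_id}) to be
#'   typed as spliceosomal rather than group I.
#' @param chromName Chromosome name for the output \code{GRanges}.
#' @return A sorted \code{GRanges} with \code{type}/\code{ID} metadata.
#' @export
assembleAnnotation <- function(chromLength, telomeres = NULL,
                               palindromes = NULL, arrays = NULL,
                               motifHits = NULL, junctions = NULL,
                               polya = NULL, geneModel = NULL,
                               coverage = NULL, tt = NULL,
                               spliceosomalIds = "I51",
                               chromName = "rDNA") {
  feats <- list(.feat("chromosome", 1L, chromLength, "chromosome"))

  ts <- NA_integer_
  if (!is.null(coverage)) {
    nz <- which(as.numeric(coverage) > 0)
    if (length(nz)) ts <- nz[1]
  }
  if (!is.na(ts))
    feats[[length(feats) + 1L]] <- .feat("transcription_start", ts, ts, "Ts")
  ttInferred <- FALSE
  if (is.null(tt) && !is.null(coverage)) {
    nz <- which(as.numeric(coverage) > 0)
    if (length(nz)) {
      tt <- nz[length(nz)]
      ttInferred <- TRUE
    }
  }
  if (!is.null(tt))
    feats[[length(feats) + 1L]] <- .feat("transcription_terminator", tt, tt,
                                         "tt", inferred = ttInferred)

  ## introns from perfect-ligation junctions
  intr <- NULL
  if (!is.null(junctions) && nrow(junctions)) {
    p <- junctions[junctions$perfect_ligation, , drop = FALSE]
    if (nrow(p)) {
      intr <- data.frame(start = p$donor, end = p$acceptor - 1L,
                         ID = ifelse(is.na(p$intron_id),
                                     sprintf("intron_%d", p$donor),
                                     p$intron_id),
                         stringsAsFactors = FALSE)
      for (i in seq_len(nrow(intr))) {
        if (intr$end[i] < intr$start[i])
          stop(sprintf("junction at %d implies a negative-length intron",
                       intr$start[i]))
        ty <- if (intr$ID[i] %in% spliceosomalIds) "spliceosomal_intron"
        else "intron"
        feats[[length(feats) + 1L]] <- .feat(ty, intr$start[i], intr$end[i],
                                             intr$ID[i])
      }
    }
  }

  ## exons: complement of (maximal, non-nested) introns within gene spans
  geneBounds <- NULL
  if (!is.null(geneModel) && length(geneModel)) {
    gdf <- data.frame(start = start(geneModel), end = end(geneModel),
                      ID = mcols(geneModel)$ID, stringsAsFactors = FALSE)
    geneBounds <- gdf
    for (gi in seq_len(nrow(gdf))) {
      gs <- gdf$start[gi]; ge <- gdf$end[gi]
      feats[[length(feats) + 1L]] <- .feat("gene", gs, ge, gdf$ID[gi])
      gintr <- if (is.null(intr)) NULL else
        intr[intr$start >= gs & intr$end <= ge, , drop = FALSE]
      if (!is.null(gintr) && nrow(gintr)) {
        ## keep maximal introns only (a spliceosomal intron nested inside a
        ## group I intron does not break the rRNA exon structure)
        gintr <- gintr[order(-(gintr$end - gintr$start)), , drop = FALSE]
        keep <- rep(TRUE, nrow(gintr))
        for (i in seq_len(nrow(gintr))[-1])
          for (j in which(keep[seq_len(i - 1L)]))
            if (gintr$start[i] >= gintr$start[j] &&
                gintr$end[i] <= gintr$end[j]) {
              keep[i] <- FALSE
              break
            }
        gintr <- gintr[keep, , drop = FALSE]
        gintr <- gintr[order(gintr$start), , drop = FALSE]
        cur <- gs
        for (i in seq_len(nrow(gintr))) {
          if (gintr$start[i] <= cur)
            stop(sprintf(
              "junction at %d implies a negative-length exon in gene %s",
              gintr$start[i], gdf$ID[gi]))
          feats[[length(feats) + 1L]] <- .feat(
            "exon", cur, gintr$start[i] - 1L,
            sprintf("%s_exon%d", gdf$ID[gi], i))
          cur <- gintr$end[i] + 1L
        }
        if (cur > ge)
          stop(sprintf("introns exceed gene span in gene %s", gdf$ID[gi]))
        feats[[length(feats) + 1L]] <- .feat(
          "exon", cur, ge, sprintf("%s_exon%d", gdf$ID[gi],
                                   nrow(gintr) + 1L))
      } else {
        feats[[length(feats) + 1L]] <- .feat(
          "exon", gs, ge, sprintf("%s_exon1", gdf$ID[gi]))
      }
    }
  }

  ## transcribed spacers from the gaps between Ts, genes and tt
  if (!is.null(geneBounds) && nrow(geneBounds) && !is.na(ts)) {
    gdf <- geneBounds[order(geneBounds$start), , drop = FALSE]
    if (gdf$start[1] > ts)
      feats[[length(feats) + 1L]] <- .feat("ETS", ts, gdf$start[1] - 1L,
                                           "ETS")
    spacerNames <- c("ITS1", "ITS2")
    for (i in seq_len(nrow(gdf) - 1L)) {
      if (gdf$start[i + 1L] > gdf$end[i] + 1L) {
        nmS <- if (i <= length(spacerNames)) spacerNames[i] else
          sprintf("spacer_%d", i)
        feats[[length(feats) + 1L]] <- .feat(
          nmS, gdf$end[i] + 1L, gdf$start[i + 1L] - 1L, nmS)
      }
    }
    if (!is.null(tt) && tt > gdf$end[nrow(gdf)])
      feats[[length(feats) + 1L]] <- .feat(
        "trailer", gdf$end[nrow(gdf)] + 1L, tt, "trailer")
  }

  if (!is.null(polya) && nrow(polya))
    for (i in seq_len(nrow(polya)))
      feats[[length(feats) + 1L]] <- .feat(
        "polyA_site", polya$position[i], polya$position[i],
        sprintf("polyA_%d", polya$position[i]), support = polya$support[i])

  if (!is.null(telomeres) && nrow(telomeres))
    for (i in seq_len(nrow(telomeres)))
      feats[[length(feats) + 1L]] <- .feat(
        "telomere", telomeres$start[i], telomeres$stop[i],
        paste0("telomere_", telomeres$end[i]), motif = telomeres$motif[i])

  if (!is.null(palindromes) && nrow(palindromes))
    for (i in seq_len(nrow(palindromes)))
      feats[[length(feats) + 1L]] <- .feat(
        "palindrome", palindromes$left_start[i], palindromes$right_end[i],
        sprintf("palindrome_%d", palindromes$left_start[i]),
        arm_length = palindromes$left_end[i] - palindromes$left_start[i] + 1L,
        loop_length = palindromes$loop[i],
        half_identity = palindromes$half_identity[i])

  if (!is.null(arrays) && nrow(arrays))
    for (i in seq_len(nrow(arrays)))
      feats[[length(feats) + 1L]] <- .feat(
        "tandem_array", arrays$start[i], arrays$end[i],
        sprintf("array_%d", arrays$start[i]),
        unit_length = arrays$unit_length[i], copies = arrays$copies[i])

  if (!is.null(motifHits) && nrow(motifHits))
    for (i in seq_len(nrow(motifHits)))
      feats[[length(feats) + 1L]] <- .feat(
        "motif_hit", motifHits$start[i], motifHits$end[i],
        if (!is.null(motifHits$name)) motifHits$name[i] else
          sprintf("motif_%d", motifHits$start[i]),
        strand = if (!is.null(motifHits$strand)) motifHits$strand[i] else "+")

  df <- .bindFeats(feats)
  gr <- .featsToGRanges(df, chromName, chromLength)
  gr[order(start(gr), end(gr))]
}

#' Segment-length bookkeeping table
#'
#' Computes the architectural length table from an assembled annotation:
#' ETS; mature SSU (19S) length as SSU gene span minus the group I intron
#' inferred inside it; the S956-1 and I51 intron lengths; 5.8S; mature 26S
#' as gene span minus L1949/L2449; the transcription-unit length tt - Ts;
#' and the chromosome length.  Lengths are reported in bp alongside a kb
#' rendering rounded half-away-from-zero to one decimal.
#'
#' @param features Assembled annotation \code{GRanges} (from
#'   \code{\link{assembleAnnotation}}).
#' @return data.frame with \code{feature}, \code{bp} and \code{kb} columns;
#'   entries that cannot be computed are \code{NA}.
#' @export
segmentLengths <- function(features) {
  ty <- mcols(features)$type
  id <- mcols(features)$ID
  get1 <- function(theId) {
    i <- which(id == theId)
    if (!length(i)) NULL else c(start(features)[i[1]], end(features)[i[1]])
  }
  w <- function(x) if (is.null(x)) NA_integer_ else x[2] - x[1] + 1L
  spanOf <- function(theId) w(get1(theId))

  ssu <- get1("SSU_rRNA_gene")
  l26 <- get1("26S_rRNA_gene")
  intronsIn <- function(gene) {
    if (is.null(gene)) return(0L)
    i <- which(ty == "intron" & start(features) >= gene[1] &
                 end(features) <= gene[2])
    if (!length(i)) 0L else sum(width(features)[i])
  }
  ets <- spanOf("ETS")
  s956 <- spanOf("S956-1")
  i51 <- spanOf("I51")
  ts <- get1("Ts"); tt <- get1("tt")
  tu <- if (is.null(ts) || is.null(tt)) NA_integer_ else tt[1] - ts[1] + 1L
  chrom <- spanOf("chromosome")
  mat19 <- if (is.null(ssu)) NA_integer_ else w(ssu) - intronsIn(ssu)
  mat26 <- if (is.null(l26)) NA_integer_ else w(l26) - intronsIn(l26)

  bp <- c(ETS = ets, `19S` = mat19, `S956-1` = s956, I51 = i51,
          `5.8S` = spanOf("5.8S_rRNA_gene"), `26S` = mat26,
          transcription_unit = tu, chromosome = chrom)
  data.frame(feature = names(bp), bp = as.integer(bp),
             kb = sprintf("%.1f", roundHalfUp(as.numeric(bp) / 1000, 1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score an assembled annotation against the ground truth
#'
#' Matches calls to truth features of compatible type by interval overlap;
#' a truth feature is \emph{recovered} when some compatible call agrees at
#' both boundaries within \code{tolerance} bp, \emph{boundary-shifted} when
#' only overlap is achieved, and \emph{missed} otherwise.  Calls with no
#' compatible overlapping truth feature are \emph{spurious}.  Precision is
#' the fraction of non-spurious calls, recall the fraction of recovered
#' truth features.
#'
#' @param calls Assembled annotation \code{GRanges}.
#' @param truth Truth \code{GRanges} from \code{\link{buildChromosome}}.
#' @param tolerance Boundary tolerance in bp.
#' @param types Truth feature types included in the comparison.
#' @return List with \code{precision}, \code{recall}, \code{truthStatus}
#'   (per-truth-feature data.frame with status and boundary shift) and
#'   \code{callStatus} (per-call data.frame).
#' @export
compareToTruth <- function(calls, truth, tolerance = 10L,
                           types = .DEFAULT_COMPARE_TYPES) {
  tdf <- data.frame(start = start(truth), end = end(truth),
                    type = as.character(mcols(truth)$type),
                    ID = as.character(mcols(truth)$ID),
                    stringsAsFactors = FALSE)
  tdf <- tdf[tdf$type %in% types, , drop = FALSE]
  cdf <- data.frame(start = start(calls), end = end(calls),
                    type = as.character(mcols(calls)$type),
                    ID = as.character(mcols(calls)$ID),
                    stringsAsFactors = FALSE)
  cdf <- cdf[vapply(cdf$type, function(x)
    any(.TYPE_COMPAT[[x]] %in% types), logical(1)), , drop = FALSE]

  compatOK <- function(callType, truthType)
    truthType %in% (.TYPE_COMPAT[[callType]] %||% callType)

  status <- character(nrow(tdf))
  shift <- rep(NA_integer_, nrow(tdf))
  callTrue <- rep(FALSE, nrow(cdf))
  for (i in seq_len(nrow(tdf))) {
    ov <- which(cdf$start <= tdf$end[i] & cdf$end >= tdf$start[i] &
                  vapply(cdf$type, compatOK, logical(1),
                         truthType = tdf$type[i]))
    if (!length(ov)) {
      status[i] <- "missed"
      next
    }
    callTrue[ov] <- TRUE
    d <- pmax(abs(cdf$start[ov] - tdf$start[i]),
              abs(cdf$end[ov] - tdf$end[i]))
    shift[i] <- min(d)
    status[i] <- if (min(d) <= tolerance) "recovered" else
      "boundary_shifted"
  }
  ## a call is true if it overlaps any compatible truth feature
  for (j in seq_len(nrow(cdf))) {
    if (callTrue[j]) next
    ov <- any(tdf$start <= cdf$end[j] & tdf$end >= cdf$start[j] &
                vapply(tdf$type, function(tt2)
                  compatOK(cdf$type[j], tt2), logical(1)))
    callTrue[j] <- ov
  }
  list(precision = if (nrow(cdf)) mean(callTrue) else NA_real_,
       recall = if (nrow(tdf)) mean(status == "recovered") else NA_real_,
       truthStatus = data.frame(ID = tdf$ID, type = tdf$type,
                                status = status, shift = shift,
                                stringsAsFactors = FALSE),
       callStatus = data.frame(ID = cdf$ID, type = cdf$type,
                               status = ifelse(callTrue, "true",
                                               "spurious"),
                               stringsAsFactors = FALSE))
}
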