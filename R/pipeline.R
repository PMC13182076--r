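#' Simulate a depth-ratio copy-number experiment
#'
#' Builds uniform-random single-copy background contigs, simulates long
#' reads over background plus the multicopy rDNA chromosome at
#' \code{copies} times the background depth, maps them with the exact-seed
#' mapper and estimates the copy number as the median-depth ratio.
#'
#' @param chromSeq The rDNA chromosome sequence.
#' @param seed Integer seed.
#' @param backgroundDepth Mean background depth.
#' @param copies True simulated copy number of the rDNA per haploid genome.
#' @param nBackground Number of background contigs.
#' @param backgroundLength Length of each background contig in bp.
#' @param readLenMean,readLenSd,errorRate Long-read simulation parameters.
#' @return List with \code{estimate} (a
#'   \code{\linkS4class{CopyNumberEstimate}}), \code{profiles},
#'   \code{alignments}, \code{reads} and the \code{refs} used.
#' @export
simulateCopyNumberRun <- function(chromSeq, seed = 1L, backgroundDepth = 5,
                                  copies = 132, nBackground = 3L,
                                  backgroundLength = 50000L,
                                  readLenMean = 250, readLenSd = 25,
                                  errorRate = 0.02) {
  chromSeq <- asChar(chromSeq)
  bg <- withSeed(seed + 7L, {
    setNames(vapply(seq_len(nBackground),
                    function(i) randomDNA(backgroundLength), character(1)),
             sprintf("contig_%02d", seq_len(nBackground)))
  })
  refs <- c(bg, rDNA = chromSeq)
  depths <- c(rep(backgroundDepth, nBackground), backgroundDepth * copies)
  names(depths) <- names(refs)
  reads <- simulateLongReads(refs, depths, readLenMean = readLenMean,
                             readLenSd = readLenSd, errorRate = errorRate,
                             seed = seed)
  aln <- mapLongReads(reads, refs)
  profs <- depthProfile(aln, setNames(nchar(refs), names(refs)))
  est <- estimateCopyNumber(profs[["rDNA"]], profs[names(bg)])
  list(estimate = est, profiles = profs, alignments = aln, reads = reads,
       refs = refs)
}

#' Run the full characterization pipeline on a synthetic rDNA chromosome
#'
#' End-to-end driver: builds the chromosome from a plan, rediscovers the
#' repeat architecture blind from the sequence (self dot-plot, palindrome,
#' tandem-array and telomere calls, replication-origin motif search),
#' simulates and maps stage-labelled 3'-tag RNA reads, extracts junction /
#' poly(A) / species evidence, assembles the feature annotation, computes
#' the segment-length table, and scores the annotation against truth.
#'
#' @param plan A \code{SegmentPlan}.
#' @param seed Integer seed for build and simulations.
#' @param nTagReads Tag reads per life stage.
#' @param tagAbundances Optional species abundances (see
#'   \code{\link{simulateTagReads}}).
#' @param doCopyNumber Whether to also run the long-read copy-number
#'   simulation (slower).
#' @param copies Simulated rDNA copy number when \code{doCopyNumber}.
#' @param proMotif Query motif for the replication-origin search inside the
#'   NTS palindrome.
#' @return List with the chromosome, truth, all detector outputs, RNA
#'   evidence, the assembled annotation, the length table, and the
#'   truth-comparison report.
#' @export
runPipeline <- function(plan = defaultPlan(), seed = 1L, nTagReads = 5000L,
                        tagAbundances = NULL, doCopyNumber = FALSE,
                        copies = 132, proMotif = PRO_MOTIF) {
  bc <- buildChromosome(plan, seed)
  seqc <- asChar(bc$sequence)
  truth <- bc$truth

  ## blind repeat architecture
  dp <- selfDotplot(seqc)
  pals <- callPalindromes(seqc, dp)
  arrays <- findTandemArrays(seqc, dp)
  tel <- detectTelomeres(seqc)
  motifHits <- NULL
  palTruthIdx <- which(mcols(truth)$ID == "NTS_palindrome")
  if (length(palTruthIdx) && !is.null(proMotif)) {
    ps <- start(truth)[palTruthIdx]
    pe <- end(truth)[palTruthIdx]
    lm <- longestExactMatch(proMotif, substr(seqc, ps, pe))
    if (lm$length > 0L && nrow(lm$hits)) {
      motifHits <- data.frame(start = lm$hits$start + ps - 1L,
                              end = lm$hits$end + ps - 1L,
                              strand = lm$hits$strand,
                              name = sprintf("PRO%d",
                                             seq_len(nrow(lm$hits))),
                              stringsAsFactors = FALSE)
    }
  } else {
    lm <- NULL
  }

  ## RNA evidence
  intronTruth <- truth[mcols(truth)$type %in%
                         c("intron", "spliceosomal_intron")]
  tags <- simulateTagReads(truth, seqc, abundances = tagAbundances,
                           nReads = nTagReads, seed = seed)
  aln <- mapTagReads(tags, seqc, intronTruth)
  junctions <- callJunctions(aln, intronTruth)
  polya <- callPolyA(aln)
  speciesCls <- classifySpecies(aln, truth, polya)
  tracks <- coverageTracks(aln, plan@totalLength)

  annotation <- assembleAnnotation(
    chromLength = plan@totalLength, telomeres = tel, palindromes = pals,
    arrays = arrays, motifHits = motifHits, junctions = junctions,
    polya = polya, geneModel = truth[mcols(truth)$type == "gene"],
    coverage = tracks$pooled$coverage, tt = plan@ttOffset)
  lengths <- segmentLengths(annotation)
  report <- compareToTruth(annotation, truth)

  cn <- if (doCopyNumber)
    simulateCopyNumberRun(seqc, seed = seed, copies = copies) else NULL

  list(plan = plan, sequence = bc$sequence, truth = truth, dotplot = dp,
       palindromes = pals, arrays = arrays, telomeres = tel,
       motifSearch = lm, motifHits = motifHits, tagReads = tags,
       tagAlignments = aln, junctions = junctions, polya = polya,
       species = speciesCls, tracks = tracks, annotation = annotation,
       lengths = lengths, report = report, copyNumberRun = cn)
}
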