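#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @importFrom S4Vectors Rle runValue runLength
NULL

#' SegmentPlan: parametrized layout of a synthetic rDNA chromosome
#'
#' An ordered list of segment specifications (telomeres, the NTS palindrome,
#' direct-repeat arrays, the UPR, and the pieces of the rRNA transcription
#' unit), doubling as the ground truth the detectors are scored against.
#' Each segment is a list with elements \code{name}, \code{length} and
#' \code{params}.
#'
#' @slot segments Ordered list of segment specifications.
#' @slot totalLength Chromosome length in bp.
#' @slot tsOffset 1-based chromosome position of the transcription start.
#' @slot ttOffset 1-based chromosome position of the transcription terminator.
#' @slot seed Default integer seed used by \code{\link{buildChromosome}}.
#' @export
setClass("SegmentPlan", representation(
  segments = "list",
  totalLength = "integer",
  tsOffset = "integer",
  ttOffset = "integer",
  seed = "integer"
))

setValidity("SegmentPlan", function(object) {
  segs <- object@segments
  if (length(segs) == 0L) return("plan has no segments")
  nm <- vapply(segs, `[[`, character(1), "name")
  len <- vapply(segs, `[[`, numeric(1), "length")
  if (anyDuplicated(nm)) return("segment names must be unique")
  if (any(len <= 0)) return("all segment lengths must be > 0")
  if (sum(len) != object@totalLength)
    return(sprintf("segment lengths sum to %d, not totalLength %d",
                   sum(len), object@totalLength))
  if (object@tsOffset < 1L || object@ttOffset > object@totalLength ||
      object@tsOffset > object@ttOffset)
    return("tsOffset/ttOffset out of range")
  TRUE
})

#' ReadSet: simulated sequencing reads plus per-read ground truth
#'
#' @slot reads A \code{DNAStringSet}, one entry per read, named by read id.
#' @slot origin Either \code{"dna_long"} or \code{"rna_tag"}.
#' @slot info data.frame of per-read truth metadata recorded by the
#'   simulator (origin coordinates, transcript species, stage, untemplated
#'   tail length, ...), used by downstream oracles.
#' @slot seed Integer seed the reads were generated with.
#' @export
setClass("ReadSet", representation(
  reads = "DNAStringSet",
  origin = "character",
  info = "data.frame",
  seed = "integer"
))

setValidity("ReadSet", function(object) {
  if (!object@origin %in% c("dna_long", "rna_tag"))
    return("origin must be 'dna_long' or 'rna_tag'")
  if (length(object@reads) != nrow(object@info))
    return("info must have one row per read")
  ids <- names(object@reads)
  if (is.null(ids) || anyDuplicated(ids)) return("read ids must be unique")
  TRUE
})

#' DepthProfile: per-base and binned read coverage of one reference
#'
#' @slot refName Reference sequence name.
#' @slot binSize Bin width in bp used for the binned track.
#' @slot depth Per-bin mean coverage (complete bins only).
#' @slot medianDepth Median per-base depth over the reference.
#' @slot perBase Per-base coverage as an \code{Rle}.
#' @export
setClass("DepthProfile", representation(
  refName = "character",
  binSize = "integer",
  depth = "numeric",
  medianDepth = "numeric",
  perBase = "Rle"
))

#' CopyNumberEstimate: depth-ratio estimate of rDNA copy number
#'
#' The copy number of a multicopy element per haploid genome is estimated as
#' the ratio of its median read depth to the pooled median depth of
#' single-copy background contigs.
#'
#' @slot targetMedian Median depth of the target (rDNA) reference.
#' @slot backgroundMedian Pooled median depth of the background contigs.
#' @slot ratio \code{targetMedian / backgroundMedian}.
#' @slot nBackground Number of background contigs pooled.
#' @export
setClass("CopyNumberEstimate", representation(
  targetMedian = "numeric",
  backgroundMedian = "numeric",
  ratio = "numeric",
  nBackground = "integer"
))

setValidity("CopyNumberEstimate", function(object) {
  if (object@backgroundMedian <= 0) return("backgroundMedian must be > 0")
  if (abs(object@ratio - object@targetMedian / object@backgroundMedian) >
      1e-8 * max(1, object@ratio))
    return("ratio must equal targetMedian / backgroundMedian")
  TRUE
})

## ---- accessors ----

#' @export
setGeneric("planSegments", function(x) standardGeneric("planSegments"))
#' @describeIn SegmentPlan-class list of segment specifications
#' @param x A \code{SegmentPlan}.
#' @export
setMethod("planSegments", "SegmentPlan", function(x) x@segments)

#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))
#' @describeIn SegmentPlan-class chromosome length in bp
#' @export
setMethod("totalLength", "SegmentPlan", function(x) x@totalLength)

#' @export
setGeneric("tsOffset", function(x) standardGeneric("tsOffset"))
#' @describeIn SegmentPlan-class transcription start position (1-based)
#' @export
setMethod("tsOffset", "SegmentPlan", function(x) x@tsOffset)

#' @export
setGeneric("ttOffset", function(x) standardGeneric("ttOffset"))
#' @describeIn SegmentPlan-class transcription terminator position (1-based)
#' @export
setMethod("ttOffset", "SegmentPlan", function(x) x@ttOffset)

#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @describeIn ReadSet-class the reads as a \code{DNAStringSet}
#' @param x A \code{ReadSet}.
#' @export
setMethod("readSequences", "ReadSet", function(x) x@reads)

#' @export
setGeneric("readInfo", function(x) standardGeneric("readInfo"))
#' @describeIn ReadSet-class per-read simulator truth metadata
#' @export
setMethod("readInfo", "ReadSet", function(x) x@info)

#' @export
setGeneric("medianDepth", function(x) standardGeneric("medianDepth"))
#' @describeIn DepthProfile-class median per-base depth
#' @param x A \code{DepthProfile}.
#' @export
setMethod("medianDepth", "DepthProfile", function(x) x@medianDepth)

#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))
#' @describeIn CopyNumberEstimate-class the estimated copy number (depth ratio)
#' @param x A \code{CopyNumberEstimate}.
#' @export
setMethod("copyNumber", "CopyNumberEstimate", function(x) x@ratio)

## ---- show ----

setMethod("show", "SegmentPlan", function(object) {
  cat(sprintf("SegmentPlan: %d segments, %d bp total\n",
              length(object@segments), object@totalLength))
  cat(sprintf("  transcription unit: %d..%d (%d bp)\n",
              object@tsOffset, object@ttOffset,
              object@ttOffset - object@tsOffset + 1L))
  nm <- vapply(object@segments, `[[`, character(1), "name")
  len <- vapply(object@segments, `[[`, numeric(1), "length")
  cat("  ", paste(sprintf("%s(%d)", nm, len), collapse = " "), "\n", sep = "")
})

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet of %d %s reads", length(object@reads), object@origin))
  if ("stage" %in% names(object@info)) {
    tb <- table(object@info$stage)
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
})

setMethod("show", "DepthProfile", function(object) {
  cat(sprintf("DepthProfile for '%s': %d bp, median depth %.2f (bin %d bp)\n",
              object@refName, length(object@perBase), object@medianDepth,
              object@binSize))
})

setMethod("show", "CopyNumberEstimate", function(object) {
  cat(sprintf(
    "CopyNumberEstimate: %.1f copies per haploid genome\n  (target median %.2f / pooled median of %d background contigs %.2f)\n",
    object@ratio, object@targetMedian, object@nBackground,
    object@backgroundMedian))
})
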