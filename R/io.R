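#' @importFrom Biostrings writeXStringSet readDNAStringSet
#' @importFrom rtracklayer export import
NULL

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or \code{DNAStringSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaFile <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Write reads as FASTQ (constant quality)
#'
#' @param reads A \code{\linkS4class{ReadSet}} or named character vector.
#' @param path Output path.
#' @param qualChar Constant per-base quality character.
#' @return \code{path}, invisibly.
#' @export
writeFastqFile <- function(reads, path, qualChar = "I") {
  sq <- if (is(reads, "ReadSet")) as.character(readSequences(reads)) else
    as.character(reads)
  ids <- names(sq)
  lines <- character(4L * length(sq))
  lines[seq(1L, by = 4L, length.out = length(sq))] <- paste0("@", ids)
  lines[seq(2L, by = 4L, length.out = length(sq))] <- sq
  lines[seq(3L, by = 4L, length.out = length(sq))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(sq))] <-
    strrep(qualChar, nchar(sq))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
readFastqFile <- function(path) {
  lines <- readLines(path)
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  setNames(lines[seq(2L, length(lines), by = 4L)], ids)
}

#' Write / read a feature annotation as GFF3
#'
#' Column 3 carries the feature type (SO terms where they exist: telomere,
#' exon, intron, polyA_site; descriptive terms otherwise, declared by a
#' header pragma); coordinates are converted to the 1-based inclusive GFF3
#' convention; additional metadata columns travel as attributes.
#'
#' @param gr \code{GRanges} with \code{type} and \code{ID} metadata.
#' @param path Output path.
#' @return \code{exportGFF3} returns \code{path} invisibly;
#'   \code{importGFF3} the \code{GRanges} read back.
#' @export
exportGFF3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname exportGFF3
#' @export
importGFF3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Write a coverage track as bedGraph
#'
#' @param cov A coverage \code{Rle} or \code{\linkS4class{DepthProfile}}.
#' @param path Output path.
#' @param refName Reference name for column 1.
#' @param log10 Whether to write \code{log10(coverage + 1)} instead of raw
#'   coverage.
#' @return \code{path}, invisibly.
#' @export
exportBedGraph <- function(cov, path, refName = "rDNA", log10 = FALSE) {
  if (is(cov, "DepthProfile")) {
    refName <- cov@refName
    cov <- cov@perBase
  }
  v <- runValue(cov)
  w <- runLength(cov)
  en <- cumsum(w)
  st <- en - w       # bedGraph is 0-based half-open
  if (log10) v <- log10(v + 1)
  writeLines(c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%g", refName, st, en, v)), path)
  invisible(path)
}

#' Write alignments as minimal SAM (substitution-only CIGARs)
#'
#' Long-read alignments become single \code{M} runs; spliced tag-read
#' alignments an \code{M-N-M} pattern with the untemplated tail soft
#' clipped.
#'
#' @param alignments Output of \code{\link{mapLongReads}} or
#'   \code{\link{mapTagReads}}.
#' @param refLengths Named vector of reference lengths.
#' @param reads Optional \code{ReadSet} to fill the SEQ column.
#' @param path Output path.
#' @param refName Reference name used for tag-read alignments (which carry
#'   no \code{ref} column).
#' @return \code{path}, invisibly.
#' @export
writeSamFile <- function(alignments, refLengths, path, reads = NULL,
                         refName = "rDNA") {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                   as.integer(refLengths)))
  sq <- if (!is.null(reads)) as.character(readSequences(reads)) else NULL
  recs <- character(0)
  if (nrow(alignments)) {
    if ("block" %in% names(alignments)) {
      ## spliced tag alignments: one record per read
      for (rid in unique(alignments$read_id)) {
        d <- alignments[alignments$read_id == rid, , drop = FALSE]
        d <- d[order(d$block), , drop = FALSE]
        cigar <- if (nrow(d) == 2L)
          sprintf("%dM%dN%dM", d$t_end[1] - d$t_start[1] + 1L,
                  d$t_start[2] - d$t_end[1] - 1L,
                  d$t_end[2] - d$t_start[2] + 1L)
        else sprintf("%dM", d$t_end[1] - d$t_start[1] + 1L)
        if (d$clip3[1] > 0L) cigar <- paste0(cigar, d$clip3[1], "S")
        flag <- if (d$strand[1] == "-") 16L else 0L
        s <- if (!is.null(sq) && rid %in% names(sq)) sq[[rid]] else "*"
        recs <- c(recs, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                                rid, flag, refName, d$t_start[1], cigar, s))
      }
    } else {
      flag <- ifelse(alignments$strand == "-", 16L, 0L)
      cigar <- sprintf("%dM", alignments$t_end - alignments$t_start + 1L)
      s <- if (!is.null(sq)) sq[alignments$read_id] else
        rep("*", nrow(alignments))
      recs <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                      alignments$read_id, flag, alignments$ref,
                      alignments$t_start, cigar, s)
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
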