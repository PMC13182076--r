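#' Simulate long DNA reads from one or more reference sequences
#'
#' Reads are sampled uniformly from both strands with approximately normal
#' lengths and a uniform substitution error rate (no indels).  The expected
#' per-reference mean depth equals the requested depth; read counts are
#' Poisson, so for depths of 50 or more the realized mean depth is within a
#' few percent of target.
#'
#' @param refs Named character vector or \code{DNAStringSet} of references.
#' @param depths Named numeric vector of target mean depths (recycled if
#'   unnamed scalar).
#' @param readLenMean,readLenSd Read length distribution in bp.
#' @param errorRate Substitution error rate per base, in [0, 0.1].
#' @param seed Integer seed.
#' @return A \code{\linkS4class{ReadSet}} with origin \code{"dna_long"};
#'   per-read truth coordinates are kept in \code{readInfo()}.
#' @export
simulateLongReads <- function(refs, depths, readLenMean = 1000,
                              readLenSd = 100, errorRate = 0.02, seed = 1L) {
  if (!is.character(refs)) refs <- as.character(refs)
  if (is.null(names(refs))) stop("refs must be named")
  if (length(depths) == 1L && is.null(names(depths)))
    depths <- setNames(rep(depths, length(refs)), names(refs))
  stopifnot(all(names(refs) %in% names(depths)), all(depths > 0),
            errorRate >= 0, errorRate <= 0.1)
  withSeed(seed, {
    allReads <- character(0)
    info <- list()
    for (rn in names(refs)) {
      L <- nchar(refs[[rn]])
      ## sample read starts over the extended range [2 - len, L] and clip
      ## at the reference ends: coverage is then uniform at the target
      ## depth across the whole reference (reads reaching an end are
      ## truncated there, as telomere-to-telomere reads are)
      n <- rpois(1L, (L + readLenMean - 1L) * depths[[rn]] / readLenMean)
      if (n == 0L) next
      len <- as.integer(round(rnorm(n, readLenMean, readLenSd)))
      len <- pmax(len, 50L)
      if (any(len > L)) {
        warning(sprintf("reference '%s' shorter than some read lengths; %d reads truncated",
                        rn, sum(len > L)))
        len <- pmin(len, L)
      }
      start0 <- as.integer(floor(runif(n, 2 - len, L + 1)))
      start <- pmax(start0, 1L)
      ends <- pmin(start0 + len - 1L, L)
      keep <- ends - start + 1L >= 30L
      start <- start[keep]; ends <- ends[keep]
      n <- sum(keep)
      if (n == 0L) next
      len <- ends - start + 1L
      strand <- sample(c("+", "-"), n, replace = TRUE)
      sq <- substring(refs[[rn]], start, ends)
      neg <- strand == "-"
      if (any(neg)) sq[neg] <- revComp(sq[neg])
      allReads <- c(allReads, sq)
      info[[rn]] <- data.frame(ref = rn, start = start,
                               end = start + len - 1L, strand = strand,
                               length = len, stringsAsFactors = FALSE)
    }
    info <- do.call(rbind, info)
    rownames(info) <- NULL
    allReads <- mutateMany(allReads, errorRate)
    ids <- sprintf("read_%06d", seq_along(allReads))
    rs <- DNAStringSet(allReads)
    names(rs) <- ids
    info$id <- ids
    new("ReadSet", reads = rs, origin = "dna_long", info = info,
        seed = as.integer(seed))
  })
}
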