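#' @importFrom stats rmultinom setNames
NULL

.truthById <- function(truth, id) {
  i <- which(mcols(truth)$ID == id)
  if (length(i) != 1L) return(NULL)
  c(start(truth)[i], end(truth)[i])
}

## Internal description of the mature / processed transcript species that a
## 3'-tag library samples from.  Each species is a set of chromosome blocks
## (exon surgery applied), an optional untemplated poly(A) tail, and a read
## sampling mode.
.speciesModels <- function(truth, tailLen = 25L, fivePrimeWindow = 20L) {
  g <- function(id) .truthById(truth, id)
  sp <- list()
  ssu1 <- g("SSU_exon1"); ssu2 <- g("SSU_exon2")
  if (!is.null(ssu1)) {
    blocks <- if (is.null(ssu2)) list(ssu1) else list(ssu1, ssu2)
    sp$RNA1 <- list(name = "RNA1", blocks = blocks, tail = 0L,
                    mode = "uniform",
                    junctions = if (is.null(ssu2)) character(0) else "S956-1")
  }
  e58 <- g("5.8S")
  if (!is.null(e58))
    sp$rRNA_5.8S <- list(name = "rRNA_5.8S", blocks = list(e58), tail = 0L,
                         mode = "uniform", junctions = character(0))
  l1 <- g("26S_exon1"); l2 <- g("26S_exon2"); l3 <- g("26S_exon3")
  if (!is.null(l1) && !is.null(l2) && !is.null(l3))
    sp$rRNA_26S <- list(name = "rRNA_26S", blocks = list(l1, l2, l3),
                        tail = 0L, mode = "uniform",
                        junctions = c("L1949", "L2449"))
  heg <- g("HEG"); i51 <- g("I51")
  if (!is.null(heg)) {
    sp$RNA2 <- list(name = "RNA2", blocks = list(heg), tail = tailLen,
                    mode = "polya", junctions = character(0))
    if (!is.null(i51))
      sp$RNA3 <- list(name = "RNA3",
                      blocks = list(c(heg[1], i51[1] - 1L),
                                    c(i51[2] + 1L, heg[2])),
                      tail = tailLen, mode = "polya", junctions = "I51")
  }
  ets <- g("ETS")
  if (!is.null(ets))
    sp$ETS_5p <- list(name = "ETS_5p",
                      blocks = list(c(ets[1], ets[1] + 119L)), tail = 0L,
                      mode = "five_prime", junctions = character(0),
                      window = fivePrimeWindow)
  sp
}

.speciesSeq <- function(model, sequence) {
  seqc <- asChar(sequence)
  tpl <- paste(vapply(model$blocks, function(b)
    substr(seqc, b[1], b[2]), character(1)), collapse = "")
  paste0(tpl, strrep("A", model$tail))
}

#' Mature transcript species sequences implied by a truth annotation
#'
#' Performs the exon/intron string surgery encoded in the truth annotation:
#' the ligated SSU rRNA (RNA1, S956-1 removed), the unprocessed
#' polyadenylated HEG transcript (RNA2, I51 retained), the mature homing
#' endonuclease mRNA (RNA3, I51 removed), 5.8S, the ligated 26S (L1949 and
#' L2449 removed) and a 5' ETS fragment.
#'
#' @param truth Truth \code{GRanges} from \code{\link{buildChromosome}}.
#' @param sequence The chromosome sequence.
#' @param tailLen Untemplated poly(A) tail length appended to the
#'   polyadenylated species.
#' @return Named character vector of species sequences.
#' @export
speciesSequences <- function(truth, sequence, tailLen = 25L) {
  models <- .speciesModels(truth, tailLen)
  vapply(models, .speciesSeq, character(1), sequence = sequence)
}

## map an interval [a, b] in species (templated) coordinates to chromosome
## blocks; returns list of c(start, end) chromosome intervals
.mapToChrom <- function(model, a, b) {
  lens <- vapply(model$blocks, function(x) x[2] - x[1] + 1L, numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  out <- list()
  for (i in seq_along(model$blocks)) {
    lo <- max(a, starts[i]); hi <- min(b, ends[i])
    if (lo <= hi) {
      off <- model$blocks[[i]][1] - starts[i]
      out[[length(out) + 1L]] <- c(lo + off, hi + off)
    }
  }
  out
}

#' Simulate stage-labelled 3'-tag RNA reads
#'
#' Draws short reads from the mature transcript species of the truth
#' annotation, emulating a 3'-end tag library: polyadenylated species (the
#' HEG transcripts RNA2/RNA3) are sampled with a geometric-decay 3' bias so
#' reads are enriched near the poly(A) tail, rRNA species are sampled
#' uniformly, and the ETS fragment is sampled at the transcript 5' end so
#' read onsets mark the transcription start.  No reads originate from the
#' non-transcribed spacer.
#'
#' @param truth Truth \code{GRanges} from \code{\link{buildChromosome}}.
#' @param sequence Chromosome sequence.
#' @param abundances Named numeric vector of species weights (a single
#'   vector shared by all stages, or a named list of per-stage vectors).
#'   Defaults: rRNA-derived 0.90 (RNA1 0.40, 26S 0.40, 5.8S 0.10), RNA3
#'   0.06, RNA2 0.03, ETS fragments 0.01.
#' @param nReads Reads per stage.
#' @param readLen Read length in nt.
#' @param stages Character vector of life-stage labels.
#' @param tailLen Poly(A) tail length (untemplated, appended at the truth
#'   poly(A) site).
#' @param decayMean Mean of the geometric/exponential 3'-end offset of reads
#'   from polyadenylated species, in nt.
#' @param errorRate Substitution error rate per base.
#' @param seed Integer seed.
#' @return A \code{\linkS4class{ReadSet}} with origin \code{"rna_tag"}.
#' @export
simulateTagReads <- function(truth, sequence, abundances = NULL,
                             nReads = 5000L, readLen = 100L,
                             stages = c("amoeba", "microcyst", "flagellate",
                                        "plasmodium"),
                             tailLen = 25L, decayMean = 300, errorRate = 0,
                             seed = 1L) {
  if (is.null(abundances))
    abundances <- c(RNA1 = 0.40, rRNA_26S = 0.40, rRNA_5.8S = 0.10,
                    RNA3 = 0.06, RNA2 = 0.03, ETS_5p = 0.01)
  perStage <- if (is.list(abundances)) abundances else
    setNames(rep(list(abundances), length(stages)), stages)
  models <- .speciesModels(truth, tailLen)
  seqs <- vapply(models, .speciesSeq, character(1), sequence = sequence)
  withSeed(seed, {
    reads <- character(0)
    rows <- list()
    for (stg in stages) {
      ab <- perStage[[stg]]
      ab <- ab[ab > 0]
      if (length(ab) == 0L || sum(ab) <= 0)
        stop("total species abundance must be positive")
      if (!all(names(ab) %in% names(models)))
        stop("unknown species in abundances: ",
             paste(setdiff(names(ab), names(models)), collapse = ", "))
      counts <- as.vector(rmultinom(1L, nReads, ab / sum(ab)))
      names(counts) <- names(ab)
      for (spn in names(counts)) {
        n <- counts[[spn]]
        if (n == 0L) next
        m <- models[[spn]]
        spSeq <- seqs[[spn]]
        Lt <- nchar(spSeq) - m$tail      # templated length
        Ltot <- nchar(spSeq)
        rl <- min(readLen, Ltot)
        start <- switch(m$mode,
          uniform = sample.int(Lt - rl + 1L, n, replace = TRUE),
          five_prime = sample.int(min(m$window %||% 20L, Lt - rl) + 1L, n,
                                  replace = TRUE),
          polya = {
            e <- floor(rexp(n, 1 / decayMean))
            e <- pmin(e, Ltot - rl)
            as.integer(Ltot - e - rl + 1L)
          })
        sq <- substring(spSeq, start, start + rl - 1L)
        tailIn <- pmax(0L, (start + rl - 1L) - Lt)
        blocks <- lapply(seq_len(n), function(i) {
          hi <- min(start[i] + rl - 1L, Lt)
          .mapToChrom(m, start[i], hi)
        })
        nb <- vapply(blocks, length, integer(1))
        b1 <- t(vapply(blocks, function(b) b[[1]], numeric(2)))
        b2 <- t(vapply(blocks, function(b)
          if (length(b) >= 2L) b[[2]] else c(NA_real_, NA_real_),
          numeric(2)))
        junct <- ifelse(nb >= 2L,
                        if (length(m$junctions)) m$junctions[1] else NA,
                        NA)
        ## for the 26S species, identify which junction was spanned
        if (spn == "rRNA_26S") {
          junct <- rep(NA_character_, n)
          spanned <- nb >= 2L
          junct[spanned] <- ifelse(b1[spanned, 2] == m$blocks[[1]][2],
                                   "L1949", "L2449")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stg, species = spn, sp_start = start, read_len = rl,
          tail_len = as.integer(tailIn),
          b1s = b1[, 1], b1e = b1[, 2], b2s = b2[, 1], b2e = b2[, 2],
          junction = junct, stringsAsFactors = FALSE)
        reads <- c(reads, sq)
      }
    }
    info <- do.call(rbind, rows)
    rownames(info) <- NULL
    reads <- mutateMany(reads, errorRate)
    ids <- sprintf("tag_%06d", seq_along(reads))
    rs <- DNAStringSet(reads)
    names(rs) <- ids
    info$id <- ids
    new("ReadSet", reads = rs, origin = "rna_tag", info = info,
        seed = as.integer(seed))
  })
}
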