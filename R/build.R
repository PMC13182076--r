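#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlengths<-
NULL

#' Build a (possibly diverged) DNA palindrome
#'
#' Concatenates \code{arm}, \code{loop} and the reverse complement of
#' \code{arm} mutated by substitutions at the given per-base rate, so the
#' expected pairwise identity of the two halves is \code{1 - divergence}.
#'
#' @param arm Left arm sequence (character).
#' @param divergence Per-base substitution rate applied to the right arm,
#'   in [0, 0.5).
#' @param loop Optional unpaired loop sequence between the arms.
#' @param seed Optional integer seed; if \code{NULL} the current RNG stream
#'   is used.
#' @return A character string of length \code{2 * nchar(arm) + nchar(loop)}.
#' @export
makePalindrome <- function(arm, divergence = 0, loop = "", seed = NULL) {
  stopifnot(divergence >= 0, divergence < 0.5)
  mk <- function() paste0(arm, loop, mutateSeq(revComp(arm), divergence))
  if (is.null(seed)) mk() else withSeed(seed, mk())
}

#' Build a tandem repeat array of similar-but-not-identical units
#'
#' Each copy of \code{unit} is independently mutated by substitutions at
#' \code{perCopyMutRate}, mimicking the heterogeneous unit copies seen in
#' real rDNA direct-repeat arrays.
#'
#' @param unit Repeat unit sequence (character).
#' @param copies Number of copies (>= 1).
#' @param perCopyMutRate Per-base substitution rate applied to each copy.
#' @param seed Optional integer seed.
#' @return List with \code{sequence} (character) and \code{boundaries}
#'   (integer vector of 1-based unit start positions within the array).
#' @export
makeTandemArray <- function(unit, copies, perCopyMutRate = 0, seed = NULL) {
  stopifnot(copies >= 1)
  mk <- function() {
    parts <- vapply(seq_len(copies),
                    function(i) mutateSeq(unit, perCopyMutRate), character(1))
    list(sequence = paste(parts, collapse = ""),
         boundaries = as.integer((seq_len(copies) - 1L) * nchar(unit) + 1L))
  }
  if (is.null(seed)) mk() else withSeed(seed, mk())
}

.feat <- function(type, start, end, ID, strand = "+", ...) {
  extra <- list(...)
  row <- data.frame(type = type, start = as.integer(start),
                    end = as.integer(end), strand = strand, ID = ID,
                    stringsAsFactors = FALSE)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

.bindFeats <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(cols, names(r))) r[[nm]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}

.featsToGRanges <- function(df, chromName, totalLen) {
  gr <- GRanges(chromName, IRanges(df$start, df$end), strand = df$strand)
  meta <- df[, setdiff(names(df), c("start", "end", "strand")), drop = FALSE]
  mcols(gr) <- DataFrame(meta)
  seqlengths(gr) <- totalLen
  gr
}

#' Build the synthetic rDNA chromosome and its ground-truth annotation
#'
#' Realizes a \code{\linkS4class{SegmentPlan}} into a concrete DNA sequence,
#' planting every architectural element (telomere arrays, the NTS palindrome
#' with PRO1/PRO2 origin motifs, direct-repeat arrays, D-type UPR units with
#' their internal 140 bp palindromes and IR motifs, exons, group I introns,
#' the I51 spliceosomal intron, the HEG and its poly(A) site) and recording
#' each at its exact coordinate in a \code{GRanges} truth annotation.
#' Deterministic given \code{(plan, seed)}.
#'
#' @param plan A \code{SegmentPlan}.
#' @param seed Integer seed (defaults to the plan's stored seed).
#' @param chromName Sequence name used in the truth annotation.
#' @return List with elements \code{sequence} (a \code{DNAString}),
#'   \code{truth} (a \code{GRanges} with \code{type}/\code{ID} metadata) and
#'   \code{plan}.
#' @export
buildChromosome <- function(plan, seed = plan@seed, chromName = "rDNA") {
  validObject(plan)
  masters <- defaultMasters()
  withSeed(seed, {
    pieces <- character(0)
    feats <- list()
    pos <- 0L
    segStart <- integer(0)
    segEnd <- integer(0)
    nm <- vapply(plan@segments, `[[`, character(1), "name")

    addArraysInto <- function(filler, arrays, segName, segOff, rate = 0.01) {
      ## splice tandem arrays into a filler sequence at fixed offsets
      for (an in names(arrays)) {
        a <- arrays[[an]]
        unit <- masters[[a$unit]]
        if (nchar(unit) != a$unit_length)
          stop(sprintf("segment '%s': unit %s length mismatch", segName, an))
        aLen <- a$unit_length * a$copies
        if (a$offset + aLen - 1L > nchar(filler))
          stop(sprintf("segment '%s': array %s exceeds segment length",
                       segName, an))
        arr <- makeTandemArray(unit, a$copies, a$mut_rate %||% rate)
        substr(filler, a$offset, a$offset + aLen - 1L) <- arr$sequence
        feats[[length(feats) + 1L]] <<- .feat(
          "tandem_array", segOff + a$offset, segOff + a$offset + aLen - 1L,
          paste0(segName, "_array_", an),
          unit_length = a$unit_length, copies = a$copies)
      }
      filler
    }

    for (i in seq_along(plan@segments)) {
      s <- plan@segments[[i]]
      p <- s$params
      st <- pos + 1L
      en <- pos + s$length
      segStart[i] <- st; segEnd[i] <- en
      seq <- switch(
        s$name,
        "telomere_left" = , "telomere_right" = {
          motif <- p$motif
          if (p$copies * nchar(motif) != s$length)
            stop(sprintf("segment '%s': copies x motif length != length",
                         s$name))
          feats[[length(feats) + 1L]] <- .feat(
            "telomere", st, en, s$name, motif = motif, copies = p$copies,
            unit_length = nchar(motif))
          strrep(motif, p$copies)
        },
        "palindrome_NTS" = {
          armLen <- p$arm_length; loopLen <- p$loop_length %||% 0L
          if (2L * armLen + loopLen != s$length)
            stop(sprintf("segment '%s': 2*arm + loop != length", s$name))
          arm <- randomDNA(armLen)
          proOff <- p$pro_offset
          proLen <- nchar(PRO_MOTIF)
          if (!is.null(proOff)) {
            if (proOff + proLen - 1L > armLen)
              stop(sprintf("segment '%s': PRO motif exceeds arm", s$name))
            substr(arm, proOff, proOff + proLen - 1L) <- PRO_MOTIF
          }
          arm2 <- mutateSeq(revComp(arm), p$divergence %||% 0)
          if (!is.null(proOff)) {
            ## re-stamp the mirrored origin motif after divergence so both
            ## palindrome halves carry an exact copy
            a2 <- armLen - proOff - proLen + 2L
            substr(arm2, a2, a2 + proLen - 1L) <- revComp(PRO_MOTIF)
            feats[[length(feats) + 1L]] <- .feat(
              "PRO", st + proOff - 1L, st + proOff + proLen - 2L, "PRO1",
              motif = PRO_MOTIF)
            p2 <- st + armLen + loopLen + a2 - 1L
            feats[[length(feats) + 1L]] <- .feat(
              "PRO", p2, p2 + proLen - 1L, "PRO2", strand = "-",
              motif = PRO_MOTIF)
          }
          feats[[length(feats) + 1L]] <- .feat(
            "palindrome", st, en, "NTS_palindrome",
            arm_length = armLen, loop_length = loopLen,
            divergence = p$divergence %||% 0)
          paste0(arm, randomDNA(loopLen), arm2)
        },
        "UPR" = {
          unit <- masters[[p$unit]]
          if (p$unit_length * p$copies != s$length ||
              nchar(unit) != p$unit_length)
            stop(sprintf("segment '%s': unit_length x copies != length",
                         s$name))
          arr <- makeTandemArray(unit, p$copies, p$mut_rate %||% 0)
          feats[[length(feats) + 1L]] <- .feat(
            "UPR", st, en, "UPR", unit_length = p$unit_length,
            copies = p$copies)
          for (u in seq_len(p$copies)) {
            u0 <- st + (u - 1L) * p$unit_length
            feats[[length(feats) + 1L]] <- .feat(
              "repeat_unit", u0, u0 + p$unit_length - 1L,
              paste0("D_unit_", u), unit_index = u)
            feats[[length(feats) + 1L]] <- .feat(
              "palindrome", u0 + 110L, u0 + 249L, paste0("D_palindrome_", u),
              arm_length = 65L, loop_length = 10L, unit_index = u)
            feats[[length(feats) + 1L]] <- .feat(
              "motif_hit", u0, u0 + 19L, paste0("IR5p_", u), unit_index = u)
            feats[[length(feats) + 1L]] <- .feat(
              "motif_hit", u0 + 20L, u0 + 39L, paste0("IR3p_", u),
              strand = "-", unit_index = u)
          }
          arr$sequence
        },
        "ETS" = {
          filler <- randomDNA(s$length)
          filler <- addArraysInto(filler, p$arrays %||% list(), "ETS", pos,
                                  p$mut_rate %||% 0.01)
          feats[[length(feats) + 1L]] <- .feat("ETS", st, en, "ETS")
          feats[[length(feats) + 1L]] <- .feat(
            "transcription_start", st, st, "Ts")
          filler
        },
        "ITS1" = {
          filler <- randomDNA(s$length)
          filler <- addArraysInto(filler, p$arrays %||% list(), "ITS1", pos,
                                  p$mut_rate %||% 0.01)
          feats[[length(feats) + 1L]] <- .feat("ITS1", st, en, "ITS1")
          filler
        },
        "ITS2" = {
          feats[[length(feats) + 1L]] <- .feat("ITS2", st, en, "ITS2")
          randomDNA(s$length)
        },
        "S956-1" = {
          lay <- S956_LAYOUT
          if (s$length != lay$total)
            stop(sprintf("segment '%s': length must be %d", s$name,
                         lay$total))
          hegSt <- st + lay$gir + lay$lc
          hegEn <- hegSt + lay$heg - 1L
          i51St <- hegSt + lay$i51_offset
          feats[[length(feats) + 1L]] <- .feat(
            "intron", st, en, "S956-1", intron_class = "groupI")
          feats[[length(feats) + 1L]] <- .feat("HEG", hegSt, hegEn, "HEG")
          feats[[length(feats) + 1L]] <- .feat(
            "spliceosomal_intron", i51St, i51St + lay$i51_len - 1L, "I51")
          feats[[length(feats) + 1L]] <- .feat(
            "polyA_site", hegEn, hegEn, "HEG_polyA")
          masters$S956
        },
        "L1949" = , "L2449" = {
          feats[[length(feats) + 1L]] <- .feat(
            "intron", st, en, s$name, intron_class = "groupI")
          randomDNA(s$length)
        },
        "SSU_exon1" = , "SSU_exon2" = , "26S_exon1" = , "26S_exon2" = ,
        "26S_exon3" = {
          feats[[length(feats) + 1L]] <- .feat("exon", st, en, s$name)
          randomDNA(s$length)
        },
        "5.8S" = {
          feats[[length(feats) + 1L]] <- .feat("exon", st, en, "5.8S")
          randomDNA(s$length)
        },
        "trailer" = {
          feats[[length(feats) + 1L]] <- .feat("trailer", st, en, "trailer")
          feats[[length(feats) + 1L]] <- .feat(
            "transcription_terminator", en, en, "tt")
          randomDNA(s$length)
        },
        {
          if (grepl("^repeat_array_", s$name)) {
            unit <- if (!is.null(p$unit)) masters[[p$unit]] else
              p$unit_sequence
            if (nchar(unit) * p$copies != s$length)
              stop(sprintf("segment '%s': unit_length x copies != length",
                           s$name))
            arr <- makeTandemArray(unit, p$copies, p$mut_rate %||% 0)
            feats[[length(feats) + 1L]] <- .feat(
              "tandem_array", st, en, s$name, unit_length = nchar(unit),
              copies = p$copies)
            arr$sequence
          } else {
            feats[[length(feats) + 1L]] <- .feat(s$name, st, en, s$name)
            if (!is.null(p$sequence)) p$sequence else randomDNA(s$length)
          }
        })
      if (nchar(seq) != s$length)
        stop(sprintf("segment '%s': built %d bp, expected %d", s$name,
                     nchar(seq), s$length))
      pieces[i] <- seq
      pos <- en
    }

    ## gene-level features spanning exons + introns
    addGene <- function(fromName, toName, id) {
      i <- match(fromName, nm); j <- match(toName, nm)
      if (!is.na(i) && !is.na(j))
        feats[[length(feats) + 1L]] <<- .feat(
          "gene", segStart[i], segEnd[j], id)
    }
    if ("SSU_exon1" %in% nm)
      addGene("SSU_exon1",
              if ("SSU_exon2" %in% nm) "SSU_exon2" else "SSU_exon1",
              "SSU_rRNA_gene")
    addGene("5.8S", "5.8S", "5.8S_rRNA_gene")
    addGene("26S_exon1", "26S_exon3", "26S_rRNA_gene")
    if ("telomere_left" %in% nm && "ETS" %in% nm)
      feats[[length(feats) + 1L]] <- .feat(
        "NTS", segEnd[match("telomere_left", nm)] + 1L,
        segStart[match("ETS", nm)] - 1L, "NTS")

    df <- .bindFeats(feats)
    list(sequence = DNAString(paste(pieces, collapse = "")),
         truth = .featsToGRanges(df, chromName, plan@totalLength),
         plan = plan)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
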