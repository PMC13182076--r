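#' @importFrom yaml write_yaml read_yaml
NULL

segSpec <- function(name, length, params = list()) {
  list(name = name, length = as.integer(length), params = params)
}

## Compute transcription start / terminator offsets from the segment list.
## Ts is the first base of the ETS; tt the last base of the trailer.  Plans
## without a transcription unit (toy plans) get the full span.
.planOffsets <- function(segments) {
  nm <- vapply(segments, `[[`, character(1), "name")
  len <- vapply(segments, function(s) as.integer(s$length), integer(1))
  ends <- cumsum(len)
  starts <- ends - len + 1L
  total <- sum(len)
  ts <- if ("ETS" %in% nm) starts[match("ETS", nm)] else 1L
  tt <- if ("trailer" %in% nm) ends[match("trailer", nm)] else total
  list(ts = as.integer(ts), tt = as.integer(tt), total = as.integer(total))
}

#' Construct a SegmentPlan from a list of segment specifications
#'
#' @param segments Ordered list of segments, each a list with \code{name},
#'   \code{length} and \code{params}.
#' @param seed Default seed for \code{\link{buildChromosome}}.
#' @return A \code{\linkS4class{SegmentPlan}}.
#' @export
newSegmentPlan <- function(segments, seed = 1L) {
  off <- .planOffsets(segments)
  new("SegmentPlan", segments = segments, totalLength = off$total,
      tsOffset = off$ts, ttOffset = off$tt, seed = as.integer(seed))
}

#' Default synthetic rDNA chromosome plan
#'
#' Encodes the printed architecture of the 20.3 kb linear rDNA chromosome:
#' 150 bp CCCTAA/TTAGGG telomere arrays at the ends, a 4.2 kb palindromic NTS
#' region with two planted 15 bp replication-origin motifs (PRO1/PRO2),
#' direct-repeat arrays A-C, a 5 x 260 bp upstream promoter region (UPR) of
#' D-type units each containing a 140 bp palindrome and IR5'/IR3' motifs, an
#' 11.3 kb transcription unit (1,483 bp ETS with E-H repeat arrays; a
#' 1,916 nt SSU rRNA gene split by the 1,436 nt group I intron S956-1 whose
#' HEG carries the 51 nt spliceosomal intron I51; ITS-1 with I/J arrays;
#' 154 bp 5.8S; ITS-2; a 3,702 bp 26S gene split by introns L1949 and L2449;
#' a short trailer), and sub-telomeric arrays K-N.  Where the architecture
#' fixes only totals, the splits are package defaults chosen so that every
#' printed total (1,483 / 1,916 / 1,436 / 51 / 154 / 3,702 / 11,300 /
#' 20,300) is satisfied simultaneously.
#'
#' @param seed Default build seed stored in the plan.
#' @param its1ICopies Copy number of the polymorphic ITS-1 I-type array
#'   (3 in the Pan2 reference isolate, 4 in Hon1).
#' @param includeS956 Whether the optional S956-1 intron is present
#'   (\code{TRUE} for Pan2; absent in Hon1).
#' @return A \code{\linkS4class{SegmentPlan}} of total length 20,300 bp
#'   (default arguments).
#' @export
defaultPlan <- function(seed = 1L, its1ICopies = 3L, includeS956 = TRUE) {
  its1ICopies <- as.integer(its1ICopies)
  iLen <- 45L * its1ICopies
  its1Len <- 500L + 45L * (its1ICopies - 3L)
  jOffset <- 51L + iLen + 20L
  segs <- list(
    segSpec("telomere_left", 150L,
            list(motif = TELOMERE_LEFT_MOTIF, copies = 25L)),
    segSpec("palindrome_NTS", 4200L,
            list(arm_length = 2100L, loop_length = 0L, divergence = 0.01,
                 pro_offset = 1001L)),
    segSpec("repeat_array_A", 600L,
            list(unit = "A", unit_length = 40L, copies = 15L,
                 mut_rate = 0.01)),
    segSpec("repeat_array_B", 600L,
            list(unit = "B", unit_length = 30L, copies = 20L,
                 mut_rate = 0.01)),
    segSpec("repeat_array_C", 1200L,
            list(unit = "C", unit_length = 60L, copies = 20L,
                 mut_rate = 0.01)),
    segSpec("UPR", 1300L,
            list(unit = "D", unit_length = 260L, copies = 5L,
                 mut_rate = 0.01)),
    segSpec("ETS", 1483L,
            list(mut_rate = 0.01, arrays = list(
              E = list(offset = 201L, unit = "E", unit_length = 30L,
                       copies = 5L),
              F = list(offset = 501L, unit = "F", unit_length = 25L,
                       copies = 4L),
              G = list(offset = 801L, unit = "G", unit_length = 40L,
                       copies = 3L),
              H = list(offset = 1101L, unit = "H", unit_length = 35L,
                       copies = 2L)))),
    if (includeS956) segSpec("SSU_exon1", 956L) else
      segSpec("SSU_exon1", 1916L),
    if (includeS956) segSpec("S956-1", 1436L) else NULL,
    if (includeS956) segSpec("SSU_exon2", 960L) else NULL,
    segSpec("ITS1", its1Len,
            list(mut_rate = 0.01, arrays = list(
              I = list(offset = 51L, unit = "I", unit_length = 45L,
                       copies = its1ICopies),
              J = list(offset = jOffset, unit = "J", unit_length = 40L,
                       copies = 2L)))),
    segSpec("5.8S", 154L),
    segSpec("ITS2", 300L),
    segSpec("26S_exon1", 1100L),
    segSpec("L1949", 900L),
    segSpec("26S_exon2", 500L),
    segSpec("L2449", 850L),
    segSpec("26S_exon3", 2102L),
    segSpec("trailer", 59L),
    segSpec("repeat_array_K", 200L,
            list(unit = "K", unit_length = 25L, copies = 8L,
                 mut_rate = 0.01)),
    segSpec("repeat_array_L", 200L,
            list(unit = "L", unit_length = 20L, copies = 10L,
                 mut_rate = 0.01)),
    segSpec("repeat_array_M", 200L,
            list(unit = "M", unit_length = 40L, copies = 5L,
                 mut_rate = 0.01)),
    segSpec("repeat_array_N", 200L,
            list(unit = "N", unit_length = 50L, copies = 4L,
                 mut_rate = 0.01)),
    segSpec("telomere_right", 150L,
            list(motif = TELOMERE_RIGHT_MOTIF, copies = 25L))
  )
  segs <- segs[!vapply(segs, is.null, logical(1))]
  newSegmentPlan(segs, seed = seed)
}

#' Isolate-specific plan variants
#'
#' The ITS-1 I-type direct-repeat array is strain-polymorphic (3 copies in
#' the Pan2-like isolates, 4 in Hon1-like isolates), and the mobile group I
#' intron S956-1 is optional, being carried only by the Pan2 isolate.
#' \code{strainVariant} transforms the default plan accordingly: Pan2 is the
#' identity transformation; Hon1 gains one I-type unit and loses S956-1 (the
#' SSU gene becomes a single contiguous 1,916 nt exon).
#'
#' @param plan A \code{SegmentPlan} containing an ITS1 segment.
#' @param isolate \code{"Pan2"} or \code{"Hon1"}.
#' @return A \code{SegmentPlan}.
#' @export
strainVariant <- function(plan, isolate = c("Pan2", "Hon1")) {
  isolate <- match.arg(isolate)
  nm <- vapply(plan@segments, `[[`, character(1), "name")
  if (!"ITS1" %in% nm) stop("plan has no ITS1 segment")
  if (isolate == "Pan2") return(plan)
  defaultPlan(seed = plan@seed, its1ICopies = 4L, includeS956 = FALSE)
}

#' Write / read a plan as a YAML configuration file
#'
#' The file echoes every segment's name, length and parameters, so a run is
#' fully reproducible from the config plus a seed.
#'
#' @param plan A \code{SegmentPlan}.
#' @param path Output file path.
#' @return \code{writePlanConfig} returns \code{path} invisibly;
#'   \code{readPlanConfig} returns the reconstructed \code{SegmentPlan}.
#' @export
writePlanConfig <- function(plan, path) {
  x <- list(seed = plan@seed,
            segments = lapply(plan@segments, function(s)
              list(name = s$name, length = s$length, params = s$params)))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writePlanConfig
#' @export
readPlanConfig <- function(path) {
  x <- yaml::read_yaml(path)
  segs <- lapply(x$segments, function(s) {
    p <- if (is.null(s$params)) list() else s$params
    ## yaml loses integer-ness on round trip; restore it for whole numbers
    p <- rapply(p, function(v) {
      if (is.numeric(v) && all(v == floor(v))) as.integer(v) else v
    }, how = "replace")
    segSpec(s$name, s$length, p)
  })
  newSegmentPlan(segs, seed = x$seed)
}
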