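test_that("empty inputs assemble to just the chromosome span", {
  gr <- assembleAnnotation(chromLength = 1000L)
  expect_identical(length(gr), 1L)
  expect_identical(S4Vectors::mcols(gr)$type, "chromosome")
})

test_that("exon and intron features tile each gene without gaps", {
  pipe <- defaultPipeline()
  ann <- pipe$annotation
  df <- as.data.frame(ann)
  for (gid in c("SSU_rRNA_gene", "26S_rRNA_gene")) {
    g <- df[df$ID == gid & df$type == "gene", ]
    parts <- df[(df$type %in% c("exon", "intron")) &
                  df$start >= g$start & df$end <= g$end, ]
    parts <- parts[order(parts$start), ]
    expect_identical(parts$start[1], g$start)
    expect_identical(parts$end[nrow(parts)], g$end)
    if (nrow(parts) > 1)
      expect_true(all(parts$start[-1] == head(parts$end, -1) + 1L))
  }
})

test_that("the length table reproduces every printed architectural number", {
  pipe <- defaultPipeline()
  len <- pipe$lengths
  bp <- setNames(len$bp, len$feature)
  expect_identical(bp[["ETS"]], 1483L)
  expect_identical(bp[["19S"]], 1916L)
  expect_identical(bp[["S956-1"]], 1436L)
  expect_identical(bp[["I51"]], 51L)
  expect_identical(bp[["5.8S"]], 154L)
  expect_identical(bp[["26S"]], 3702L)
  expect_identical(bp[["transcription_unit"]], 11300L)
  expect_identical(bp[["chromosome"]], 20300L)
  kb <- setNames(len$kb, len$feature)
  expect_identical(kb[["transcription_unit"]], "11.3")
  expect_identical(kb[["chromosome"]], "20.3")
})

test_that("segment lengths are invariant under feature reordering", {
  pipe <- defaultPipeline()
  ann <- pipe$annotation
  set.seed(7)
  expect_identical(segmentLengths(ann[sample(length(ann))]),
                   segmentLengths(ann))
})

test_that("kb rendering rounds half away from zero", {
  expect_identical(rDNAscan:::roundHalfUp(11.25, 1), 11.3)
  expect_identical(rDNAscan:::roundHalfUp(1.15, 1), 1.2)
  expect_identical(rDNAscan:::roundHalfUp(-1.15, 1), -1.2)
})

test_that("a junction outside its gene raises a clear error", {
  gm <- GenomicRanges::GRanges("rDNA", IRanges::IRanges(100, 400))
  S4Vectors::mcols(gm)$ID <- "gene1"
  ## two overlapping, non-nested introns imply a negative-length exon
  jx <- data.frame(donor = c(150L, 200L), acceptor = c(251L, 301L),
                   width = c(101L, 101L), support = c(5L, 5L),
                   perfect_ligation = TRUE,
                   intron_id = c("i1", "i2"))
  expect_error(
    assembleAnnotation(chromLength = 1000L, junctions = jx,
                       geneModel = gm),
    "negative-length exon")
})

test_that("truth comparison scores deletions exactly", {
  pipe <- defaultPipeline()
  truth <- pipe$truth
  cmp <- compareToTruth(pipe$annotation, truth)
  expect_identical(cmp$precision, 1)
  expect_identical(cmp$recall, 1)
  ## drop the only call matching one truth feature: recall drops by 1/N
  ann2 <- pipe$annotation[S4Vectors::mcols(pipe$annotation)$ID !=
                            "palindrome_151"]
  cmp2 <- compareToTruth(ann2, truth)
  n <- nrow(cmp$truthStatus)
  expect_equal(cmp2$recall, 1 - 1 / n)
})

test_that("GFF3 write/read round-trips the truth annotation", {
  bc <- defaultBuild()
  path <- tempfile(fileext = ".gff3")
  exportGFF3(bc$truth, path)
  back <- importGFF3(path)
  expect_identical(length(back), length(bc$truth))
  o1 <- order(GenomicRanges::start(bc$truth),
              GenomicRanges::end(bc$truth),
              S4Vectors::mcols(bc$truth)$ID)
  o2 <- order(GenomicRanges::start(back), GenomicRanges::end(back),
              S4Vectors::mcols(back)$ID)
  a <- bc$truth[o1]; b <- back[o2]
  expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_identical(GenomicRanges::end(a), GenomicRanges::end(b))
  expect_identical(as.character(GenomicRanges::strand(a)),
                   as.character(GenomicRanges::strand(b)))
  expect_identical(S4Vectors::mcols(a)$ID, S4Vectors::mcols(b)$ID)
  expect_identical(as.character(S4Vectors::mcols(a)$type),
                   as.character(S4Vectors::mcols(b)$type))
  unlink(path)
})

test_that("FASTQ and bedGraph writers round-trip their content", {
  bc <- defaultBuild()
  tags <- simulateTagReads(bc$truth, as.character(bc$sequence),
                           abundances = c(rRNA_5.8S = 1), nReads = 20L,
                           stages = "amoeba", seed = 3)
  fq <- tempfile(fileext = ".fastq")
  writeFastqFile(tags, fq)
  back <- readFastqFile(fq)
  expect_identical(unname(back),
                   unname(as.character(readSequences(tags))))
  cov <- S4Vectors::Rle(c(0L, 3L, 1L), c(10L, 5L, 5L))
  bg <- tempfile(fileext = ".bedGraph")
  exportBedGraph(cov, bg, refName = "chr")
  lines <- readLines(bg)[-1]
  f <- read.table(text = lines)
  expect_identical(f$V2, c(0L, 10L, 15L))
  expect_identical(f$V3, c(10L, 15L, 20L))
  expect_identical(f$V4, c(0L, 3L, 1L))
  unlink(c(fq, bg))
})
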