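test_that("contiguous and spliced tag reads are placed correctly", {
  set.seed(121)
  ref <- randomSeq(2000, 121)
  introns <- data.frame(start = 801L, end = 1200L, ID = "intr1")
  ## read wholly inside the upstream exon
  r1 <- substr(ref, 200, 299)
  ## read spanning the ligated junction: 40 nt exon1 + 60 nt exon2
  r2 <- paste0(substr(ref, 761, 800), substr(ref, 1201, 1260))
  aln <- mapTagReads(c(a = r1, b = r2), ref, introns)
  a <- aln[aln$read_id == "a", ]
  expect_identical(nrow(a), 1L)
  expect_false(a$spliced)
  expect_identical(c(a$t_start, a$t_end), c(200L, 299L))
  b <- aln[aln$read_id == "b", ]
  expect_identical(nrow(b), 2L)
  expect_true(all(b$spliced))
  expect_identical(b$intron_start[1], 801L)
  expect_identical(b$intron_end[1], 1201L - 1L)
})

test_that("junctions with insufficient anchors are not split-mapped", {
  ref <- randomSeq(2000, 122)
  introns <- data.frame(start = 801L, end = 1200L, ID = "intr1")
  ## only 5 nt on the donor side
  r <- paste0(substr(ref, 796, 800), substr(ref, 1201, 1295))
  aln <- mapTagReads(c(x = r), ref, introns, minAnchor = 8L)
  expect_true(nrow(aln) == 0L || !any(aln$spliced))
})

test_that("de novo split mapping finds unannotated gaps", {
  ref <- randomSeq(3000, 123)
  r <- paste0(substr(ref, 501, 550), substr(ref, 901, 950))
  aln <- mapTagReads(c(x = r), ref, introns = NULL)
  expect_identical(nrow(aln), 2L)
  expect_identical(aln$intron_start[1], 551L)
  expect_identical(aln$intron_end[1], 900L)
})

test_that("untemplated tails are soft-clipped but templated A runs are not", {
  ref <- paste0(randomSeq(200, 124), strrep("A", 30), randomSeq(200, 125))
  ## read ending inside the genomic A-run: the trailing As are templated
  r1 <- substr(ref, 140, 215)
  ## read with a genuinely untemplated tail appended
  r2 <- paste0(substr(ref, 300, 379), strrep("A", 20))
  aln <- mapTagReads(c(t1 = r1, t2 = r2), ref)
  a1 <- aln[aln$read_id == "t1", ]
  expect_identical(a1$clip3, 0L)
  expect_identical(a1$t_end, 215L)
  a2 <- aln[aln$read_id == "t2", ]
  expect_identical(a2$clip3, 20L)
  expect_identical(a2$t_end, 379L)
  polya <- callPolyA(aln, minA = 10, minSupport = 1)
  expect_identical(nrow(polya), 1L)
  expect_identical(polya$position, 379L)
})

test_that("every RNA3 read across the I51 locus split-maps with a 51 nt gap", {
  bc <- defaultBuild()
  seqc <- as.character(bc$sequence)
  truth <- bc$truth
  tags <- simulateTagReads(truth, seqc, abundances = c(RNA3 = 1),
                           nReads = 500L, stages = "amoeba", seed = 8)
  introns <- truth[S4Vectors::mcols(truth)$type %in%
                     c("intron", "spliceosomal_intron")]
  aln <- mapTagReads(tags, seqc, introns)
  info <- readInfo(tags)
  spanning <- info$id[!is.na(info$b2s) &
                        info$b1e - info$b1s + 1L >= 8L &
                        info$b2e - info$b2s + 1L >= 8L]
  called <- unique(aln$read_id[aln$spliced])
  expect_setequal(called, spanning)
  gaps <- unique(aln$intron_end[aln$spliced] -
                   aln$intron_start[aln$spliced] + 1L)
  expect_identical(gaps, 51L)
})

test_that("junction support equals the simulator's spanning-read count", {
  pipe <- defaultPipeline()
  info <- readInfo(pipe$tagReads)
  jx <- pipe$junctions
  expect_identical(nrow(jx), 4L)
  expect_true(all(jx$perfect_ligation))
  oracle <- table(info$junction[!is.na(info$b2s) &
                                  info$b1e - info$b1s + 1L >= 8L &
                                  info$b2e - info$b2s + 1L >= 8L])
  for (id in names(oracle))
    expect_identical(jx$support[jx$intron_id == id],
                     as.integer(oracle[[id]]))
})

test_that("poly(A) calling recovers the single HEG site with oracle support", {
  pipe <- defaultPipeline()
  truth <- pipe$truth
  pa <- pipe$polya
  expect_identical(nrow(pa), 1L)
  site <- truthFeature(truth, "HEG_polyA")[1]
  expect_lte(abs(pa$position - site), 2L)
  info <- readInfo(pipe$tagReads)
  expect_identical(pa$support, sum(info$tail_len >= 10L))
})
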