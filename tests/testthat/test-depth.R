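test_that("binned depth and medians behave on toy alignments", {
  aln <- data.frame(ref = "chr", t_start = 1L, t_end = 100L)
  prof <- depthProfile(aln, c(chr = 100L), binSize = 10L)[["chr"]]
  expect_identical(prof@depth, rep(1, 10))
  expect_identical(medianDepth(prof), 1)
  empty <- depthProfile(aln[0, ], c(chr = 50L))[["chr"]]
  expect_identical(medianDepth(empty), 0)
  expect_true(all(as.numeric(empty@perBase) == 0))
})

test_that("per-base depth equals an independent pileup oracle", {
  refs <- c(chr = randomSeq(6000, 111))
  rs <- simulateLongReads(refs, 8, readLenMean = 500, readLenSd = 50,
                          errorRate = 0.01, seed = 17)
  aln <- mapLongReads(rs, refs)
  prof <- depthProfile(aln, c(chr = 6000L))[["chr"]]
  oracle <- oraclePileup(aln$t_start, aln$t_end, 6000L)
  expect_identical(as.integer(as.numeric(prof@perBase)), oracle)
  ## coverage conservation: total aligned bases == track sum
  expect_equal(sum(as.numeric(prof@perBase)),
               sum(aln$t_end - aln$t_start + 1))
})

test_that("copy number is a pure median ratio on hand-built profiles", {
  tgt <- data.frame(ref = "t", t_start = rep(1L, 3), t_end = rep(100L, 3))
  bg <- data.frame(ref = "b", t_start = 1L, t_end = 100L)
  pt <- depthProfile(tgt, c(t = 100L))[["t"]]
  pb <- depthProfile(bg, c(b = 100L))[["b"]]
  est <- estimateCopyNumber(pt, list(pb))
  expect_identical(copyNumber(est), 3)
  expect_identical(copyNumber(estimateCopyNumber(pb, list(pb))), 1)
  empty <- depthProfile(bg[0, ], c(b = 100L))[["b"]]
  expect_error(estimateCopyNumber(pt, list(empty)), "zero")
  expect_error(estimateCopyNumber(pt, list()), "background")
})

test_that("the estimator is scale invariant in depth", {
  chrom <- as.character(defaultBuild()$sequence)
  r1 <- simulateCopyNumberRun(chrom, seed = 4, backgroundDepth = 5,
                              copies = 20)
  r2 <- simulateCopyNumberRun(chrom, seed = 4, backgroundDepth = 10,
                              copies = 20)
  expect_lt(abs(copyNumber(r1$estimate) - copyNumber(r2$estimate)) / 20,
            0.06)
})
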