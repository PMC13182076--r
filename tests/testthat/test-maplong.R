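test_that("error-free reads and their reverse complements map to the source", {
  refs <- c(chrA = randomSeq(5000, 101))
  read <- substr(refs[["chrA"]], 1001, 3000)
  aln <- mapLongReads(c(r1 = read, r2 = oracleRevComp(read)), refs)
  expect_identical(nrow(aln), 2L)
  expect_identical(aln$t_start, c(1001L, 1001L))
  expect_identical(aln$t_end, c(3000L, 3000L))
  expect_identical(aln$strand, c("+", "-"))
  expect_identical(aln$n_mismatch, c(0L, 0L))
})

test_that("simulated error-free reads all map back to their true interval", {
  refs <- c(bg = randomSeq(20000, 102),
            rDNA = as.character(defaultBuild()$sequence))
  rs <- simulateLongReads(refs, c(bg = 5, rDNA = 20), errorRate = 0,
                          seed = 5)
  aln <- mapLongReads(rs, refs)
  info <- readInfo(rs)
  m <- merge(aln, info, by.x = "read_id", by.y = "id",
             suffixes = c(".aln", ".true"))
  expect_identical(nrow(m), nrow(info))      # every read mapped
  ok <- m$ref.aln == m$ref.true & m$t_start == m$start &
    m$t_end == m$end & m$strand.aln == m$strand.true
  ## reads wholly inside a perfect telomeric repeat array are ambiguous
  ## (period-shifted and opposite-end placements are sequence-identical),
  ## as are reads inside the large palindrome (a read crossing the centre
  ## is its own near reverse complement); every other read must be placed
  ## exactly
  amb <- m$ref.true == "rDNA" &
    (m$end <= 150L | m$start >= 20151L |
       (m$start >= 151L & m$end <= 4350L))
  expect_identical(mean(ok[!amb]), 1)
  expect_gt(mean(ok), 0.98)
})

test_that("realized depth tracks the target and errors are tolerated", {
  refs <- c(chr = randomSeq(10000, 103))
  rs <- simulateLongReads(refs, 50, readLenMean = 1000, readLenSd = 100,
                          errorRate = 0.02, seed = 11)
  info <- readInfo(rs)
  depth <- sum(info$length) / 10000
  expect_lt(abs(depth - 50) / 50, 0.1)
  expGain <- (10000 + 999) * 50 / 1000
  expect_lt(abs(nrow(info) - expGain) / expGain, 0.15)
  aln <- mapLongReads(rs, refs)
  expect_gt(nrow(aln) / nrow(info), 0.99)
})

test_that("short references truncate reads with a warning; empty refs error", {
  refs <- c(tiny = randomSeq(400, 104))
  expect_warning(simulateLongReads(refs, 30, readLenMean = 1000,
                                   readLenSd = 50, seed = 2),
                 "truncated")
  expect_error(mapLongReads(c(r1 = "ACGT"), character(0)), "empty")
})

test_that("error-free reads are exact substrings of their source", {
  refs <- c(chr = randomSeq(8000, 105))
  rs <- simulateLongReads(refs, 10, errorRate = 0, seed = 3)
  sq <- as.character(readSequences(rs))
  info <- readInfo(rs)
  for (i in seq_len(min(50, length(sq)))) {
    s <- unname(if (info$strand[i] == "+") sq[i] else
      oracleRevComp(sq[i]))
    expect_identical(substr(refs[["chr"]], info$start[i], info$end[i]), s)
  }
})
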