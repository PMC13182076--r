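test_that("an exact short array decomposes into period, copies and identity", {
  x <- strrep("ACGTT", 3)
  arr <- findTandemArrays(x, k = 4L, minRun = 5L)
  expect_identical(nrow(arr), 1L)
  expect_identical(arr$unit_length, 5L)
  expect_identical(arr$copies, 3L)
  expect_identical(arr$identity, 1)
})

test_that("period estimation is idempotent under array extension", {
  unit <- randomSeq(40, 61)
  for (copies in c(4L, 8L)) {
    arr <- makeTandemArray(unit, copies, 0.005, seed = 9)
    x <- paste0(randomSeq(100, 62), arr$sequence, randomSeq(100, 63))
    calls <- findTandemArrays(x)
    expect_identical(nrow(calls), 1L)
    expect_identical(calls$unit_length, 40L)
    expect_identical(calls$copies, copies)
  }
})

test_that("the UPR period matches a brute-force autocorrelation oracle", {
  bc <- defaultBuild()
  seqc <- as.character(bc$sequence)
  upr <- truthFeature(bc$truth, "UPR")
  uprSeq <- substr(seqc, upr[1], upr[2])
  expect_identical(oraclePeriod(uprSeq), 260L)
  pipe <- defaultPipeline()
  call <- pipe$arrays[pipe$arrays$start <= upr[2] &
                        pipe$arrays$end >= upr[1] &
                        pipe$arrays$unit_length > 100, ]
  expect_identical(call$unit_length, 260L)
  expect_identical(call$copies, 5L)
})

test_that("reported unit identity equals the all-pairs comparison oracle", {
  unit <- randomSeq(50, 71)
  arr <- makeTandemArray(unit, 6, 0.02, seed = 13)
  x <- paste0(randomSeq(80, 72), arr$sequence, randomSeq(80, 73))
  calls <- findTandemArrays(x)
  expect_identical(nrow(calls), 1L)
  b <- as.integer(strsplit(calls$boundaries, ",")[[1]])
  full <- b[b + calls$unit_length - 1L <= calls$end]
  copies <- substring(x, full, full + calls$unit_length - 1L)
  pairs <- combn(length(copies), 2)
  ids <- vapply(seq_len(ncol(pairs)), function(i)
    oracleIdentity(copies[pairs[1, i]], copies[pairs[2, i]]), numeric(1))
  expect_equal(calls$identity, mean(ids))
})

test_that("every truth repeat array of the default plan is recovered within 10 bp", {
  pipe <- defaultPipeline()
  truth <- pipe$truth
  tdf <- as.data.frame(truth)
  tdf <- tdf[tdf$type %in% c("tandem_array", "UPR", "telomere") &
               tdf$unit_length >= 5 & tdf$copies >= 2, ]
  arr <- pipe$arrays
  for (i in seq_len(nrow(tdf))) {
    j <- which(abs(arr$start - tdf$start[i]) <= 10 &
                 abs(arr$end - tdf$end[i]) <= 10 &
                 arr$unit_length == tdf$unit_length[i])
    expect_identical(length(j), 1L)
    expect_identical(arr$copies[j], as.integer(tdf$copies[i]))
  }
  ## and no spurious calls: every call corresponds to some truth array
  for (j in seq_len(nrow(arr))) {
    hit <- any(abs(arr$start[j] - tdf$start) <= 10 &
                 abs(arr$end[j] - tdf$end) <= 10)
    expect_true(hit)
  }
})
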