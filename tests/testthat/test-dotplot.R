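test_that("a simple duplication yields the expected sense match", {
  dp <- selfDotplot("ACGTACGT", k = 4, minRun = 4, mergeGap = 0)
  sense <- dp[dp$orientation == "sense" & dp$q_start < dp$t_start, ]
  expect_identical(nrow(sense), 1L)
  expect_identical(sense$q_start, 1L)
  expect_identical(sense$q_end, 4L)
  expect_identical(sense$t_start, 5L)
  expect_identical(sense$t_end, 8L)
})

test_that("a sequence joined to its reverse complement is one antisense run", {
  s <- randomSeq(100, 21)
  x <- paste0(s, oracleRevComp(s))
  dp <- selfDotplot(x, k = 12, minRun = 20)
  anti <- dp[dp$orientation == "antisense" & dp$q_start <= dp$t_start, ]
  expect_identical(nrow(anti), 1L)
  expect_lte(anti$q_start, 1L + 0L)
  expect_gte(anti$t_end, 200L)
})

test_that("matches agree with a brute-force all-pairs k-mer oracle", {
  ## composite sequence with a direct and an inverted repeat
  set.seed(31)
  core <- randomSeq(80, 31)
  inv <- randomSeq(60, 32)
  x <- paste0(randomSeq(60, 33), core, randomSeq(50, 34), core,
              randomSeq(40, 35), inv, randomSeq(30, 36), oracleRevComp(inv),
              randomSeq(40, 37))
  k <- 12L
  got <- selfDotplot(x, k = k, minRun = k, mergeGap = 0)
  got <- got[got$orientation == "sense" & got$q_start < got$t_start |
               got$orientation == "antisense" & got$q_start <= got$t_start, ]
  exp <- oracleDotplot(x, k)
  ord <- function(d) {
    d <- d[order(d$orientation, d$q_start, d$t_start), ,
           drop = FALSE]
    rownames(d) <- NULL
    d[, c("q_start", "q_end", "t_start", "t_end", "orientation", "length")]
  }
  expect_identical(ord(got), ord(exp))
})

test_that("output is symmetric and invariant under reverse complement", {
  bc <- defaultBuild()
  x <- substr(as.character(bc$sequence), 6000, 9000)
  dp <- selfDotplot(x, k = 12, minRun = 20)
  ## symmetry: (q, t) present iff (t, q) present
  key <- paste(dp$q_start, dp$q_end, dp$t_start, dp$t_end, dp$orientation)
  mirror <- paste(dp$t_start, dp$t_end, dp$q_start, dp$q_end,
                  dp$orientation)
  expect_setequal(key, mirror)
  ## reverse complement mirrors coordinates
  n <- nchar(x)
  dp2 <- selfDotplot(oracleRevComp(x), k = 12, minRun = 20)
  flip <- data.frame(q_start = n - dp$q_end + 1L, q_end = n - dp$q_start + 1L,
                     t_start = n - dp$t_end + 1L, t_end = n - dp$t_start + 1L,
                     orientation = dp$orientation, length = dp$length)
  ordkey <- function(d) sort(paste(d$q_start, d$q_end, d$t_start, d$t_end,
                                   d$orientation))
  expect_identical(ordkey(dp2), ordkey(flip))
})

test_that("non-ACGT characters are skipped, not fatal", {
  x <- paste0("ACGTACGTACGT", "NNNN", "ACGTACGTACGT")
  dp <- selfDotplot(x, k = 4, minRun = 4, mergeGap = 0)
  expect_true(all(dp$q_start >= 1))
})
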