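test_that("a perfect planted palindrome is called exactly", {
  arm <- randomSeq(100, 41)
  x <- paste0(randomSeq(150, 42), arm, oracleRevComp(arm),
              randomSeq(150, 43))
  calls <- callPalindromes(x, minArm = 30, maxLoop = 20)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$left_start, 151L)
  expect_identical(calls$right_end, 350L)
  expect_identical(calls$loop, 0L)
  expect_identical(calls$span, 200L)
  expect_identical(calls$half_identity, 1)
})

test_that("no antisense self-matches means no palindrome calls", {
  x <- randomSeq(3000, 44)
  dp <- selfDotplot(x)
  expect_identical(nrow(callPalindromes(x, dp)), 0L)
})

test_that("diverged palindrome boundaries stay within 20 bp of truth", {
  worst <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    arm <- randomDNA(500)
    pal <- makePalindrome(arm, 0.01, "")
    x <- paste0(randomDNA(300), pal, randomDNA(300))
    calls <- callPalindromes(x, minArm = 100, maxLoop = 30)
    expect_gte(nrow(calls), 1L)
    top <- calls[1, ]
    worst <- max(worst, abs(top$left_start - 301L),
                 abs(top$right_end - 1300L))
  }
  expect_lte(worst, 20L)
})

test_that("half identity matches an independent base-wise oracle", {
  arm <- randomSeq(400, 51)
  pal <- makePalindrome(arm, 0.02, "TTTT", seed = 3)
  x <- paste0(randomSeq(100, 52), pal, randomSeq(100, 53))
  calls <- callPalindromes(x, minArm = 100, maxLoop = 30)
  expect_identical(nrow(calls), 1L)
  top <- calls[1, ]
  left <- substr(x, top$left_start, top$left_end)
  right <- substr(x, top$right_start, top$right_end)
  expect_equal(top$half_identity,
               oracleIdentity(left, oracleRevComp(right)))
  expect_equal(halfIdentity(x, top), top$half_identity)
  expect_error(halfIdentity(x, list(left_start = 5, left_end = 4,
                                    right_start = 10, right_end = 9)))
})

test_that("the default chromosome carries the large NTS palindrome and five D-unit palindromes", {
  pipe <- defaultPipeline()
  pals <- pipe$palindromes
  expect_identical(nrow(pals), 6L)
  top <- pals[which.max(pals$span), ]
  expect_identical(top$span, 4200L)
  expect_identical(top$left_start, 151L)       # abuts the left telomere
  expect_identical(sort(pals$span[-which.max(pals$span)]),
                   rep(140L, 5))
  ## arm identity of the large palindrome rounds to 99%
  expect_identical(round(100 * top$half_identity), 99)
})

test_that("each D-type unit contains a 140 bp internal palindrome", {
  bc <- defaultBuild()
  seqc <- as.character(bc$sequence)
  truth <- bc$truth
  for (u in 1:5) {
    r <- truthFeature(truth, paste0("D_unit_", u))
    unitSeq <- substr(seqc, r[1], r[2])
    calls <- callPalindromes(unitSeq, minArm = 30, maxLoop = 40)
    expect_gte(nrow(calls), 1L)
    expect_identical(calls$span[1], 140L)
  }
})
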