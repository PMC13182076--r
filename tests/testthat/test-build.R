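test_that("palindrome construction concatenates arm, loop and mutated arm", {
  expect_identical(makePalindrome("ACGT", 0, ""), "ACGTACGT")
  expect_identical(makePalindrome("ACGT", 0, "TTT"), "ACGTTTTACGT")
  ## diverged halves: identity measured by direct base-wise comparison
  arm <- randomSeq(2100, 11)
  pal <- makePalindrome(arm, 0.01, "", seed = 10)
  second <- substr(pal, 2101, 4200)
  id <- oracleIdentity(arm, oracleRevComp(second))
  expect_gte(id, 0.985)
  expect_lte(id, 0.995)
})

test_that("palindrome half identity converges to 1 - divergence", {
  arm <- randomSeq(2100, 5)
  ids <- vapply(1:20, function(s) {
    pal <- makePalindrome(arm, 0.01, "", seed = s)
    oracleIdentity(arm, oracleRevComp(substr(pal, 2101, 4200)))
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.99), 0.005)
})

test_that("tandem arrays have the right geometry and unit divergence", {
  arr <- makeTandemArray("ACGTT", 3, 0)
  expect_identical(arr$sequence, "ACGTTACGTTACGTT")
  expect_identical(arr$boundaries, c(1L, 6L, 11L))
  ## mutated copies: all-pairs base-wise identity oracle
  unit <- randomSeq(260, 3)
  arr <- makeTandemArray(unit, 5, 0.01, seed = 42)
  copies <- substring(arr$sequence, arr$boundaries, arr$boundaries + 259L)
  pairs <- combn(5, 2)
  ids <- vapply(seq_len(ncol(pairs)), function(i)
    oracleIdentity(copies[pairs[1, i]], copies[pairs[2, i]]), numeric(1))
  ## two copies each mutated at 1% -> expected pairwise identity ~ 0.98
  expect_gt(mean(ids), 0.96)
  expect_lt(mean(ids), 0.999)
})

test_that("a one-segment literal plan builds verbatim", {
  plan <- newSegmentPlan(list(
    segSpec("poly_A_tract", 10L, list(sequence = strrep("A", 10)))))
  bc <- buildChromosome(plan, 1L)
  expect_identical(as.character(bc$sequence), "AAAAAAAAAA")
  expect_identical(length(bc$truth), 1L)
})

test_that("the default chromosome is deterministic and plants every motif", {
  bc <- defaultBuild()
  expect_identical(length(bc$sequence), 20300L)
  seqc <- as.character(bc$sequence)
  bc2 <- buildChromosome(defaultPlan(), 1L)
  expect_identical(seqc, as.character(bc2$sequence))
  expect_identical(as.data.frame(bc$truth), as.data.frame(bc2$truth))

  truth <- bc$truth
  ## planted origin motifs sit at their truth coordinates in both halves
  p1 <- truthFeature(truth, "PRO1")
  p2 <- truthFeature(truth, "PRO2")
  expect_identical(substr(seqc, p1[1], p1[2]), rDNAscan:::PRO_MOTIF)
  expect_identical(substr(seqc, p2[1], p2[2]),
                   oracleRevComp(rDNAscan:::PRO_MOTIF))
  ## telomeric ends
  expect_identical(substr(seqc, 1, 6), "CCCTAA")
  expect_identical(substr(seqc, 20295, 20300), "TTAGGG")
  ## truth ETS span
  ets <- truthFeature(truth, "ETS")
  expect_identical(ets[2] - ets[1] + 1L, 1483L)
})

test_that("exon/intron surgery on truth intervals reproduces the mature species", {
  bc <- defaultBuild()
  seqc <- as.character(bc$sequence)
  truth <- bc$truth
  sp <- speciesSequences(truth, seqc, tailLen = 25L)
  g <- function(id) {
    r <- truthFeature(truth, id)
    substr(seqc, r[1], r[2])
  }
  expect_identical(sp[["RNA1"]], paste0(g("SSU_exon1"), g("SSU_exon2")))
  expect_identical(nchar(sp[["RNA1"]]), 1916L)
  expect_identical(sp[["rRNA_26S"]],
                   paste0(g("26S_exon1"), g("26S_exon2"), g("26S_exon3")))
  expect_identical(nchar(sp[["rRNA_26S"]]), 3702L)
  ## RNA3 skips exactly the 51 nt spliceosomal intron and gains the tail
  heg <- truthFeature(truth, "HEG")
  i51 <- truthFeature(truth, "I51")
  expect_identical(
    sp[["RNA3"]],
    paste0(substr(seqc, heg[1], i51[1] - 1L),
           substr(seqc, i51[2] + 1L, heg[2]), strrep("A", 25)))
  expect_identical(nchar(sp[["RNA3"]]), 955L - 51L + 25L)
})

test_that("incompatible segment parameters raise configuration errors", {
  plan <- defaultPlan()
  segs <- planSegments(plan)
  nm <- vapply(segs, `[[`, character(1), "name")
  i <- match("UPR", nm)
  segs[[i]]$params$copies <- 6L          # 6 x 260 != 1300
  ## keep total length consistent so the plan itself validates
  bad <- newSegmentPlan(segs, seed = 1L)
  expect_error(buildChromosome(bad, 1L), "UPR")
})

test_that("the Hon1 chromosome drops S956-1 and keeps a contiguous SSU", {
  plan <- strainVariant(defaultPlan(), "Hon1")
  bc <- buildChromosome(plan, 1L)
  ids <- S4Vectors::mcols(bc$truth)$ID
  expect_false("S956-1" %in% ids)
  ssu <- truthFeature(bc$truth, "SSU_rRNA_gene")
  expect_identical(ssu[2] - ssu[1] + 1L, 1916L)
  expect_identical(length(bc$sequence),
                   20300L + 45L - 1436L)
})
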