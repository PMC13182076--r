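test_that("species classification matches an oracle built from simulator truth", {
  pipe <- defaultPipeline()
  truth <- pipe$truth
  info <- readInfo(pipe$tagReads)
  cls <- pipe$species
  ## oracle: reclassify each read from its truth metadata using the
  ## defining predicates directly
  i51 <- truthFeature(truth, "I51")
  anchored <- !is.na(info$b2s) & info$b1e - info$b1s + 1L >= 8L &
    info$b2e - info$b2s + 1L >= 8L
  oracleRNA3 <- tapply(anchored & info$species == "RNA3" &
                         !is.na(info$junction) & info$junction == "I51",
                       info$stage, sum)
  for (stg in names(oracleRNA3))
    expect_identical(cls$counts["RNA3", stg],
                     as.integer(oracleRNA3[[stg]]))
  ## RNA2 reads are those covering the retained I51 interior by at least
  ## one anchor length
  oracleRNA2 <- tapply(info$species == "RNA2" &
                         info$b1s <= i51[2] - 7L &
                         info$b1e >= i51[1] + 7L, info$stage, sum)
  for (stg in names(oracleRNA2))
    expect_identical(cls$counts["RNA2", stg],
                     as.integer(oracleRNA2[[stg]]))
  expect_true(all(cls$counts["RNA3", ] > 0))
  expect_identical(sort(colnames(cls$counts)),
                   sort(c("amoeba", "microcyst", "flagellate",
                          "plasmodium")))
  expect_true(cls$present[["RNA3"]])
  expect_true(cls$present[["RNA2"]])
})

test_that("zero RNA3 abundance yields no RNA3 calls", {
  bc <- defaultBuild()
  seqc <- as.character(bc$sequence)
  ab <- c(RNA1 = 0.5, rRNA_26S = 0.4, RNA2 = 0.1)
  tags <- simulateTagReads(bc$truth, seqc, abundances = ab,
                           nReads = 1000L, stages = "amoeba", seed = 6)
  introns <- bc$truth[S4Vectors::mcols(bc$truth)$type %in%
                        c("intron", "spliceosomal_intron")]
  aln <- mapTagReads(tags, seqc, introns)
  cls <- classifySpecies(aln, bc$truth, callPolyA(aln))
  expect_identical(sum(cls$counts["RNA3", ]), 0L)
})

test_that("classification is stable under read-order permutation", {
  pipe <- defaultPipeline()
  aln <- pipe$tagAlignments
  set.seed(99)
  ## permute read blocks (keeping block pairs together via ordering)
  perm <- aln[sample(nrow(aln)), ]
  cls1 <- classifySpecies(aln, pipe$truth, pipe$polya)
  cls2 <- classifySpecies(perm, pipe$truth, pipe$polya)
  expect_identical(cls1$counts[, sort(colnames(cls1$counts))],
                   cls2$counts[, sort(colnames(cls2$counts))])
})

test_that("coverage tracks conserve aligned bases and leave the NTS empty", {
  pipe <- defaultPipeline()
  trk <- pipe$tracks
  aln <- pipe$tagAlignments
  nts <- truthFeature(pipe$truth, "NTS")
  pooled <- as.numeric(trk$pooled$coverage)
  expect_identical(max(pooled[nts[1]:nts[2]]), 0)
  ## pooled equals the positionwise sum of the four stage tracks
  stages <- setdiff(names(trk), "pooled")
  ssum <- Reduce(`+`, lapply(stages, function(s)
    as.numeric(trk[[s]]$coverage)))
  expect_identical(pooled, ssum)
  ## per-stage conservation of aligned bases
  for (s in stages) {
    al <- aln[!is.na(aln$stage) & aln$stage == s, ]
    expect_equal(sum(as.numeric(trk[[s]]$coverage)),
                 sum(pmin(al$t_end, 20300L) - al$t_start + 1))
  }
  ## log10 display transform is monotone in coverage
  expect_identical(order(trk$pooled$log10), order(pooled))
})

test_that("a single-species library maps entirely within its source transcript", {
  bc <- defaultBuild()
  seqc <- as.character(bc$sequence)
  tags <- simulateTagReads(bc$truth, seqc, abundances = c(RNA1 = 1),
                           nReads = 200L, stages = "amoeba", seed = 12)
  sq <- as.character(readSequences(tags))
  rna1 <- speciesSequences(bc$truth, seqc)[["RNA1"]]
  expect_true(all(vapply(sq, function(r)
    grepl(r, rna1, fixed = TRUE), logical(1))))
})
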