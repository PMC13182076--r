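## Frozen default sequences for the synthetic rDNA chromosome.
##
## The published architecture gives the *geometry* of the repeat elements
## (unit lengths, copy numbers, spans) but the unit sequences themselves are
## only shown graphically.  The defaults below are fixed arbitrary stand-in
## sequences of the correct lengths, generated once from an internal seed
## that is independent of any user-facing seed, so that the default plan is
## identical across machines and sessions.
##
## The D-type unit (the 260 bp upstream-promoter-region repeat) is built with
## explicit internal structure: a 20 bp IR5' motif, a 20 bp IR3' motif, a
## spacer, a perfect 140 bp palindrome (65 bp arms, 10 bp loop) and a short
## tail.  The four base pairs flanking the palindrome on each side are forced
## to be non-complementary so the planted palindrome has a well-defined
## maximal span of exactly 140 bp inside the master unit.

MASTER_SEED <- 948271L

## Telomeric repeat motifs (forward strand: CCCTAA arrays at the left end,
## TTAGGG arrays at the right end).
TELOMERE_LEFT_MOTIF <- "CCCTAA"
TELOMERE_RIGHT_MOTIF <- "TTAGGG"

## 15 bp replication-origin stand-in motif (PRO1/PRO2).
PRO_MOTIF <- "GCATTACGGTCAGGA"

.mastersEnv <- new.env(parent = emptyenv())

.makeDUnit <- function(ir5) {
  armLen <- 65L
  loopLen <- 10L
  spacer <- randomDNA(70L)
  arm <- randomDNA(armLen)
  loop <- randomDNA(loopLen)
  tail10 <- randomDNA(10L)
  ir3 <- revComp(ir5)
  unit <- paste0(ir5, ir3, spacer, arm, loop, revComp(arm), tail10)
  stopifnot(nchar(unit) == 260L)
  u <- strsplit(unit, "")[[1]]
  ## force non-complementary flanks around the 140 bp palindrome (111..250)
  for (j in 1:4) {
    u[250L + j] <- u[111L - j]      # same base as partner => cannot pair
  }
  paste(u, collapse = "")
}

## Layout constants of the S956-1 group I intron stand-in (total 1,436 nt):
## 5' group I ribozyme core 250, lariat-capping ribozyme 180, HEG 955
## (containing the 51 nt spliceosomal intron I51 starting 300 nt into the
## HEG), and a 51 nt 3' remainder.  Only the totals 1,436 and 51 are
## architecture-constrained; the internal split is a package default.
S956_LAYOUT <- list(
  gir = 250L, lc = 180L, heg = 955L,
  i51_offset = 300L,   # I51 starts this many nt into the HEG
  i51_len = 51L,
  total = 1436L
)

defaultMasters <- function() {
  if (!is.null(.mastersEnv$masters)) return(.mastersEnv$masters)
  m <- withSeed(MASTER_SEED, {
    ir5 <- randomDNA(20L)
    unitLens <- c(A = 40L, B = 30L, C = 60L, E = 30L, F = 25L, G = 40L,
                  H = 35L, I = 45L, J = 40L, K = 25L, L = 20L, M = 40L,
                  N = 50L)
    units <- lapply(unitLens, randomDNA)
    d <- .makeDUnit(ir5)
    intron <- randomDNA(S956_LAYOUT$total)
    ## the base right after the poly(A) site (end of HEG) must not be an A,
    ## so that templated/untemplated tail assignment is unambiguous
    pa <- S956_LAYOUT$gir + S956_LAYOUT$lc + S956_LAYOUT$heg
    if (substr(intron, pa + 1L, pa + 1L) == "A")
      substr(intron, pa + 1L, pa + 1L) <- "G"
    c(units, list(D = d, IR5 = ir5, IR3 = revComp(ir5), S956 = intron))
  })
  .mastersEnv$masters <- m
  m
}
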