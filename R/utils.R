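#' @import methods
#' @importFrom stats median rbinom rexp rnorm rpois runif
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

## Run code under a given seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA sequence
#'
#' Draws a uniform random DNA string from the current RNG stream.
#'
#' @param n Length in bp.
#' @return A single character string of A/C/G/T.
#' @export
randomDNA <- function(n) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a character DNA string
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  vapply(x, function(s) {
    r <- rev(charToRaw(chartr("ACGTacgtN", "TGCAtgcaN", s)))
    rawToChar(r)
  }, character(1), USE.NAMES = FALSE)
}

complementBase <- function(b) chartr("ACGT", "TGCA", b)

## Substitution-only mutation of one DNA string at a per-base rate.
## Mutated bases always change (draw from the three alternatives).
mutateSeq <- function(x, rate) {
  n <- nchar(x)
  if (n == 0L || rate <= 0) return(x)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(x)
  pos <- sample.int(n, k)
  r <- charToRaw(x)
  cur <- rawToChar(r[pos], multiple = TRUE)
  new <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), character(1))
  r[pos] <- charToRaw(paste(new, collapse = ""))
  rawToChar(r)
}

## Mutate many reads at once via one concatenated raw vector (fast path for
## read simulation; equivalent to mutateSeq per read).
mutateMany <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  big <- charToRaw(paste(reads, collapse = ""))
  n <- length(big)
  k <- rbinom(1L, n, rate)
  if (k > 0L) {
    pos <- sample.int(n, k)
    cur <- rawToChar(big[pos], multiple = TRUE)
    new <- vapply(cur, function(b) sample(setdiff(BASES, b), 1L), character(1))
    big[pos] <- charToRaw(paste(new, collapse = ""))
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  all <- rawToChar(big)
  substring(all, starts, ends)
}

## Count of positions at which two equal-length strings differ.
countMismatches <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

## Round half away from zero to `digits` decimals (11.25 -> 11.3).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

asChar <- function(x) {
  if (is.character(x)) x else as.character(x)
}
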