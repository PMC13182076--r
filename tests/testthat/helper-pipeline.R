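## Memoized expensive fixtures shared across test files (computed on first
## use; everything is derived from the default plan at seed 1).
.fixtureCache <- new.env(parent = emptyenv())

defaultBuild <- function() {
  if (is.null(.fixtureCache$build))
    .fixtureCache$build <- buildChromosome(defaultPlan(), 1L)
  .fixtureCache$build
}

defaultPipeline <- function() {
  if (is.null(.fixtureCache$pipe))
    .fixtureCache$pipe <- runPipeline(seed = 1L)
  .fixtureCache$pipe
}

truthFeature <- function(truth, id) {
  i <- which(S4Vectors::mcols(truth)$ID == id)
  c(GenomicRanges::start(truth)[i[1]], GenomicRanges::end(truth)[i[1]])
}
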