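#' Longest exact match between a query motif and a region
#'
#' Finds the length of the longest common exact substring between
#' \code{query} and \code{region}, considering the region in forward and
#' reverse-complement orientation, and returns all maximal hit positions in
#' region coordinates.  Used to locate short conserved motifs (such as the
#' 15 bp replication-origin cores shared between myxomycete rDNAs) inside
#' larger regions.
#'
#' @param query Query motif sequence.
#' @param region Region sequence to search.
#' @return List with \code{length} (bp; 0 when no common substring exists)
#'   and \code{hits}, a data.frame of \code{start}, \code{end} (1-based in
#'   \code{region}) and \code{strand}.
#' @export
longestExactMatch <- function(query, region) {
  q <- asChar(query); r <- asChar(region)
  stopifnot(nchar(q) > 0L, nchar(r) > 0L)
  rrc <- revComp(r)
  nq <- nchar(q); nr <- nchar(r)

  subsOf <- function(x, L) {
    n <- nchar(x)
    if (L > n) return(character(0))
    st <- seq_len(n - L + 1L)
    substring(x, st, st + L - 1L)
  }
  hasCommon <- function(L) {
    qs <- unique(subsOf(q, L))
    any(qs %in% subsOf(r, L)) || any(qs %in% subsOf(rrc, L))
  }

  lo <- 0L; hi <- min(nq, nr)   # invariant: common at lo, none at hi + 1
  if (!hasCommon(1L)) {
    return(list(length = 0L,
                hits = data.frame(start = integer(0), end = integer(0),
                                  strand = character(0))))
  }
  lo <- 1L
  while (lo < hi) {
    mid <- as.integer((lo + hi + 1) %/% 2)
    if (hasCommon(mid)) lo <- mid else hi <- mid - 1L
  }
  L <- lo
  qs <- unique(subsOf(q, L))
  hits <- list()
  for (x in qs) {
    f <- gregexpr(x, r, fixed = TRUE)[[1]]
    if (f[1] != -1L)
      hits[[length(hits) + 1L]] <- data.frame(start = as.integer(f),
                                              end = as.integer(f) + L - 1L,
                                              strand = "+")
    b <- gregexpr(x, rrc, fixed = TRUE)[[1]]
    if (b[1] != -1L) {
      st <- nr - (as.integer(b) + L - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(start = st, end = st + L - 1L,
                                              strand = "-")
    }
  }
  hits <- unique(do.call(rbind, hits))
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(length = L, hits = hits)
}
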