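## Outward arm extension for a palindrome candidate.  Pairs (l, r) step
## outward from the arm ends; a mismatching pair is bridged only when at
## least one of the next two outward pairs matches, and arms are finally
## retracted so the outermost pair matches.  This tolerates isolated
## substitutions inside diverged arms without walking into flanking
## non-palindromic sequence.
.extendArms <- function(ch, comp, leftStart, rightEnd) {
  n <- length(ch)
  pairOK <- function(l, r) l >= 1L && r <= n && ch[l] == comp[r]
  l <- leftStart; r <- rightEnd
  repeat {
    nl <- l - 1L; nr <- r + 1L
    if (nl < 1L || nr > n) break
    if (pairOK(nl, nr)) {
      l <- nl; r <- nr
    } else if (pairOK(nl - 1L, nr + 1L) || pairOK(nl - 2L, nr + 2L)) {
      l <- nl; r <- nr
    } else break
  }
  while (l < leftStart && !pairOK(l, r)) {
    l <- l + 1L; r <- r - 1L
  }
  c(l, r)
}

#' Call palindromes (inverted repeats) from self dot-plot matches
#'
#' Antisense diagonal runs whose two intervals are disjoint, near-adjacent
#' (loop at most \code{maxLoop}) and mirror-symmetric are merged into
#' palindrome calls.  Arm boundaries are refined by mismatch-tolerant
#' outward extension, arms are trimmed to equal length about the palindrome
#' axis, and each call is annotated with the arm identity fraction.
#' Calls are sorted by span (descending); overlapping calls are resolved in
#' favour of the larger span.
#'
#' @param seq The sequence the matches were computed from.
#' @param matches Optional output of \code{\link{selfDotplot}}; computed
#'   with defaults when \code{NULL}.
#' @param minArm Minimal arm length in bp.
#' @param maxLoop Maximal loop (spacer between arms) in bp.
#' @param k Word size used when \code{matches} is computed here.
#' @param refine Whether to apply mismatch-tolerant arm extension.
#' @return data.frame with columns \code{left_start, left_end, right_start,
#'   right_end, loop, span, half_identity}.
#' @export
callPalindromes <- function(seq, matches = NULL, minArm = 60L, maxLoop = 50L,
                            k = 12L, refine = TRUE, minArmCoverage = 0.5,
                            minIdentity = 0.8) {
  seqc <- asChar(seq)
  if (is.null(matches)) matches <- selfDotplot(seqc, k = k)
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      loop = integer(0), span = integer(0),
                      half_identity = numeric(0))
  a <- matches[matches$orientation == "antisense" &
                 matches$q_start <= matches$t_start, , drop = FALSE]
  if (nrow(a) == 0L) return(empty)
  ch <- strsplit(seqc, "")[[1]]
  comp <- chartr("ACGT", "TGCA", ch)

  ## cluster runs sharing an antidiagonal axis (tolerance +/- 3 bp), then
  ## sub-cluster by q proximity: distinct inverted repeats can share an
  ## axis by coincidence (e.g. symmetric pairs across tandem-array units)
  ## without belonging to one palindrome
  a$axis <- a$q_start + a$t_end
  a <- a[order(a$axis), , drop = FALSE]
  cl <- cumsum(c(1L, diff(a$axis) > 6L))
  connectGap <- 100L
  sub <- integer(nrow(a))
  for (g in split(seq_len(nrow(a)), cl)) {
    o <- g[order(a$q_start[g])]
    maxEnd <- a$q_end[o[1]]
    s <- 1L
    sub[o[1]] <- s
    for (i in o[-1]) {
      if (a$q_start[i] > maxEnd + connectGap) s <- s + 1L
      sub[i] <- s
      maxEnd <- max(maxEnd, a$q_end[i])
    }
  }
  cl <- paste(cl, sub)
  calls <- list()
  for (g in split(seq_len(nrow(a)), cl)) {
    runs <- a[g, , drop = FALSE]
    axis <- runs$axis[which.max(runs$length)]   # axis of the dominant run
    leftStart <- min(runs$q_start)
    leftEnd <- max(runs$q_end)
    rightStart <- axis - leftEnd
    rightEnd <- axis - leftStart
    if (leftEnd >= rightStart) {
      ## arms meet at the centre (short or absent loop): split at the axis
      half <- (rightEnd - leftStart + 1L) %/% 2L
      leftEnd <- leftStart + half - 1L
      rightStart <- rightEnd - half + 1L
    }
    loop <- rightStart - leftEnd - 1L
    if (loop > maxLoop) next
    ## arm support: the antisense runs must cover most of the claimed arm,
    ## otherwise the cluster is a constellation of distinct inverted
    ## repeats (e.g. across tandem-array units), not one palindrome
    cs <- pmax(runs$q_start, leftStart)
    ce <- pmin(runs$q_end, leftEnd)
    okc <- cs <= ce
    covered <- if (any(okc)) {
      m <- .mergeIntervals(cs[okc], ce[okc], 0L)
      sum(m[, 2] - m[, 1] + 1L)
    } else 0L
    if (covered < minArmCoverage * (leftEnd - leftStart + 1L)) next
    if (refine) {
      ext <- .extendArms(ch, comp, leftStart, rightEnd)
      d <- leftStart - ext[1]
      leftStart <- ext[1]; rightEnd <- ext[2]
      leftEnd <- leftEnd    # inner ends unchanged
      rightStart <- rightStart
    }
    armLen <- min(leftEnd - leftStart + 1L, rightEnd - rightStart + 1L)
    if (armLen < minArm) next
    leftEnd <- leftStart + armLen - 1L
    rightStart <- rightEnd - armLen + 1L
    if (rightStart <= leftEnd) next
    span <- rightEnd - leftStart + 1L
    hid <- .halfIdentityArms(ch, comp, leftStart, leftEnd, rightStart,
                             rightEnd)
    if (hid < minIdentity) next
    calls[[length(calls) + 1L]] <- data.frame(
      left_start = leftStart, left_end = leftEnd,
      right_start = rightStart, right_end = rightEnd,
      loop = rightStart - leftEnd - 1L, span = span, half_identity = hid)
  }
  if (!length(calls)) return(empty)
  res <- do.call(rbind, calls)
  res <- res[order(-res$span), , drop = FALSE]
  ## resolve overlaps: keep the largest-span call of each overlapping group
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (res$left_start[i] <= res$right_end[j] &&
          res$right_end[i] >= res$left_start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.halfIdentityArms <- function(ch, comp, ls, le, rs, re) {
  L <- min(le - ls + 1L, re - rs + 1L)
  if (L <= 0L) stop("zero-length palindrome arms")
  left <- ch[ls:(ls + L - 1L)]
  right <- rev(comp[(re - L + 1L):re])
  mean(left == right)
}

#' Arm identity of a palindrome call
#'
#' Fraction of positions at which the left arm equals the reverse
#' complement of the right arm (arms trimmed to the shorter length;
#' ungapped comparison).
#'
#' @param seq The sequence.
#' @param call One row of the data.frame returned by
#'   \code{\link{callPalindromes}} (or any list with \code{left_start},
#'   \code{left_end}, \code{right_start}, \code{right_end}).
#' @return Identity fraction in [0, 1].
#' @export
halfIdentity <- function(seq, call) {
  seqc <- asChar(seq)
  ch <- strsplit(seqc, "")[[1]]
  comp <- chartr("ACGT", "TGCA", ch)
  .halfIdentityArms(ch, comp, call$left_start, call$left_end,
                    call$right_start, call$right_end)
}
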