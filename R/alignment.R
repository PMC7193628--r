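#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment under an affine gap model in which a
#' gap of length `L` costs `gap_open + gap_extend * (L - 1)`; end gaps are
#' penalized like any other gap.  The defaults mirror the classic
#' EDNAFULL-style global-alignment convention (match +5, mismatch -4, gap
#' open 10, extend 0.5).  `N` scores as a mismatch against every base.
#' Traceback ties resolve diagonal first, then gap-in-`b`, then gap-in-`a`,
#' so the returned alignment is deterministic.
#'
#' @param a,b DNA strings over `{A,C,G,T,N}`.
#' @param match,mismatch substitution scores.
#' @param gap_open penalty (positive number) for the first base of a gap.
#' @param gap_extend penalty for each additional gap base.
#' @return a list of class `"nwAlignment"` with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, and `ops` -- a
#'   run-length `data.frame` of operations (`match`, `mismatch`,
#'   `insertion`, `deletion`) with 0-based half-open coordinates on `b`
#'   (`b_start`, `b_end`) and on `a` (`a_start`, `a_end`); insertions have
#'   `b_start == b_end`.
#' @examples
#' aln <- needlemanWunsch("GATTACA", "GATACA")
#' aln$score
#' @export
needlemanWunsch <- function(a, b, match = 5, mismatch = -4,
                            gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (!.is_dna(a, allow_n = TRUE) && nzchar(a))
    stop("'a' must be over {A,C,G,T,N}")
  if (!.is_dna(b, allow_n = TRUE) && nzchar(b))
    stop("'b' must be over {A,C,G,T,N}")
  raw <- .nw_align_cpp(a, b, match, mismatch, -abs(gap_open),
                       -abs(gap_extend))
  out <- list(aligned_a = raw$aligned_a, aligned_b = raw$aligned_b,
              score = raw$score,
              ops = alignmentOps(raw$aligned_a, raw$aligned_b))
  class(out) <- "nwAlignment"
  out
}

#' @export
print.nwAlignment <- function(x, ...) {
  cat("Global alignment, score", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Run-length operations of a gapped alignment
#'
#' @param aligned_a,aligned_b equal-length gapped strings as produced by
#'   [needlemanWunsch()].
#' @return `data.frame` with columns `op`, `length`, `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based, half-open; every `b` position is covered
#'   exactly once by non-insertion operations).
#' @export
alignmentOps <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  if (!length(ca))
    return(data.frame(op = character(), length = integer(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer()))
  kind <- ifelse(ca == "-", "deletion",
          ifelse(cb == "-", "insertion",
          ifelse(ca == cb, "match", "mismatch")))
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  a_prior <- c(0L, cumsum(ca != "-"))
  b_prior <- c(0L, cumsum(cb != "-"))
  a_start <- a_prior[starts]
  b_start <- b_prior[starts]
  a_prior <- a_prior[-1L]
  b_prior <- b_prior[-1L]
  data.frame(op = r$values, length = r$lengths,
             a_start = as.integer(a_start),
             a_end = as.integer(a_prior[ends]),
             b_start = as.integer(b_start),
             b_end = as.integer(b_prior[ends]))
}
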