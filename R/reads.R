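#' Trim 3' adapter read-through
#'
#' Removes the longest read suffix that matches a prefix of the adapter
#' (minimum 3 nt, at most one mismatch allowed per 10 nt of match), with
#' qualities trimmed in step.  Reads without adapter content are returned
#' unchanged.
#'
#' @param reads a `QualityScaledDNAStringSet`.
#' @param adapter adapter sequence (non-empty).
#' @param min_match shortest adapter prefix considered (default 3 nt).
#' @return a `QualityScaledDNAStringSet` of the same length.
#' @export
trimAdapter <- function(reads, adapter, min_match = 3L) {
  stopifnot(nzchar(adapter))
  adapter <- toupper(adapter)
  bases <- as.character(reads)
  quals <- .phred_scores(reads)
  keep <- vapply(bases, .trim_adapter_cpp, integer(1),
                 adapter = adapter, min_match = as.integer(min_match),
                 USE.NAMES = FALSE)
  sequenceReads(names(reads), substr(bases, 1L, keep),
                mapply(function(q, k) q[seq_len(k)], quals, keep,
                       SIMPLIFY = FALSE))
}

#' Merge overlapping read pairs
#'
#' Reverse-complements the mate, finds the overlap with the most matching
#' bases (length at least `min_overlap`, mismatch fraction at most
#' `max_mismatch_frac`), and merges the pair; base disagreements in the
#' overlap resolve to the higher-quality base (ties keep the forward
#' read's call).  Pairs with no acceptable overlap are reported as merge
#' failures and dropped from the merged set.
#'
#' @param r1,r2 `QualityScaledDNAStringSet`s of equal length; `r2` holds
#'   the reverse-strand mates as sequenced.
#' @param min_overlap minimum acceptable overlap (default 10 nt).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap
#'   (default 0.2).
#' @return a list with `merged` (a `QualityScaledDNAStringSet` of the
#'   successfully merged fragments, named by read id) and `failed`
#'   (character vector of unmergeable read ids).
#' @export
mergePairs <- function(r1, r2, min_overlap = 10L, max_mismatch_frac = 0.2) {
  stopifnot(length(r1) == length(r2))
  s1 <- as.character(r1)
  q1 <- .phred_scores(r1)
  s2 <- vapply(as.character(r2), .revcomp, character(1), USE.NAMES = FALSE)
  q2 <- lapply(.phred_scores(r2), rev)
  ids <- names(r1)
  n <- length(s1)
  ok <- logical(n)
  mb <- character(n)
  mq <- vector("list", n)
  for (i in seq_len(n)) {
    res <- .merge_pair_cpp(s1[[i]], q1[[i]], s2[[i]], q2[[i]],
                           as.integer(min_overlap), max_mismatch_frac)
    if (isTRUE(res$ok)) {
      ok[i] <- TRUE
      mb[i] <- res$merged
      mq[[i]] <- res$quals
    }
  }
  list(merged = sequenceReads(ids[ok], mb[ok], mq[ok]),
       failed = ids[!ok])
}
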