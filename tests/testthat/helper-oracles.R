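# Independent brute-force oracles.  These deliberately share no code with
# the package: the aligner oracle enumerates every global alignment path,
# the rank-sum oracle enumerates every rank configuration.

# optimal global alignment score by exhaustive path enumeration under the
# affine model: a gap of length L costs gap_open + gap_extend * (L - 1)
nwBruteScore <- function(a, b, match = 5, mismatch = -4,
                         gap_open = -10, gap_extend = -0.5) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == "N" || B[j] == "N") mismatch
           else if (A[i] == B[j]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(A))
      best <- max(best, (if (last == "A") gap_extend else gap_open) +
                    rec(i + 1L, j, "A"))
    if (j <= length(B))
      best <- max(best, (if (last == "B") gap_extend else gap_open) +
                    rec(i, j + 1L, "B"))
    best
  }
  rec(1L, 1L, "M")
}

# exact two-sided Mann-Whitney p by enumerating all C(n+m, n) rank
# configurations (tie-free data only)
mwBruteP <- function(x, y) {
  n <- length(x)
  m <- length(y)
  stopifnot(anyDuplicated(c(x, y)) == 0L)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  cfgs <- utils::combn(n + m, n)
  u_all <- colSums(cfgs) - n * (n + 1) / 2
  mean(abs(u_all - n * m / 2) >= abs(u_obs - n * m / 2))
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

randomDna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# deterministic toy amplicon: 120 bp reference, protospacer at 41..60,
# PAM right after, two donor flags downstream of the cut (cut_index 57)
toyAmpliconSpec <- function(window_halfwidth = 3L) {
  set.seed(4242)
  ref <- randomDna(120)
  ps <- substr(ref, 41, 60)
  pam <- paste0("N", substr(ref, 62, 63))
  flip <- function(b) chartr("ACGT", "CGTA", b)
  don <- ref
  substr(don, 64, 64) <- flip(substr(ref, 64, 64))
  substr(don, 70, 70) <- flip(substr(ref, 70, 70))
  AmpliconSpec(
    "toy", ref, don, protospacer = ps, pam = pam,
    flags = data.frame(
      ref_pos = c(63L, 69L),
      ref_base = c(substr(ref, 64, 64), substr(ref, 70, 70)),
      alt_base = c(substr(don, 64, 64), substr(don, 70, 70))),
    window_halfwidth = window_halfwidth)
}

# the four canonical constructed reads for a spec
canonicalReads <- function(spec) {
  ref <- refSeq(spec)
  don <- donorSeq(spec)
  cut <- cutIndex(spec)
  ins1 <- paste0(substr(ref, 1, cut), "A", substring(ref, cut + 1))
  del2 <- paste0(substr(don, 1, cut - 1), substring(don, cut + 2))
  sequenceReads(c("unedited", "hdr", "nhej_ins1", "mixed_del2"),
                c(ref, don, ins1, del2))
}
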