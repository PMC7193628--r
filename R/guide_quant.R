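#' Count guide-cassette reads against a library
#'
#' Assigns each read to the unique guide whose protospacer occurs exactly
#' (forward orientation, no mismatches) within the read.  Reads matching
#' no protospacer -- or, pathologically, more than one -- are counted as
#' unassigned; ambiguous matches are additionally reported.  Exact
#' matching is a deliberate policy: with unique fixed-length protospacers
#' it is deterministic and errors cannot silently reassign reads.
#'
#' @param reads a `QualityScaledDNAStringSet` (or `DNAStringSet`) of
#'   cassette reads.
#' @param library a [GuideLibrary-class].
#' @return list with `counts` (named integer vector in library order),
#'   `unassigned` and `ambiguous` (integer scalars;
#'   `sum(counts) + unassigned == length(reads)`).
#' @export
countGuides <- function(reads, library) {
  stopifnot(is(library, "GuideLibrary"), length(library) > 0L)
  sp <- protospacers(library)
  n_reads <- length(reads)
  counts <- setNames(integer(length(sp)), guideIds(library))
  ambiguous <- 0L
  if (n_reads) {
    subject <- Biostrings::DNAStringSet(as.character(reads))
    widths <- nchar(sp)
    if (length(unique(widths)) == 1L) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sp))
      hits <- Biostrings::vwhichPDict(pd, subject)
    } else {
      # mixed spacer lengths: per-pattern scan
      hit_mat <- vapply(sp, function(p)
        Biostrings::vcountPattern(p, subject) > 0L, logical(n_reads))
      hits <- apply(hit_mat, 1L, which, simplify = FALSE)
    }
    nh <- lengths(hits)
    ambiguous <- sum(nh > 1L)
    uniq <- unlist(hits[nh == 1L], use.names = FALSE)
    if (length(uniq)) {
      tab <- tabulate(uniq, nbins = length(sp))
      counts[] <- as.integer(tab)
    }
  }
  list(counts = counts,
       unassigned = n_reads - sum(counts),
       ambiguous = as.integer(ambiguous))
}

#' Assemble a screen count matrix
#'
#' @param counts guides x samples integer matrix (rownames = guide ids in
#'   library order) or a named list of [countGuides()] results.
#' @param library the [GuideLibrary-class] the counts refer to.
#' @param unassigned per-sample unassigned read counts.
#' @return a `SummarizedExperiment` with assay `counts`, the library in
#'   `rowData` and `metadata(x)$unassigned`.
#' @export
screenCounts <- function(counts, library, unassigned = NULL) {
  stopifnot(is(library, "GuideLibrary"))
  if (is.list(counts) && !is.matrix(counts)) {
    unassigned <- vapply(counts, `[[`, integer(1), "unassigned")
    counts <- vapply(counts, `[[`, integer(length(library)), "counts")
  }
  stopifnot(is.matrix(counts), nrow(counts) == length(library),
            all(counts >= 0))
  if (is.null(rownames(counts))) rownames(counts) <- guideIds(library)
  stopifnot(identical(rownames(counts), guideIds(library)))
  if (is.null(unassigned))
    unassigned <- setNames(integer(ncol(counts)), colnames(counts))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(as.data.frame(library)),
    metadata = list(unassigned = unassigned))
}

#' Counts-per-million normalization
#'
#' `cpm = count / assigned_total * 1e6`, per sample, over assigned reads
#' only; per-sample cpm therefore sums to 1e6.
#'
#' @param x a `SummarizedExperiment` with a `counts` assay, or a plain
#'   counts matrix.
#' @return same shape as the input: the `SummarizedExperiment` gains a
#'   `cpm` assay, a matrix input returns the cpm matrix.
#' @export
normalizeCPM <- function(x) {
  counts <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop("sample has zero assigned reads: ",
         paste(colnames(counts)[zero], collapse = ", "))
  cpm <- sweep(counts, 2L, totals, "/") * 1e6
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "cpm") <- cpm
    x
  } else cpm
}

#' Per-guide log2 enrichment between two populations
#'
#' Computes, for every guide, `log2((sorted_cpm + pseudocount) /
#' (baseline_cpm + pseudocount))` -- the guide-level phenotype of a
#' sorting screen.  The pseudocount keeps the value finite at zero
#' counts; guides with baseline cpm below `qc_min_cpm` are flagged as
#' failing QC so downstream statistics can drop them.  Control guides
#' carry `gene = NA`.
#'
#' @param x a `SummarizedExperiment` from [screenCounts()] /
#'   [simulateScreenCounts()].
#' @param sorted,baseline sample (column) names to contrast, defaults
#'   `"GFP"` vs `"PRESORT"`.
#' @param pseudocount added to both cpm values (default 1).
#' @param qc_min_cpm QC floor on baseline cpm (default 1).
#' @return `data.frame` with `guide_id`, `gene`, `is_control`,
#'   `baseline_cpm`, `sorted_cpm`, `log2_enrichment`, `passes_qc`.
#' @export
guideEnrichment <- function(x, sorted = "GFP", baseline = "PRESORT",
                            pseudocount = 1, qc_min_cpm = 1) {
  stopifnot(is(x, "SummarizedExperiment"))
  if (!all(c(sorted, baseline) %in% colnames(x)))
    stop("samples not found: need '", sorted, "' and '", baseline, "'")
  if (!"cpm" %in% SummarizedExperiment::assayNames(x))
    x <- normalizeCPM(x)
  cpm <- SummarizedExperiment::assay(x, "cpm")
  rd <- SummarizedExperiment::rowData(x)
  s <- cpm[, sorted]
  b <- cpm[, baseline]
  data.frame(
    guide_id = rd$guide_id,
    gene = ifelse(rd$is_control, NA_character_, rd$gene),
    is_control = rd$is_control,
    baseline_cpm = unname(b),
    sorted_cpm = unname(s),
    log2_enrichment = unname(log2((s + pseudocount) / (b + pseudocount))),
    passes_qc = unname(b >= qc_min_cpm),
    stringsAsFactors = FALSE)
}

#' Average guide enrichments across replicate screens
#'
#' Replicates are processed independently; per-guide log2 enrichments are
#' averaged (and QC flags AND-ed) before gene-level statistics.  The
#' combination rule is isolated here so an alternative is one function
#' swap.
#'
#' @param replicates list of [guideEnrichment()] data.frames over the
#'   same guide universe.
#' @return a single guide-phenotype `data.frame`.
#' @export
averageReplicates <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  base <- replicates[[1L]]
  for (r in replicates[-1L]) {
    stopifnot(identical(r$guide_id, base$guide_id))
    base$log2_enrichment <- base$log2_enrichment + r$log2_enrichment
    base$baseline_cpm <- base$baseline_cpm + r$baseline_cpm
    base$sorted_cpm <- base$sorted_cpm + r$sorted_cpm
    base$passes_qc <- base$passes_qc & r$passes_qc
  }
  k <- length(replicates)
  base$log2_enrichment <- base$log2_enrichment / k
  base$baseline_cpm <- base$baseline_cpm / k
  base$sorted_cpm <- base$sorted_cpm / k
  base
}
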