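#' @importFrom stats wilcox.test pnorm p.adjust setNames
NULL

#' Mann-Whitney test of a gene's guides against the control null
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) p-value comparing one
#' gene's guide enrichments to the distribution of non-targeting control
#' guide enrichments.  For small tie-free samples (`n <= 8`, `m <= 12`)
#' the exact null distribution is used; otherwise the tie-corrected
#' normal approximation with continuity correction.  Genes with fewer
#' than two usable guides get `NA` (a missing-value sentinel, never a
#' fabricated p-value).
#'
#' @param x numeric, one gene's guide-level enrichments.
#' @param controls numeric, control-guide enrichments (non-empty).
#' @return p-value in (0, 1], or `NA` when `length(x) < 2`.
#' @export
geneMannWhitney <- function(x, controls) {
  if (!length(controls)) stop("control enrichment distribution is empty")
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  n <- length(x)
  m <- length(controls)
  ties <- anyDuplicated(c(x, controls)) > 0L
  if (n <= 8L && m <= 12L && !ties)
    return(wilcox.test(x, controls, exact = TRUE)$p.value)
  # tie-corrected normal approximation with continuity correction
  # (identical to the standard large-sample rank-sum formula)
  r <- rank(c(x, controls))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  z <- u - n * m / 2
  tie_tab <- table(r)
  sigma <- sqrt((n * m / 12) *
                ((n + m + 1) - sum(tie_tab^3 - tie_tab) /
                   ((n + m) * (n + m - 1))))
  if (sigma == 0) return(1)
  z <- (z - sign(z) * 0.5) / sigma
  min(2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
}

#' Collapse guide enrichments to a gene-level phenotype score
#'
#' Mean of the `k` guides with the largest absolute enrichment (all
#' guides when fewer than `k` are available) -- the "top three
#' guide-level phenotypes" collapse used by reporter-sorting screens.
#'
#' @param enrichments numeric, non-empty guide enrichments for one gene.
#' @param k number of extreme guides to average (default 3).
#' @return the collapsed phenotype score.
#' @export
collapseGeneScore <- function(enrichments, k = 3L) {
  enrichments <- enrichments[!is.na(enrichments)]
  if (!length(enrichments)) stop("no guide enrichments to collapse")
  top <- order(abs(enrichments), decreasing = TRUE)[
    seq_len(min(k, length(enrichments)))]
  mean(enrichments[top])
}

#' Gene-level screen scoring
#'
#' Collapses guide enrichments per gene ([collapseGeneScore()]), tests
#' each gene's guide set against the non-targeting-control null
#' ([geneMannWhitney()]), and calls hits at `p < alpha`
#' ([callHits()]).  Only guides passing QC enter the statistics; genes
#' left with fewer than `min_guides` usable guides carry `NA` p-values
#' and are never hits.  A Benjamini-Hochberg column is attached for
#' information only; hit calling uses the raw threshold.
#'
#' @param guide_phenotypes a [guideEnrichment()] (or
#'   [averageReplicates()]) data.frame.
#' @param alpha hit-calling threshold on the raw p-value (default 0.005,
#'   strict `<`).
#' @param k guides averaged in the collapsed score (default 3).
#' @param min_guides minimum usable guides per gene (default 2).
#' @return `data.frame` sorted by p then |score|: `gene`,
#'   `phenotype_score`, `p_value`, `p_adj`, `n_guides_used`, `is_hit`,
#'   `direction` (`"required"` for negative scores, `"repressor"` for
#'   positive).
#' @export
scoreGenes <- function(guide_phenotypes, alpha = 0.005, k = 3L,
                       min_guides = 2L) {
  gp <- guide_phenotypes
  controls <- gp$log2_enrichment[gp$is_control & gp$passes_qc]
  if (!length(controls))
    stop("no usable control guides; cannot form the null distribution")
  tg <- gp[!gp$is_control, , drop = FALSE]
  usable <- split(tg$log2_enrichment[tg$passes_qc],
                  tg$gene[tg$passes_qc])
  all_genes <- unique(tg$gene)
  res <- data.frame(gene = all_genes,
                    phenotype_score = NA_real_, p_value = NA_real_,
                    n_guides_used = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(all_genes)) {
    e <- usable[[all_genes[i]]]
    if (is.null(e) || !length(e)) next
    res$n_guides_used[i] <- length(e)
    res$phenotype_score[i] <- collapseGeneScore(e, k)
    if (length(e) >= min_guides)
      res$p_value[i] <- geneMannWhitney(e, controls)
  }
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  callHits(res, alpha = alpha)
}

#' Call screen hits at a raw p-value threshold
#'
#' `is_hit = p_value < alpha` (strict inequality, so a gene at exactly
#' the threshold is not a hit); direction follows the sign of the
#' phenotype score (`required`: knockdown depletes HDR, negative score;
#' `repressor`: knockdown enriches HDR, positive score).  Output is
#' sorted by p-value, then by decreasing |score|.
#'
#' @param genes gene-level `data.frame` with `p_value` and
#'   `phenotype_score`.
#' @param alpha threshold (default 0.005).
#' @return the annotated, sorted `data.frame`.
#' @export
callHits <- function(genes, alpha = 0.005) {
  if (!nrow(genes)) {
    genes$is_hit <- logical(0)
    genes$direction <- character(0)
    return(genes)
  }
  genes$is_hit <- !is.na(genes$p_value) & genes$p_value < alpha
  genes$direction <- ifelse(is.na(genes$phenotype_score), NA_character_,
                            ifelse(genes$phenotype_score < 0,
                                   "required", "repressor"))
  ord <- order(genes$p_value, -abs(genes$phenotype_score), na.last = TRUE)
  out <- genes[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unity-normalize essential-gene phenotypes and bin for comparison
#'
#' For cross-screen comparison, essential genes (phenotype score < 0) are
#' unity normalized within their screen:
#' `Z = (score - min(scores)) / (max(scores) - min(scores))`, so `Z = 0`
#' is the strongest and `Z = 1` the weakest essential phenotype.  `Z` is
#' binned by half-open intervals bin 1 = [0, 0.2), 2 = [0.2, 0.4),
#' 3 = [0.4, 0.6), 4 = [0.6, 0.8), 5 = [0.8, 1].  Listed override genes
#' with a *positive* score are carried with bin 5 (`Z = NA`); other
#' positive-score genes are carried unbinned.
#'
#' @param scores named numeric vector of gene phenotype scores.
#' @param fa_positive_overrides character vector of genes assigned bin 5
#'   when their score is positive (the override list is an input, not a
#'   hard-coded set).
#' @param screen_label optional label column (e.g. `"HR"` or `"SSTR"`).
#' @return `data.frame` with `gene`, `screen_label`, `phenotype_score`,
#'   `Z`, `bin`.
#' @export
unityNormalizeBin <- function(scores, fa_positive_overrides = character(),
                              screen_label = NA_character_) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  neg <- scores[scores < 0]
  if (length(unique(neg)) < 2L)
    stop("need at least two distinct negative phenotype scores")
  z <- (neg - min(neg)) / (max(neg) - min(neg))
  bin <- findInterval(z, c(0, 0.2, 0.4, 0.6, 0.8), rightmost.closed = FALSE)
  out <- data.frame(gene = names(scores), screen_label = screen_label,
                    phenotype_score = unname(scores),
                    Z = NA_real_, bin = NA_integer_,
                    stringsAsFactors = FALSE)
  idx <- match(names(neg), out$gene)
  out$Z[idx] <- unname(z)
  out$bin[idx] <- as.integer(bin)
  override <- out$phenotype_score > 0 & out$gene %in% fa_positive_overrides
  out$bin[override] <- 5L
  out
}
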