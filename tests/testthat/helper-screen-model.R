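# Analytic expectation of the collapsed gene score under the screen
# generative model, computed directly from the model's composition
# formulas (never through the counting/scoring pipeline).  Guide noise is
# integrated by Monte Carlo over the closed-form per-guide enrichment.
modelExpectedScore <- function(mult = 4, base_hdr = 0.05,
                               noise_sd = 0.25, purity = 0.98,
                               n_genes = 2000, guides_per_gene = 5,
                               n_controls = 500, n_effect = 50,
                               pseudocount = 1, k = 3,
                               nrep = 4000, seed = 1) {
  n_guides <- n_genes * guides_per_gene + n_controls
  e2 <- exp((noise_sd * log(2))^2 / 2)  # E[2^eps], log-normal
  pbar <- ((n_genes - n_effect) * guides_per_gene * base_hdr * e2 +
             n_effect * guides_per_gene * base_hdr * mult * e2 +
             n_controls * base_hdr) / n_guides
  qbar <- 1 - pbar
  cpm1 <- 1e6 / n_guides  # cpm of a unit-representation guide
  set.seed(seed)
  reps <- replicate(nrep, {
    eps <- rnorm(guides_per_gene, 0, noise_sd)
    p <- pmin(base_hdr * mult * 2^eps, 1)
    ratio <- purity * p / pbar + (1 - purity) * (1 - p) / qbar
    enr <- log2((cpm1 * ratio + pseudocount) / (cpm1 + pseudocount))
    top <- order(abs(enr), decreasing = TRUE)[seq_len(min(k, length(enr)))]
    mean(enr[top])
  })
  stats::median(reps)
}
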