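#' @importFrom stats rnorm rbinom rmultinom runif setNames
NULL

# run expr with a private RNG stream; global .Random.seed is untouched
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# deterministic fan-out of one user seed into per-component child seeds
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

.CASSETTE_FLANK5 <- "GTGGAAAGGACGAAACACCG"
.CASSETTE_FLANK3 <- "GTTTTAGAGCTAGAAATAGC"
.DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Generate a synthetic guide library
#'
#' Builds a screen-scale catalogue: `n_genes` genes at `guides_per_gene`
#' guides per transcription start site plus `n_controls` non-targeting
#' control guides, each with a unique random protospacer of fixed length.
#'
#' @param n_genes number of targeted genes.
#' @param guides_per_gene guides per gene (default 5).
#' @param n_controls number of non-targeting control guides.
#' @param seed integer seed; identical seeds give identical libraries.
#' @param spacer_length protospacer length (default 20 nt).
#' @return a [GuideLibrary-class] with
#'   `n_genes * guides_per_gene + n_controls` entries.
#' @export
makeGuideLibrary <- function(n_genes, guides_per_gene = 5L, n_controls,
                             seed = 1L, spacer_length = 20L) {
  stopifnot(n_genes >= 0, guides_per_gene >= 1, n_controls >= 0)
  n_target <- n_genes * guides_per_gene
  n <- n_target + n_controls
  .with_seed(seed, {
    spacers <- character(0)
    for (attempt in seq_len(50L)) {
      need <- n - length(spacers)
      if (need == 0L) break
      fresh <- vapply(seq_len(need), function(i)
        paste(sample(.DNA_ALPHABET, spacer_length, replace = TRUE),
              collapse = ""), character(1))
      spacers <- unique(c(spacers, fresh))
    }
    if (length(spacers) < n)
      stop("could not generate ", n, " unique protospacers")
    spacers <- spacers[seq_len(n)]
    gene <- c(rep(sprintf("GENE%04d", seq_len(max(n_genes, 0L))),
                  each = guides_per_gene)[seq_len(n_target)],
              rep("", n_controls))
    gid_t <- if (n_target > 0L)
      paste0(gene[seq_len(n_target)], "_g",
             rep(seq_len(guides_per_gene), n_genes)) else character(0)
    gid <- c(gid_t, sprintf("CTRL%04d_g1", seq_len(max(n_controls, 0L))))
    GuideLibrary(gid, gene, spacers,
                 c(rep(FALSE, n_target), rep(TRUE, n_controls)))
  })
}

#' Screen simulation parameters
#'
#' The generative model for a BFP-to-GFP HDR reporter sorting screen: each
#' targeting guide `g` represses its gene and edits with HDR probability
#' `p_g = min(base_hdr * multiplier(gene) * 2^eps_g, 1)`, with
#' `eps_g ~ Normal(0, guide_noise_sd)` capturing guide-to-guide knockdown
#' heterogeneity; control guides edit at exactly `base_hdr`.  Cells are
#' spread over guides by a uniform multinomial, HDR cells per guide are
#' binomial, the GFP-sorted bin contains true HDR cells at
#' `sorting_purity` (contaminated by non-HDR cells otherwise), and
#' sequencing draws a multinomial of `reads_per_guide_depth * n_guides`
#' reads per population.
#'
#' @param n_genes,guides_per_gene,n_controls library dimensions (used for
#'   defaulting `n_cells`).
#' @param base_hdr baseline HDR probability (default 0.05).
#' @param effect_multipliers named numeric, per-gene HDR-effect multiplier
#'   (default 1 for every gene not listed).
#' @param guide_noise_sd log2-scale SD of per-guide efficacy (default
#'   0.25).
#' @param n_cells cells entering the sort (default 1000 per guide).
#' @param reads_per_guide_depth sequencing depth per guide (default 500).
#' @param sorting_purity FACS bin purity (default 0.98).
#' @param seed integer seed.
#' @return a validated parameter list of class `"ScreenSimParams"`.
#' @export
ScreenSimParams <- function(n_genes, guides_per_gene = 5L, n_controls,
                            base_hdr = 0.05,
                            effect_multipliers = numeric(0),
                            guide_noise_sd = 0.25, n_cells = NULL,
                            reads_per_guide_depth = 500L,
                            sorting_purity = 0.98, seed = 1L) {
  n_guides <- n_genes * guides_per_gene + n_controls
  if (is.null(n_cells)) n_cells <- 1000L * n_guides
  stopifnot(base_hdr > 0, base_hdr <= 1, guide_noise_sd >= 0,
            sorting_purity >= 0, sorting_purity <= 1, n_cells > 0)
  if (length(effect_multipliers)) {
    if (any(effect_multipliers <= 0))
      stop("effect multipliers must be > 0")
    if (base_hdr * max(effect_multipliers) > 1)
      stop("base_hdr * max(multiplier) exceeds 1")
  }
  if (reads_per_guide_depth <= 0)
    stop("reads_per_guide_depth must be positive")
  structure(list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                 n_controls = n_controls, base_hdr = base_hdr,
                 effect_multipliers = effect_multipliers,
                 guide_noise_sd = guide_noise_sd, n_cells = n_cells,
                 reads_per_guide_depth = reads_per_guide_depth,
                 sorting_purity = sorting_purity, seed = as.integer(seed)),
            class = "ScreenSimParams")
}

#' Simulate screen count data with known ground truth
#'
#' Draws per-guide read counts for the unsorted baseline (`PRESORT`), the
#' GFP-positive HDR bin (`GFP`) and the non-fluorescent bin (`NON`) under
#' the [ScreenSimParams()] generative model.
#'
#' @param library a [GuideLibrary-class].
#' @param params a [ScreenSimParams()] object.
#' @return a `SummarizedExperiment` with assay `counts`
#'   (guides x `PRESORT`,`GFP`,`NON`), the library plus truth columns
#'   (`p_g`, `multiplier`, `hdr_cells`) in `rowData`, and the parameter
#'   echo in `metadata(x)$params`.
#' @export
simulateScreenCounts <- function(library, params) {
  stopifnot(is(library, "GuideLibrary"), inherits(params, "ScreenSimParams"))
  genes <- guideGenes(library)
  ctrl <- isControl(library)
  n <- length(library)
  mult_map <- params$effect_multipliers
  unknown <- setdiff(names(mult_map), genes[!ctrl])
  if (length(unknown))
    stop("effect multiplier for unknown gene: ", unknown[1])
  mult <- rep(1, n)
  if (length(mult_map)) {
    hit <- genes %in% names(mult_map)
    mult[hit] <- mult_map[genes[hit]]
  }
  mult[ctrl] <- 1
  .with_seed(params$seed, {
    eps <- rnorm(n, 0, params$guide_noise_sd)
    eps[ctrl] <- 0
    p <- pmin(params$base_hdr * mult * 2^eps, 1)
    cells <- as.vector(rmultinom(1, params$n_cells, rep(1, n)))
    h <- rbinom(n, cells, p)
    nonh <- cells - h
    pur <- params$sorting_purity
    gfp_comp <- pur * h / sum(h) + (1 - pur) * nonh / sum(nonh)
    non_comp <- pur * nonh / sum(nonh) + (1 - pur) * h / sum(h)
    depth <- params$reads_per_guide_depth * n
    counts <- cbind(
      PRESORT = as.vector(rmultinom(1, depth, cells / sum(cells))),
      GFP = as.vector(rmultinom(1, depth, gfp_comp)),
      NON = as.vector(rmultinom(1, depth, non_comp)))
    rownames(counts) <- guideIds(library)
    rd <- S4Vectors::DataFrame(as.data.frame(library),
                               p_g = p, multiplier = mult, hdr_cells = h)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), rowData = rd,
      metadata = list(params = params,
                      unassigned = setNames(c(0L, 0L, 0L),
                                            colnames(counts))))
  })
}

#' Emit guide-cassette reads for one screen population
#'
#' Writes one read per counted guide occurrence: the guide protospacer
#' embedded in fixed vector flanks, shuffled in a seeded order, as plain
#' (uncompressed) FASTQ so output bytes are reproducible run to run.
#'
#' @param counts named integer vector (guide id -> read count).
#' @param library the [GuideLibrary-class] the counts refer to.
#' @param path output FASTQ path.
#' @param seed integer seed for the read shuffle.
#' @return invisibly, the truth count vector (equal to `counts`).
#' @export
simulateScreenReads <- function(counts, library, path, seed = 1L) {
  stopifnot(is(library, "GuideLibrary"),
            all(names(counts) %in% guideIds(library)))
  sp <- setNames(protospacers(library), guideIds(library))
  gid <- rep(names(counts), counts)
  if (!length(gid)) {
    file.create(path)
    return(invisible(counts))
  }
  .with_seed(seed, {
    ord <- sample.int(length(gid))
    gid <- gid[ord]
    reads <- sequenceReads(
      ids = sprintf("read%06d_%s", seq_along(gid), gid),
      bases = paste0(.CASSETTE_FLANK5, sp[gid], .CASSETTE_FLANK3))
    writeFastq(reads, path)
  })
  invisible(counts)
}

#' Amplicon simulation parameters
#'
#' @param mixture named probability vector over outcome templates:
#'   `unedited`, `hdr`, `ins<L>@<pos>`, `del<L>@<pos>` (with `pos` an
#'   0-based reference coordinate or `cut`), and `partial@<k>` (first `k`
#'   donor flags converted, no indel).  Must sum to 1 (tolerance 1e-9).
#' @param n_reads reads to draw (default 10000, matching the >= 10,000
#'   read-per-sample depth the classifier is designed for).
#' @param substitution_error_rate per-base substitution error probability
#'   (default 0.001); sequencer indels are not simulated so the indel
#'   truth stays unambiguous.
#' @param read_length length of each mate (default 150).
#' @param adapter adapter appended when the fragment is shorter than the
#'   read length.
#' @param seed integer seed.
#' @return a validated parameter list of class `"AmpliconSimParams"`.
#' @export
AmpliconSimParams <- function(mixture, n_reads = 10000L,
                              substitution_error_rate = 0.001,
                              read_length = 150L,
                              adapter = .DEFAULT_ADAPTER, seed = 1L) {
  stopifnot(is.numeric(mixture), !is.null(names(mixture)),
            all(mixture >= 0), n_reads >= 0,
            substitution_error_rate >= 0, substitution_error_rate < 1,
            read_length >= 20)
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture probabilities must sum to 1")
  structure(list(mixture = mixture, n_reads = as.integer(n_reads),
                 substitution_error_rate = substitution_error_rate,
                 read_length = as.integer(read_length), adapter = adapter,
                 seed = as.integer(seed)),
            class = "AmpliconSimParams")
}

# build the fragment sequence for one named outcome template
.template_seq <- function(name, spec) {
  ref <- refSeq(spec)
  if (name == "unedited") return(ref)
  if (name == "hdr") return(donorSeq(spec))
  m <- regmatches(name, regexec("^(ins|del)([0-9]+)@(cut|[0-9]+)$", name))[[1]]
  if (length(m)) {
    L <- as.integer(m[3])
    pos <- if (m[4] == "cut") cutIndex(spec) else as.integer(m[4])
    if (m[2] == "del") {
      if (pos + L > nchar(ref) || pos < 0)
        stop("deletion template '", name, "' falls outside the reference")
      return(paste0(substr(ref, 1, pos), substring(ref, pos + L + 1)))
    }
    if (pos < 0 || pos > nchar(ref))
      stop("insertion template '", name, "' falls outside the reference")
    ins <- paste(rep_len(.DNA_ALPHABET, L), collapse = "")
    return(paste0(substr(ref, 1, pos), ins, substring(ref, pos + 1)))
  }
  m <- regmatches(name, regexec("^partial@([0-9]+)$", name))[[1]]
  if (length(m)) {
    k <- as.integer(m[2])
    fl <- editFlags(spec)
    if (k > nrow(fl))
      stop("partial template asks for ", k, " flags; spec has ", nrow(fl))
    s <- strsplit(ref, "", fixed = TRUE)[[1]]
    if (k > 0) s[fl$ref_pos[seq_len(k)] + 1L] <- fl$alt_base[seq_len(k)]
    return(paste(s, collapse = ""))
  }
  stop("unrecognized outcome template: ", name)
}

.add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(.DNA_ALPHABET, ch[p]), 1)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a paired-end amplicon read pool with known per-read truth
#'
#' Draws a seeded multinomial of outcome templates, applies independent
#' per-base substitution errors, and splits each fragment into a forward
#' read and a reverse-complemented mate of `read_length` bases.  When a
#' fragment is shorter than the read length the configured adapter is
#' read through, so the pool exercises adapter trimming.
#'
#' @param spec an [AmpliconSpec-class].
#' @param params an [AmpliconSimParams()] object.
#' @param r1_path,r2_path output FASTQ paths for the two mates.
#' @return a list with `truth` (`data.frame` of `read_id`, `template`),
#'   `template_counts` (the realized multinomial draw) and the two paths.
#' @export
simulateAmpliconReads <- function(spec, params, r1_path, r2_path) {
  stopifnot(is(spec, "AmpliconSpec"), inherits(params, "AmpliconSimParams"))
  tmpl_seqs <- vapply(names(params$mixture), .template_seq, character(1),
                      spec = spec)
  .with_seed(params$seed, {
    counts <- as.vector(rmultinom(1, params$n_reads, params$mixture))
    names(counts) <- names(params$mixture)
    template <- rep(names(counts), counts)
    template <- template[sample.int(length(template))]
    frags <- .add_substitution_errors(tmpl_seqs[template],
                                      params$substitution_error_rate)
    rl <- params$read_length
    pad <- function(s) {
      short <- nchar(s) < rl
      s[short] <- substr(paste0(s[short], params$adapter), 1, rl)
      s
    }
    r1 <- pad(substr(frags, 1, rl))
    r2_full <- vapply(frags, .revcomp, character(1), USE.NAMES = FALSE)
    r2 <- pad(substr(r2_full, 1, rl))
    ids <- sprintf("amp%06d", seq_along(frags))
    writeFastq(sequenceReads(ids, r1), r1_path)
    writeFastq(sequenceReads(ids, r2), r2_path)
    list(truth = data.frame(read_id = ids, template = template,
                            stringsAsFactors = FALSE),
         template_counts = counts, r1 = r1_path, r2 = r2_path)
  })
}
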