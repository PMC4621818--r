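#' Ground truth for a simulated expression experiment
#'
#' @param deg Data frame `unigene_id`, `genotype`, `tissue`, `log2fc` of
#'   planted differentially expressed genes (drought vs control). Planted
#'   effects must satisfy |log2fc| >= 1.
#' @return List of class `"expression_truth"`.
#' @export
expression_truth <- function(deg = NULL) {
  if (!is.null(deg) && any(abs(deg$log2fc) < 1))
    stop("planted DEGs must have |log2fc| >= 1", call. = FALSE)
  structure(list(deg = deg), class = "expression_truth")
}

#' Expand a factorial hybridization design
#'
#' One row per array in a genotypes x tissues x treatments x replicates
#' factorial; the default layout is 2 x 2 x 2 x 3 = 24 hybridizations.
#'
#' @param genotypes,tissues,treatments Factor levels.
#' @param n_rep Replicates per condition (>= 2 for DE testing).
#' @return Data frame `sample`, `genotype`, `tissue`, `treatment`,
#'   `replicate`.
#' @export
expand_design <- function(genotypes = c("B47", "B128"),
                          tissues = c("leaf", "root"),
                          treatments = c("control", "drought"),
                          n_rep = 3) {
  if (n_rep < 2) stop("invalid design: at least 2 replicates required", call. = FALSE)
  d <- expand.grid(replicate = seq_len(n_rep), treatment = treatments,
                   tissue = tissues, genotype = genotypes,
                   stringsAsFactors = FALSE)[, 4:1]
  d$sample <- with(d, paste(genotype, tissue, treatment,
                            paste0("r", replicate), sep = "_"))
  d[, c("sample", "genotype", "tissue", "treatment", "replicate")]
}

#' Simulate a gene-level microarray intensity matrix
#'
#' Log-normal intensities with gene-specific baselines; planted DEGs are
#' shifted by their log2 fold change in the drought samples of their
#' genotype x tissue combination.
#'
#' @param n_genes Number of unigenes (>= number of planted DEGs).
#' @param truth An [expression_truth()] object (or `NULL` for a null
#'   experiment).
#' @param seed Integer seed.
#' @param noise_sd Residual s.d. on the log2 scale. The default 0.07 is
#'   calibrated so that (i) within-condition replicate correlations sit in
#'   the high 0.9s at the default baseline spread and (ii) planted effects
#'   at the standard two-fold threshold are recoverable from triplicates by
#'   a Welch test at FDR 0.01, whose attainable p-values are floored by the
#'   2-4 degrees of freedom.
#' @param base_mean,base_sd Mean and s.d. of gene baselines (log2 scale).
#' @inheritParams expand_design
#' @return List: `intensities` (linear-scale matrix, genes x samples),
#'   `samples` (annotation data frame), `truth`.
#' @export
simulate_expression <- function(n_genes = 2000, truth = expression_truth(),
                                seed = NULL, noise_sd = 0.07,
                                base_mean = 8, base_sd = 1.6,
                                genotypes = c("B47", "B128"),
                                tissues = c("leaf", "root"),
                                treatments = c("control", "drought"),
                                n_rep = 3) {
  stopifnot(inherits(truth, "expression_truth"))
  deg <- truth$deg
  if (!is.null(deg) && n_genes < length(unique(deg$unigene_id)))
    stop("'n_genes' must cover all planted DEGs", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  samples <- expand_design(genotypes, tissues, treatments, n_rep)
  ids <- sprintf("UG%05d", seq_len(n_genes))
  mu <- stats::rnorm(n_genes, base_mean, base_sd)
  log2m <- matrix(mu, n_genes, nrow(samples)) +
    matrix(stats::rnorm(n_genes * nrow(samples), 0, noise_sd), n_genes)
  dimnames(log2m) <- list(ids, samples$sample)

  if (!is.null(deg)) {
    stressed <- treatments[2]
    for (i in seq_len(nrow(deg))) {
      cols <- samples$genotype == deg$genotype[i] &
        samples$tissue == deg$tissue[i] & samples$treatment == stressed
      log2m[deg$unigene_id[i], cols] <- log2m[deg$unigene_id[i], cols] + deg$log2fc[i]
    }
  }
  list(intensities = 2^log2m, samples = samples, truth = truth)
}
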