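#' Quantile-normalize an intensity matrix
#'
#' Forces every sample column onto the common distribution given by the
#' cross-sample mean of order statistics (ties receive the average of the
#' target values). Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat Nonnegative intensity matrix, genes x samples.
#' @return Matrix of the same shape; all columns share the same sorted
#'   values.
#' @export
quantile_normalize <- function(mat) {
  if (any(mat < 0, na.rm = TRUE))
    stop("negative intensities are not allowed", call. = FALSE)
  if (any(colSums(!is.na(mat)) == 0))
    stop("invalid sample: a column is entirely missing", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Within-condition replicate correlations
#'
#' Pearson correlation for every pair of replicate arrays within each
#' genotype x tissue x treatment condition, computed on the log2 scale.
#'
#' @param mat Intensity matrix (linear scale), genes x samples.
#' @param samples Sample annotation (`sample`, `genotype`, `tissue`,
#'   `treatment`, `replicate`).
#' @param r_min Correlation below which a pair is flagged.
#' @return Data frame `genotype`, `tissue`, `treatment`, `sample1`,
#'   `sample2`, `r`, `flagged`.
#' @export
replicate_qc <- function(mat, samples, r_min = 0.9) {
  lg <- log2(mat + 1)
  cond <- interaction(samples$genotype, samples$tissue, samples$treatment,
                      drop = TRUE)
  rows <- list()
  for (cc in levels(cond)) {
    idx <- which(cond == cc)
    if (length(idx) < 2)
      stop("invalid design: condition '", cc, "' has fewer than 2 replicates",
           call. = FALSE)
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      r <- stats::cor(lg[, idx[a]], lg[, idx[b]])
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = samples$genotype[idx[a]], tissue = samples$tissue[idx[a]],
        treatment = samples$treatment[idx[a]],
        sample1 = samples$sample[idx[a]], sample2 = samples$sample[idx[b]],
        r = r, flagged = r < r_min)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Differential-expression test for one drought-vs-control contrast
#'
#' Per gene, a Welch two-sample t-test on log2 intensities between the
#' drought and control arrays of one genotype x tissue combination;
#' `log2_fc = mean(drought) - mean(control)`. Genes with zero variance in
#' both arms fall back to a pooled-variance test and are flagged. P-values
#' are Benjamini-Hochberg adjusted within the contrast.
#'
#' @param mat Quantile-normalized intensity matrix (linear scale), genes x
#'   samples.
#' @param samples Sample annotation data frame.
#' @param genotype,tissue The contrast to test.
#' @param treatments `c(control, stressed)` level names.
#' @return Data frame `unigene_id`, `genotype`, `tissue`, `log2_fc`, `p`,
#'   `fdr`, `flagged`.
#' @export
de_test <- function(mat, samples, genotype, tissue,
                    treatments = c("control", "drought")) {
  sel <- samples$genotype == genotype & samples$tissue == tissue
  ctrl <- samples$sample[sel & samples$treatment == treatments[1]]
  trt <- samples$sample[sel & samples$treatment == treatments[2]]
  if (length(ctrl) < 2 || length(trt) < 2)
    stop("invalid design: fewer than 2 replicates in an arm", call. = FALSE)
  lg <- log2(mat)
  x <- lg[, trt, drop = FALSE]; y <- lg[, ctrl, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  flagged <- v1 + v2 == 0
  if (any(flagged)) {       # no within-group variance anywhere: pooled fallback
    sp2 <- ((n1 - 1) * v1[flagged] + (n2 - 1) * v2[flagged]) / (n1 + n2 - 2)
    t2 <- (m1[flagged] - m2[flagged]) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p[flagged] <- ifelse(is.nan(t2), 1,
                         2 * stats::pt(abs(t2), n1 + n2 - 2, lower.tail = FALSE))
    p[flagged & m1 != m2] <- 0
  }
  data.frame(unigene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             genotype = genotype, tissue = tissue,
             log2_fc = m1 - m2, p = p,
             fdr = stats::p.adjust(p, method = "BH"), flagged = flagged,
             row.names = NULL)
}

#' Call differentially expressed genes and cross-genotype Venn counts
#'
#' Keeps records with fold change at least `fc_min` (linear scale, i.e.
#' |log2_fc| >= log2(fc_min)) and FDR at most `fdr_max`, both thresholds
#' inclusive, and partitions them by direction. When exactly two genotypes
#' are present, shared/unique gene counts per direction are attached.
#'
#' @param results Stacked [de_test()] output across contrasts.
#' @param fc_min Minimum linear fold change (default 2).
#' @param fdr_max Maximum FDR (default 0.01).
#' @return Data frame of DEG records (`direction` added); attribute
#'   `"venn"` holds per-direction shared/unique counts across genotypes.
#' @export
call_degs <- function(results, fc_min = 2, fdr_max = 0.01) {
  keep <- !is.na(results$fdr) & results$fdr <= fdr_max &
    abs(results$log2_fc) >= log2(fc_min)
  degs <- results[keep, , drop = FALSE]
  degs$direction <- ifelse(degs$log2_fc > 0, "up", "down")
  gts <- unique(results$genotype)
  venn <- NULL
  if (length(gts) == 2) {
    venn <- do.call(rbind, lapply(c("up", "down"), function(dir) {
      s1 <- unique(degs$unigene_id[degs$direction == dir & degs$genotype == gts[1]])
      s2 <- unique(degs$unigene_id[degs$direction == dir & degs$genotype == gts[2]])
      data.frame(direction = dir, genotype1 = gts[1], genotype2 = gts[2],
                 unique1 = length(setdiff(s1, s2)), shared = length(intersect(s1, s2)),
                 unique2 = length(setdiff(s2, s1)))
    }))
  }
  attr(degs, "venn") <- venn
  degs
}

#' Drought-response profile of a gene family
#'
#' For a family list (e.g. the aquaporins on the array), reports which
#' genotype x tissue cells each member is a DEG in, with direction, and
#' summary counts: members regulated in at least one cell, members
#' regulated in only one tissue (leaf- or root-specific), and members
#' regulated in only one genotype.
#'
#' @param degs DEG records from [call_degs()].
#' @param family_ids Unigene ids of the family.
#' @param assayed_ids Optional universe of assayed ids; family members
#'   absent from it are reported as not assayed.
#' @return List: `members` (per-member long table), `summary` (named
#'   counts), `not_assayed`.
#' @export
family_profile <- function(degs, family_ids, assayed_ids = NULL) {
  not_assayed <- character(0)
  if (!is.null(assayed_ids)) {
    not_assayed <- setdiff(family_ids, assayed_ids)
    family_ids <- intersect(family_ids, assayed_ids)
  }
  fam <- degs[degs$unigene_id %in% family_ids,
              c("unigene_id", "genotype", "tissue", "direction"), drop = FALSE]
  per <- split(fam, fam$unigene_id)
  regulated <- names(per)
  tissue_specific <- vapply(per, function(d) length(unique(d$tissue)) == 1, logical(1))
  genotype_specific <- vapply(per, function(d) length(unique(d$genotype)) == 1, logical(1))
  tissues <- vapply(per, function(d) unique(d$tissue)[1], character(1))
  list(members = fam,
       summary = c(
         family_size = length(family_ids),
         regulated = length(regulated),
         leaf_specific = sum(tissue_specific & tissues == "leaf"),
         root_specific = sum(tissue_specific & tissues == "root"),
         genotype_specific = sum(genotype_specific)),
       not_assayed = not_assayed)
}
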