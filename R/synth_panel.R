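#' Ground truth for a simulated association panel
#'
#' @param causal Data frame `marker_id`, `trait`, `effect` of planted causal
#'   markers (may be `NULL` for a pure-noise panel). `marker_id` may be given
#'   as an integer index into the simulated markers.
#' @param h2 Narrow-sense heritability of the causal-marker component, in
#'   [0, 1].
#' @param structure_sd S.d. of the subpopulation (confounding) effect added
#'   to every liability.
#' @param fst Differentiation between the two subpopulations
#'   (Balding-Nichols).
#' @return List of class `"panel_truth"`.
#' @export
panel_truth <- function(causal = NULL, h2 = 0.3, structure_sd = 0.5, fst = 0.15) {
  if (h2 < 0 || h2 > 1) stop("'h2' must lie in [0, 1]", call. = FALSE)
  structure(list(causal = causal, h2 = h2, structure_sd = structure_sd,
                 fst = fst), class = "panel_truth")
}

#' Simulate an inbred association panel with structure, kinship and scores
#'
#' Generates biallelic genotypes (coded 0/2, inbred accessions) for a panel
#' split into two subpopulations with Balding-Nichols differentiated allele
#' frequencies, an admixture matrix Q, a VanRaden kinship K computed from
#' the genotypes, and an ordinal 0-5 score table for the three visual
#' drought traits (Wt, Scu, Stg) across years. Quantitative liabilities are
#' the sum of planted marker effects, a subpopulation effect, and Gaussian
#' noise scaled to the stated heritability; scores discretize the liability
#' through equal-probability bins under the null.
#'
#' @param n_acc Number of accessions (>= 10).
#' @param n_snp Number of SNP markers.
#' @param truth A [panel_truth()] object.
#' @param seed Integer seed.
#' @param years Years to score.
#' @param n_rep Replicates per accession and year.
#' @param rep_noise_sd S.d. of replicate-level noise on the liability scale.
#' @param missing_rate Fraction of genotype calls set missing.
#' @param n_lg Number of linkage groups for the marker map.
#' @return List: `geno` (n_acc x n_snp matrix, 0/2/NA), `map` (marker_id,
#'   lg, pos_cm), `Q`, `K`, `scores` (accession, trait, year, replicate,
#'   score), `liabilities`, `truth`.
#' @export
simulate_panel <- function(n_acc = 95, n_snp = 1127, truth = panel_truth(),
                           seed = NULL, years = c(2011, 2012, 2014),
                           n_rep = 3, rep_noise_sd = 0.3,
                           missing_rate = 0, n_lg = 11) {
  stopifnot(inherits(truth, "panel_truth"))
  if (n_acc < 10) stop("'n_acc' must be >= 10", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  acc <- sprintf("ACC%03d", seq_len(n_acc))
  mk <- sprintf("M%04d", seq_len(n_snp))
  pop <- rep(1:2, length.out = n_acc)
  q1 <- ifelse(pop == 1, stats::rbeta(n_acc, 8, 2), stats::rbeta(n_acc, 2, 8))
  Q <- cbind(SV = q1, NSV = 1 - q1)
  rownames(Q) <- acc

  p_anc <- stats::runif(n_snp, 0.1, 0.9)
  fst <- truth$fst
  bn <- function(p) stats::rbeta(n_snp, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  p_pop <- cbind(bn(p_anc), bn(p_anc))
  p_ind <- outer(Q[, 1], p_pop[, 1]) + outer(Q[, 2], p_pop[, 2])
  geno <- matrix(2 * stats::rbinom(n_acc * n_snp, 1, p_ind), n_acc, n_snp,
                 dimnames = list(acc, mk))
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA

  # VanRaden kinship from the (complete-data) genotype matrix
  g0 <- geno; g0[is.na(g0)] <- rep(colMeans(geno, na.rm = TRUE), each = n_acc)[is.na(g0)]
  pbar <- colMeans(g0) / 2
  M <- sweep(g0, 2, 2 * pbar)
  K <- tcrossprod(M) / (2 * sum(pbar * (1 - pbar)))

  map <- data.frame(marker_id = mk,
                    lg = sort(rep_len(seq_len(n_lg), n_snp)),
                    pos_cm = round(stats::runif(n_snp, 0, 80), 2))
  map <- map[order(map$lg, map$pos_cm), ]
  map$marker_id <- mk   # keep ids in genotype column order
  rownames(map) <- NULL

  causal <- truth$causal
  if (!is.null(causal) && is.numeric(causal$marker_id))
    causal$marker_id <- mk[causal$marker_id]
  traits <- c("Wt", "Scu", "Stg")
  struct_eff <- truth$structure_sd * scale(Q[, 1])[, 1]

  liab <- list(); scores <- list()
  for (tr in traits) {
    gval <- rep(0, n_acc)
    if (!is.null(causal)) {
      cc <- causal[causal$trait == tr, , drop = FALSE]
      if (nrow(cc)) gval <- as.vector(g0[, cc$marker_id, drop = FALSE] %*% cc$effect)
    }
    vg <- stats::var(gval)
    sig_e <- if (vg > 0 && truth$h2 > 0) sqrt(vg * (1 - truth$h2) / max(truth$h2, 1e-8)) else 1
    if (vg > 0 && truth$h2 == 1) sig_e <- 1e-6
    for (yr in years) {
      x <- gval + struct_eff + stats::rnorm(n_acc, 0, sig_e)
      liab[[paste(tr, yr)]] <- data.frame(accession = acc, trait = tr, year = yr,
                                          liability = x)
      for (r in seq_len(n_rep)) {
        z <- scale(x + stats::rnorm(n_acc, 0, rep_noise_sd * stats::sd(x)))[, 1]
        scores[[paste(tr, yr, r)]] <- data.frame(
          accession = acc, trait = tr, year = yr, replicate = r,
          score = pmin(5L, as.integer(floor(stats::pnorm(z) * 6))))
      }
    }
  }
  list(geno = geno, map = map, Q = Q, K = K,
       scores = do.call(rbind, c(scores, list(make.row.names = FALSE))),
       liabilities = do.call(rbind, c(liab, list(make.row.names = FALSE))),
       truth = truth)
}
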