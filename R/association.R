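#' Marker QC filter
#'
#' Removes markers below a minor-allele-frequency floor or above a
#' missingness ceiling. Genotypes are coded 0/2 (inbred, no heterozygotes)
#' with `NA` for missing calls.
#'
#' @param geno Accessions x markers matrix, codes {0, 2, NA}.
#' @param maf_min Minimum minor allele frequency, in [0, 0.5].
#' @param missing_max Maximum fraction of missing calls, in [0, 1].
#' @return The filtered matrix; attribute `"removed"` is a data frame
#'   `marker`, `maf`, `missing`, `reason`.
#' @export
qc_filter <- function(geno, maf_min = 0.05, missing_max = 0.2) {
  if (maf_min < 0 || maf_min > 0.5 || missing_max < 0 || missing_max > 1)
    stop("thresholds out of range", call. = FALSE)
  miss <- colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  bad_maf <- maf < maf_min
  bad_miss <- miss > missing_max
  drop <- bad_maf | bad_miss
  if (all(drop)) stop("QC removed every marker (empty panel)", call. = FALSE)
  removed <- data.frame(marker = colnames(geno)[drop], maf = maf[drop],
                        missing = miss[drop],
                        reason = ifelse(bad_maf[drop], "maf", "missing"),
                        row.names = NULL)
  out <- geno[, !drop, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Replicate-mean trait values per accession
#'
#' @param scores Score table (`accession`, `trait`, `year`, `replicate`,
#'   `score`).
#' @param trait,year The trait-year combination to extract.
#' @return Named numeric vector of replicate means, one per accession.
#' @export
trait_means <- function(scores, trait, year) {
  s <- scores[scores$trait == trait & scores$year == year, ]
  out <- tapply(s$score, s$accession, mean)
  stats::setNames(as.numeric(out), names(out))
}

# mean-impute missing calls per marker
impute_marker_means <- function(geno) {
  if (!anyNA(geno)) return(geno)
  mu <- colMeans(geno, na.rm = TRUE)
  idx <- which(is.na(geno))
  geno[idx] <- mu[(idx - 1) %/% nrow(geno) + 1]
  geno
}

# single-marker F tests after projecting covariates out of y and markers.
# ys, X0s, Gs are already on the (possibly whitened) scale.
scan_core <- function(ys, X0s, Gs, p_cap = 1e-16) {
  qr0 <- qr(X0s)
  ry <- qr.resid(qr0, ys)
  RX <- qr.resid(qr0, Gs)
  rss0 <- sum(ry^2)
  sxx <- colSums(RX^2)
  sxy <- as.vector(crossprod(RX, ry))
  df2 <- length(ys) - qr0$rank - 1L
  rss1 <- rss0 - sxy^2 / sxx
  fstat <- (rss0 - rss1) / (rss1 / df2)
  p <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
  degenerate <- sxx < 1e-10 * nrow(Gs)
  p[degenerate] <- NA_real_
  capped <- !is.na(p) & p < p_cap
  p[capped] <- p_cap
  data.frame(p = p, neg_log10_p = -log10(p), var_explained = (rss0 - rss1) / rss0,
             capped = capped, degenerate = degenerate)
}

align_scan_inputs <- function(trait, geno, Q) {
  acc <- rownames(geno)
  if (!is.null(names(trait)) && !is.null(acc)) trait <- trait[acc]
  if (anyNA(trait)) stop("trait values missing for some accessions", call. = FALSE)
  X0 <- matrix(1, length(trait), 1)
  if (!is.null(Q)) {
    if (!is.null(rownames(Q)) && !is.null(acc)) Q <- Q[acc, , drop = FALSE]
    # rows of Q sum to 1: drop the last column to avoid collinearity
    X0 <- cbind(X0, Q[, -ncol(Q), drop = FALSE])
  }
  list(y = as.numeric(trait), X0 = X0, G = impute_marker_means(geno))
}

#' Fixed-effects (GLM) association scan with structure covariates
#'
#' Per marker, the F-test p-value for the marker-dosage term in a
#' least-squares fit of trait on intercept, the structure covariates Q
#' (last column dropped, since rows sum to 1), and the marker. Missing
#' genotype calls are mean-imputed per marker. Variance explained is the
#' partial R-squared of the marker. P-values are capped at 1e-16 (flagged)
#' and degenerate (monomorphic or covariate-collinear) markers are returned
#' with `NA`.
#'
#' @param trait Named numeric vector of replicate-mean trait values per
#'   accession.
#' @param geno Accessions x markers genotype matrix, codes {0, 2, NA}.
#' @param Q Structure proportion matrix (accessions x subpopulations), rows
#'   summing to 1; may be `NULL`.
#' @return Data frame `marker`, `neg_log10_p`, `p`, `var_explained`,
#'   `capped`, `degenerate`.
#' @export
glm_scan <- function(trait, geno, Q = NULL) {
  a <- align_scan_inputs(trait, geno, Q)
  res <- scan_core(a$y, a$X0, a$G)
  cbind(data.frame(marker = colnames(geno)), res, row.names = NULL)
}

#' Mixed-model (Q + K) association scan
#'
#' Single-marker tests in the mixed model \eqn{y = X\beta + u + e} with
#' \eqn{u \sim N(0, \sigma_g^2 K)} and \eqn{e \sim N(0, \sigma_e^2 I)}.
#' The variance ratio \eqn{\delta = \sigma_e^2/\sigma_g^2} is estimated
#' once by REML on the null (no-marker) model using the spectral
#' decomposition of K, and reused for every marker test
#' (population-parameters-previously-determined). Each marker's F statistic
#' comes from generalized least squares on the rotated, whitened data, so
#' with K = I the scan collapses exactly to [glm_scan()].
#'
#' @inheritParams glm_scan
#' @param K Symmetric positive semi-definite kinship matrix (accessions x
#'   accessions).
#' @return As [glm_scan()], plus attributes `"delta"` (variance ratio),
#'   `"sigma_g2"` and `"sigma_e2"`.
#' @export
mlm_scan <- function(trait, geno, Q = NULL, K) {
  a <- align_scan_inputs(trait, geno, Q)
  acc <- rownames(geno)
  if (!is.null(rownames(K)) && !is.null(acc)) K <- K[acc, acc]
  if (max(abs(K - t(K))) > 1e-8)
    stop("invalid kinship: K is not symmetric", call. = FALSE)
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop("invalid kinship: K is not positive semi-definite", call. = FALSE)
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- as.vector(crossprod(U, a$y))
  X0t <- crossprod(U, a$X0)
  q <- ncol(X0t); n <- length(yt)

  reml_crit <- function(log_delta) {
    w <- lam + exp(log_delta)
    X0w <- X0t / sqrt(w); yw <- yt / sqrt(w)
    fit <- stats::lm.fit(X0w, yw)
    rss <- sum(fit$residuals^2)
    xtx <- crossprod(X0w)
    as.numeric((n - q) * log(rss) + sum(log(w)) +
                 determinant(xtx, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(reml_crit, interval = c(-12, 12))
  delta <- exp(opt$minimum)

  w <- lam + delta
  ys <- yt / sqrt(w)
  X0s <- X0t / sqrt(w)
  Gs <- crossprod(U, a$G) / sqrt(w)
  res <- scan_core(ys, X0s, Gs)
  fit0 <- stats::lm.fit(X0s, ys)
  sigma_g2 <- sum(fit0$residuals^2) / (n - q)
  out <- cbind(data.frame(marker = colnames(geno)), res, row.names = NULL)
  attr(out, "delta") <- delta
  attr(out, "sigma_g2") <- sigma_g2
  attr(out, "sigma_e2") <- sigma_g2 * delta
  out
}

#' Declare significant markers with a cross-experiment consistency rule
#'
#' A marker is significant for a trait when its -log10(P) exceeds
#' `threshold` in at least `consistency_min` distinct (model, year)
#' combinations. The supporting combinations are reported in the compact
#' "G2011, M2012" style (G = fixed-effects scan, M = mixed-model scan).
#'
#' @param results Data frame with columns `marker`, `trait`, `year`,
#'   `model` ("GLM"/"MLM") and `neg_log10_p`.
#' @param threshold -log10(P) significance threshold (default 3).
#' @param consistency_min Minimum number of supporting (model, year)
#'   combinations (default 2).
#' @return Data frame `marker`, `trait`, `n_support`, `support`.
#' @export
call_significant <- function(results, threshold = 3, consistency_min = 2) {
  hit <- results[!is.na(results$neg_log10_p) & results$neg_log10_p > threshold, ]
  if (!nrow(hit))
    return(data.frame(marker = character(0), trait = character(0),
                      n_support = integer(0), support = character(0)))
  hit$combo <- paste0(substr(hit$model, 1, 1), hit$year)
  key <- paste(hit$marker, hit$trait, sep = "\r")
  out <- lapply(split(hit, key), function(d) {
    combos <- sort(unique(d$combo))
    data.frame(marker = d$marker[1], trait = d$trait[1],
               n_support = length(combos),
               support = paste(combos, collapse = ", "))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out <- out[out$n_support >= consistency_min, , drop = FALSE]
  out[order(out$marker, out$trait), , drop = FALSE]
}
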