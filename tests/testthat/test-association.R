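test_that("QC filter matches a brute-force allele count", {
  set.seed(6)
  g <- matrix(sample(c(0, 2), 40 * 30, replace = TRUE, prob = c(0.8, 0.2)),
              40, 30, dimnames = list(sprintf("a%02d", 1:40), sprintf("m%02d", 1:30)))
  g[, 5] <- 0                               # monomorphic
  g[sample(length(g), 60)] <- NA
  out <- qc_filter(g, maf_min = 0.1, missing_max = 0.08)
  keep_brute <- vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j]
    p <- mean(x, na.rm = TRUE) / 2
    maf <- min(p, 1 - p)
    !is.nan(maf) && maf >= 0.1 && mean(is.na(x)) <= 0.08
  }, logical(1))
  expect_identical(colnames(out), colnames(g)[keep_brute])
  expect_false("m05" %in% colnames(out))
  # permissive thresholds are the identity
  expect_identical(colnames(qc_filter(g, 0, 1)), colnames(g))
  expect_error(qc_filter(g, maf_min = 0.9), "range")
})

test_that("GLM scan equals the closed-form F test and the lm oracle", {
  set.seed(7)
  # worked 12-accession panel, one marker, no covariates
  y <- c(3, 5, 4, 6, 2, 5, 4, 7, 3, 6, 5, 4)
  x <- c(0, 2, 0, 2, 0, 2, 0, 2, 0, 2, 0, 2)
  g <- matrix(x, 12, 1, dimnames = list(sprintf("a%02d", 1:12), "m1"))
  res <- glm_scan(stats::setNames(y, rownames(g)), g)
  # closed-form F from sums of squares
  rss0 <- sum((y - mean(y))^2)
  b <- cov(x, y) / var(x)
  rss1 <- sum((y - mean(y) - b * (x - mean(x)))^2)
  Fst <- (rss0 - rss1) / (rss1 / 10)
  expect_equal(res$p, stats::pf(Fst, 1, 10, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$var_explained, (rss0 - rss1) / rss0, tolerance = 1e-12)

  # with structure covariates, against anova(lm(...)) per marker
  p <- simulate_panel(60, 25, seed = 8)
  yy <- trait_means(p$scores, "Stg", 2012)
  res2 <- glm_scan(yy, p$geno, p$Q)
  for (j in c(1, 7, 19)) {
    q1 <- p$Q[, 1]
    xj <- p$geno[, j]
    pj <- stats::anova(stats::lm(yy ~ q1 + xj))["xj", "Pr(>F)"]
    if (res2$degenerate[j]) next
    expect_equal(res2$p[j], pj, tolerance = 1e-10)
  }
})

test_that("a perfect marker-trait fit is reported at the p-value cap", {
  g <- matrix(rep(c(0, 2), 10), 20, 1,
              dimnames = list(sprintf("a%02d", 1:20), "m1"))
  y <- stats::setNames(as.numeric(g[, 1]), rownames(g))
  res <- glm_scan(y, g)
  expect_true(res$capped)
  expect_equal(res$neg_log10_p, 16)
})

test_that("MLM with identity kinship collapses to the GLM", {
  p <- simulate_panel(95, 150, panel_truth(h2 = 0.4), seed = 9)
  g <- qc_filter(p$geno)
  y <- trait_means(p$scores, "Scu", 2012)
  glm <- glm_scan(y, g, p$Q)
  mlm <- mlm_scan(y, g, p$Q, diag(nrow(g)))
  expect_equal(mlm$p, glm$p, tolerance = 1e-6)
})

test_that("MLM approaches the GLM when the polygenic variance is null", {
  p <- simulate_panel(80, 100, panel_truth(h2 = 0), seed = 10)
  g <- qc_filter(p$geno)
  # traits with no kinship-shaped signal; individual draws can correlate
  # with kinship eigenvectors by chance, so judge the typical behaviour
  set.seed(24)
  ratio <- numeric(5); diffs <- numeric(5)
  for (i in 1:5) {
    y <- stats::setNames(rnorm(80), rownames(g))
    mlm <- mlm_scan(y, g, p$Q, p$K)
    glm <- glm_scan(y, g, p$Q)
    ratio[i] <- 1 / attr(mlm, "delta")
    diffs[i] <- max(abs(mlm$neg_log10_p - glm$neg_log10_p))
  }
  expect_lt(stats::median(ratio), 0.05)
  expect_lt(stats::median(diffs), 0.05)
  y <- stats::setNames(rnorm(80), rownames(g))
  expect_error(mlm_scan(y, g, p$Q, matrix(rnorm(6400), 80, 80)), "symmetric")
})

test_that("scan results are invariant to marker and accession order", {
  p <- simulate_panel(50, 40, panel_truth(h2 = 0.3), seed = 12)
  g <- p$geno
  y <- trait_means(p$scores, "Wt", 2014)
  base <- mlm_scan(y, g, p$Q, p$K)
  set.seed(13)
  pm <- sample(ncol(g)); pa <- sample(nrow(g))
  shuf <- mlm_scan(y[pa], g[pa, pm], p$Q[pa, ], p$K[pa, pa])
  expect_equal(shuf$p[match(base$marker, shuf$marker)], base$p, tolerance = 1e-8)
})

test_that("significance calling applies the threshold and consistency rule", {
  res <- data.frame(
    marker = c("m1", "m1", "m1", "m2", "m3", "m3"),
    trait = "Scu",
    year = c(2011, 2011, 2012, 2011, 2011, 2014),
    model = c("GLM", "MLM", "GLM", "GLM", "MLM", "MLM"),
    neg_log10_p = c(3.5, 3.2, 2.0, 4.0, 3.1, 3.3))
  sig <- call_significant(res)
  expect_equal(sig$marker, c("m1", "m3"))
  expect_equal(sig$support[sig$marker == "m1"], "G2011, M2011")
  expect_equal(sig$support[sig$marker == "m3"], "M2011, M2014")
  # single detection excluded by the consistency rule, kept when relaxed
  expect_false("m2" %in% sig$marker)
  expect_true("m2" %in% call_significant(res, consistency_min = 1)$marker)

  # brute-force oracle on a random results table
  set.seed(14)
  big <- expand.grid(marker = sprintf("m%02d", 1:15), trait = c("Wt", "Scu"),
                     year = c(2011, 2012), model = c("GLM", "MLM"),
                     stringsAsFactors = FALSE)
  big$neg_log10_p <- runif(nrow(big), 0, 5)
  sig2 <- call_significant(big, threshold = 3, consistency_min = 2)
  brute <- do.call(rbind, lapply(split(big, paste(big$marker, big$trait)), function(d) {
    n <- length(unique(paste(d$model, d$year)[d$neg_log10_p > 3]))
    if (n >= 2) data.frame(marker = d$marker[1], trait = d$trait[1], n = n)
  }))
  expect_setequal(paste(sig2$marker, sig2$trait),
                  paste(brute$marker, brute$trait))
})

test_that("permuted traits keep the scan calibrated at the tail", {
  p <- simulate_panel(95, 200, panel_truth(h2 = 0), seed = 15)
  g <- qc_filter(p$geno)
  y <- trait_means(p$scores, "Scu", 2011)
  set.seed(16)
  exceed <- 0L; total <- 0L
  for (i in 1:100) {
    res <- glm_scan(sample(unname(y)), g, p$Q)
    pv <- res$p[!res$degenerate]
    exceed <- exceed + sum(pv < 1e-3)
    total <- total + length(pv)
  }
  ci <- stats::binom.test(exceed, total, 1e-3)$conf.int
  expect_true(ci[1] <= 1e-3 && 1e-3 <= ci[2])
})
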