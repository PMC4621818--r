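test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  qn <- quantile_normalize(m)
  expect_equal(qn[, 1], c(2.5, 3.5, 4.5))
  expect_equal(qn[, 2], c(2.5, 3.5, 4.5))

  set.seed(17)
  m2 <- matrix(rexp(400), 100, 4)
  qn2 <- quantile_normalize(m2)
  ref <- sort(qn2[, 1])
  for (j in 2:4) expect_equal(sort(qn2[, j]), ref)
  # ranks within each column are preserved
  for (j in 1:4) expect_equal(order(qn2[, j]), order(m2[, j]))
  # identical columns are a fixed point
  m3 <- matrix(rep(c(1, 5, 9), 3), 3, 3)
  expect_equal(quantile_normalize(m3), m3, ignore_attr = TRUE)
  expect_error(quantile_normalize(matrix(-1)), "negative")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(18)
  for (i in 1:10) {
    p <- runif(sample(3:20, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("replicate QC reports within-condition correlations", {
  sim <- simulate_expression(800, seed = 19)
  qn <- quantile_normalize(sim$intensities)
  qc <- replicate_qc(qn, sim$samples)
  expect_equal(nrow(qc), 8 * 3)            # 8 conditions x choose(3, 2) pairs
  expect_true(all(qc$r > 0.9))             # simulator noise keeps replicates tight
  # a duplicated sample correlates exactly
  m <- qn; m[, 2] <- m[, 1]
  qc2 <- replicate_qc(m, sim$samples)
  expect_equal(max(qc2$r), 1)
})

test_that("uncorrelated replicate columns are flagged as near-zero correlation", {
  set.seed(20)
  ok <- replicate(20, {
    m <- matrix(2^rnorm(2000 * 2, 8, 1.5), 2000, 2)
    abs(stats::cor(log2(m[, 1] + 1), log2(m[, 2] + 1))) < 0.1
  })
  expect_gte(mean(ok), 0.95)
})

test_that("the DE test measures planted log2 fold changes", {
  # balanced up/down planting keeps quantile normalization from attenuating
  # the planted shifts
  deg <- data.frame(unigene_id = sprintf("UG%05d", 1:20), genotype = "B47",
                    tissue = "root", log2fc = rep(c(2, -2), 10))
  errs <- vapply(1:10, function(s) {
    sim <- simulate_expression(800, expression_truth(deg), seed = 40 + s,
                               noise_sd = 0.2)
    de <- de_test(quantile_normalize(sim$intensities), sim$samples, "B47", "root")
    stats::median(abs(abs(de$log2_fc[1:20]) - 2))
  }, numeric(1))
  expect_lt(max(errs), 0.3)

  # identical group means give zero fold change
  m <- matrix(4, 10, 24, dimnames = list(sprintf("g%02d", 1:10),
                                         expand_design()$sample))
  de0 <- de_test(m, expand_design(), "B47", "leaf")
  expect_equal(de0$log2_fc, rep(0, 10))
  expect_true(all(de0$flagged))            # zero variance everywhere
  expect_true(all(de0$p == 1))
  expect_error(de_test(m, expand_design(n_rep = 3)[c(1, 4), ], "B47", "leaf"),
               "invalid design")
})

test_that("DEG calling applies inclusive thresholds and matches brute force", {
  res <- data.frame(unigene_id = sprintf("g%02d", 1:10),
                    genotype = rep(c("B47", "B128"), 5), tissue = "leaf",
                    log2_fc = c(1.0, -1.0, 0.99, 2.5, -3, 0.2, 1.8, -0.5, 4, 1.2),
                    p = 0.001,
                    fdr = c(0.01, 0.01, 0.001, 0.011, 0.005, 0.001, 0.2, 0.001,
                            0.0001, 0.01))
  degs <- call_degs(res)
  brute <- res[abs(res$log2_fc) >= 1 & res$fdr <= 0.01, "unigene_id"]
  expect_setequal(degs$unigene_id, brute)
  expect_true(all(c("g01", "g02") %in% degs$unigene_id))   # boundary inclusive
  expect_false("g04" %in% degs$unigene_id)                 # fdr just over
  expect_equal(degs$direction, ifelse(degs$log2_fc > 0, "up", "down"))

  venn <- attr(degs, "venn")
  for (dir in c("up", "down")) {
    v <- venn[venn$direction == dir, ]
    n1 <- length(unique(degs$unigene_id[degs$direction == dir &
                                          degs$genotype == v$genotype1]))
    expect_equal(v$unique1 + v$shared, n1)
  }
  expect_equal(nrow(call_degs(res[0, ])), 0)
})

test_that("family profiles count regulated, tissue- and genotype-specific members", {
  fam <- sprintf("AQP%02d", 1:52)
  mk <- function(id, g, t) data.frame(unigene_id = id, genotype = g, tissue = t,
                                      log2_fc = -2, p = 1e-5, fdr = 1e-4,
                                      direction = "down")
  degs <- rbind(
    do.call(rbind, lapply(fam[1:8], mk, g = "B128", t = "leaf")),    # leaf-specific
    do.call(rbind, lapply(fam[9:14], mk, g = "B47", t = "root")),    # root-specific
    rbind(mk(fam[15], "B47", "leaf"), mk(fam[15], "B47", "root"),
          mk(fam[15], "B128", "leaf"), mk(fam[15], "B128", "root")), # everywhere
    rbind(mk(fam[16], "B47", "leaf"), mk(fam[16], "B128", "root")))  # both tissues
  prof <- family_profile(degs, fam)
  expect_equal(unname(prof$summary["family_size"]), 52)
  expect_equal(unname(prof$summary["regulated"]), 16)
  expect_equal(unname(prof$summary["leaf_specific"]), 8)
  expect_equal(unname(prof$summary["root_specific"]), 6)
  expect_equal(unname(prof$summary["genotype_specific"]), 14)
  # member regulated everywhere is not tissue- or genotype-specific
  expect_false(fam[15] %in% prof$members$unigene_id[FALSE])
  # absent family members are reported as not assayed
  prof2 <- family_profile(degs, c(fam, "AQP99"), assayed_ids = fam)
  expect_equal(prof2$not_assayed, "AQP99")
  # a family with no DEGs yields zero counts
  prof0 <- family_profile(degs[0, ], fam)
  expect_equal(unname(prof0$summary["regulated"]), 0)
})
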