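test_that("climate trace hits the configured extremes and is deterministic", {
  cl <- simulate_climate(1, step_min = 15, noise_sd = 0)
  expect_equal(max(cl$air_temp), 34)
  expect_equal(min(cl$air_temp), 15)
  expect_equal(format(cl$timestamp[which.max(cl$air_temp)], "%H:%M"), "14:00")
  expect_true(all(cl$rel_humidity >= 0 & cl$rel_humidity <= 100))

  a <- simulate_climate(2, step_min = 15, seed = 5, noise_sd = 0.5)
  b <- simulate_climate(2, step_min = 15, seed = 5, noise_sd = 0.5)
  expect_identical(a, b)

  expect_error(simulate_climate(0, 15), "days")
  expect_error(simulate_climate(1, 7), "divide")
})

test_that("noise-free diurnal VPD repeats identically across days", {
  cl <- simulate_climate(7, step_min = 15, noise_sd = 0)
  vpd <- compute_vpd(cl$air_temp, cl$rel_humidity)
  daily_peak <- tapply(vpd, as.Date(cl$timestamp, tz = "UTC"), max)
  expect_equal(max(daily_peak) - min(daily_peak), 0, tolerance = 1e-12)
})

test_that("lysimeter run closes its water ledger and obeys the schedule", {
  run <- make_run(phases = c(5, 8, 2))
  # water in = water transpired + water still stored (to a micro-gram)
  expect_equal(sum(run$events$added_g),
               run$total_transp_g + (run$pot$water_capacity_g - run$final_water_g),
               tolerance = 1e-6)
  # no irrigation events during drought days
  expect_false(any(run$events$day %in% 6:13))
  expect_error(
    simulate_lysimeter_run(run$truth, simulate_climate(5, 15), phases = c(2, 3, 0),
                           irrigation_days = 1:5),
    "invalid schedule")
})

test_that("without drought, each predawn weight steps up by the biomass gain", {
  run <- make_run(phases = c(6, 0, 0))
  w <- run$weigh
  predawn <- tapply(w$weight_g[format(w$timestamp, "%H:%M") == "04:30"],
                    as.Date(w$timestamp[format(w$timestamp, "%H:%M") == "04:30"],
                            tz = "UTC"), mean)
  gains <- diff(as.numeric(predawn))
  expect_equal(gains, run$daily_truth$gain_g[1:5], tolerance = 1e-6)
})

test_that("a plant with zero transpiration leaves a flat trace between irrigations", {
  truth <- lysimeter_truth("null", e_max = 0)
  run <- make_run(truth, phases = c(3, 0, 0))
  spans <- split(run$weigh$weight_g[!run$weigh$irrigation_flag],
                 cumsum(run$weigh$irrigation_flag)[!run$weigh$irrigation_flag])
  expect_true(all(vapply(spans, function(x) max(x) - min(x), numeric(1)) < 1e-9))
})

test_that("downstream analysis recovers the planted breakpoint from a clean run", {
  run <- make_run(phases = c(5, 10, 0))
  fit <- analyze_run(run)$fit
  expect_false(fit$no_breakpoint)
  expect_lt(abs(fit$theta_cr - run$truth$theta_cr), 0.01)
})

test_that("panel simulation matches the study geometry and ground-truth contracts", {
  p <- simulate_panel(95, 1127, seed = 3)
  expect_equal(dim(p$geno), c(95, 1127))
  expect_true(all(p$geno %in% c(0, 2)))
  expect_equal(rowSums(p$Q), rep(1, 95), ignore_attr = TRUE)
  expect_equal(p$K, t(p$K), tolerance = 1e-12)
  expect_gte(min(eigen(p$K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_true(all(p$scores$score %in% 0:5))
  expect_setequal(unique(p$map$lg), 1:11)
  expect_identical(simulate_panel(20, 50, seed = 4), simulate_panel(20, 50, seed = 4))
  expect_error(panel_truth(h2 = 1.2), "h2")
})

test_that("a no-signal panel yields uniform association p-values", {
  p <- simulate_panel(95, 1000, panel_truth(h2 = 0), seed = 11)
  y <- trait_means(p$scores, "Wt", 2011)
  res <- glm_scan(y, p$geno, p$Q)
  pv <- res$p[!res$degenerate & !is.na(res$p)]
  expect_gt(length(pv), 900)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("a strongly heritable causal marker tops the scan in most panels", {
  hits <- 0L
  for (s in 1:25) {
    p <- simulate_panel(200, 200,
                        panel_truth(causal = data.frame(marker_id = 50L,
                                                        trait = "Scu", effect = 1),
                                    h2 = 0.5),
                        seed = 500 + s)
    res <- glm_scan(trait_means(p$scores, "Scu", 2011), p$geno, p$Q)
    if (which.max(ifelse(is.na(res$neg_log10_p), 0, res$neg_log10_p)) == 50L)
      hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.9)
})

test_that("expression simulator emits the factorial design and plants recoverable DEGs", {
  expect_equal(nrow(expand_design()), 24)
  expect_error(expand_design(n_rep = 1), "replicates")
  sim <- simulate_expression(500, seed = 2)
  expect_equal(ncol(sim$intensities), 24)
  expect_true(all(sim$intensities > 0))
  expect_identical(simulate_expression(100, seed = 9)$intensities,
                   simulate_expression(100, seed = 9)$intensities)

  # null experiment: essentially nothing passes FDR 0.01
  qn <- quantile_normalize(sim$intensities)
  de <- de_test(qn, sim$samples, "B47", "leaf")
  expect_lte(nrow(call_degs(de)), 2)

  # planted DEGs at |log2fc| = 2 are recovered at high recall
  recalls <- vapply(1:5, function(s) {
    deg <- data.frame(unigene_id = sprintf("UG%05d", 1:100),
                      genotype = "B47", tissue = "leaf",
                      log2fc = rep(c(2, -2), 50))
    sim <- simulate_expression(1000, expression_truth(deg), seed = 30 + s)
    de <- de_test(quantile_normalize(sim$intensities), sim$samples, "B47", "leaf")
    called <- call_degs(de)
    length(intersect(called$unigene_id, deg$unigene_id)) / nrow(deg)
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})

test_that("map simulator plants exactly the requested co-localized pairs", {
  maps <- simulate_maps(60, 25, planted_genetic = 0, planted_physical = 0, seed = 1)
  expect_equal(nrow(genetic_colocalize(maps$deg_map, maps$snp_map)), 0)
  expect_equal(nrow(physical_colocalize(best_ortholog(maps$deg_hits),
                                        best_ortholog(maps$snp_hits))), 0)
  expect_true(all(maps$snp_map$lg %in% 1:11))
  expect_error(simulate_maps(5, 5, planted_genetic = 6), "plant")
})
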