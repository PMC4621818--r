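#' Default pipeline configuration
#'
#' All thresholds carry the study defaults: association significance at
#' -log10(P) > 3 with consistency over >= 2 (model, year) combinations,
#' DEG calling at fold change >= 2 and FDR <= 0.01, co-localization windows
#' of < 2 cM (genetic) and <= 1.8 Mb (ortholog-physical), correlation
#' masking at P <= 0.05. Synthetic-design sizes are scaled for a desk-size
#' demonstration run and can be raised to the full study design (95 x 1127
#' panel, 29,471-unigene array).
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    lysimetry = list(
      genotypes = list(
        list(id = "B47", e_max = 0.0026, theta_cr = 0.5, slope = 0.010, wue = 0.04),
        list(id = "B128", e_max = 0.0016, theta_cr = 0.28, slope = 0.005, wue = 0.06)),
      n_plants = 3, step_min = 15,
      phases = c(pretreatment = 5, drought = 10, recovery = 0),
      weight_noise_sd = 0.5, rate_noise_cv = 0.05,
      initial_plant_weight_g = 20,
      predawn = c("04:30", "05:00"), evening = c("19:30", "20:00"),
      midday = c("11:00", "14:00"), vpd_floor = 0.1, alpha = 0.05),
    panel = list(n_acc = 95, n_snp = 300, h2 = 0.5, n_causal = 3,
                 effect = 0.8, maf_min = 0.05, missing_max = 0.2,
                 threshold = 3, consistency_min = 2),
    expression = list(n_genes = 1500, n_deg = 80, log2fc = 2,
                      fc_min = 2, fdr_max = 0.01),
    coloc = list(n_deg = 60, n_snp = 25, planted_genetic = 5,
                 planted_physical = 5, max_cm = 2, max_bp = 1.8e6),
    scores = list(alpha = 0.05))
}

write_stage <- function(tables, dir) {
  for (nm in names(tables)) write_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
}

#' Run the full synthetic-demonstration pipeline
#'
#' Generates every input with known ground truth, then executes all stages:
#' lysimetry (daily physiology, WUE), water response (segmented midday
#' transpiration fits and genotype comparison), phenotype score
#' correlations, the GLM/MLM association scan with the consistency rule,
#' expression normalization and DEG calling, and DEG-SNP co-localization.
#' Writes every stage table as TSV plus a YAML run manifest, and returns
#' the results invisibly.
#'
#' @param config Configuration list from [default_config()] (or a path to a
#'   YAML file with the same structure).
#' @param out_dir Output directory (created if missing).
#' @return List of stage results, invisibly.
#' @export
run_all <- function(config = default_config(), out_dir = tempfile("drylysim_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("seed", "lysimetry", "panel", "expression", "coloc", "scores")
  missing_fields <- setdiff(required, names(config))
  if (length(missing_fields))
    stop("config error: missing field(s) ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  cfgl <- config$lysimetry

  # --- lysimetry + water response ------------------------------------------
  climate <- simulate_climate(sum(cfgl$phases), step_min = cfgl$step_min,
                              seed = seed)
  fits <- list(); wue_tab <- list(); daily_all <- list()
  k <- 0
  for (g in cfgl$genotypes) for (pl in seq_len(cfgl$n_plants)) {
    k <- k + 1
    truth <- lysimeter_truth(g$id, e_max = g$e_max, theta_cr = g$theta_cr,
                             slope = g$slope, wue = g$wue,
                             initial_plant_weight_g = cfgl$initial_plant_weight_g,
                             plant_id = sprintf("%s_p%d", g$id, pl))
    run <- simulate_lysimeter_run(truth, climate, phases = cfgl$phases,
                                  weight_noise_sd = cfgl$weight_noise_sd,
                                  rate_noise_cv = cfgl$rate_noise_cv,
                                  seed = seed + 100 + k)
    res <- analyze_run(run, predawn = cfgl$predawn, evening = cfgl$evening,
                       midday = cfgl$midday, vpd_floor = cfgl$vpd_floor)
    daily_all[[k]] <- res$daily
    wue_tab[[k]] <- data.frame(genotype = g$id, plant_id = truth$plant_id,
                               wue = res$wue$wue, r2 = res$wue$r2)
    fits[[k]] <- data.frame(genotype = g$id, plant_id = truth$plant_id,
                            e_max = res$fit$e_max, theta_cr = res$fit$theta_cr,
                            slope = res$fit$slope, rss = res$fit$rss,
                            n_points = res$fit$n_points)
  }
  fits <- do.call(rbind, fits)
  wue_tab <- do.call(rbind, wue_tab)
  comparison <- compare_genotypes(fits)

  # --- panel: scores, correlations, association scan -----------------------
  cfgp <- config$panel
  causal <- data.frame(marker_id = seq_len(cfgp$n_causal) * 7L, trait = "Scu",
                       effect = cfgp$effect)
  panel <- simulate_panel(cfgp$n_acc, cfgp$n_snp,
                          panel_truth(causal = causal, h2 = cfgp$h2),
                          seed = seed + 2)
  cors <- trait_correlations(panel$scores, alpha = config$scores$alpha)
  geno <- qc_filter(panel$geno, cfgp$maf_min, cfgp$missing_max)
  res_assoc <- list()
  for (tr in unique(panel$scores$trait)) for (yr in unique(panel$scores$year)) {
    y <- trait_means(panel$scores, tr, yr)
    for (model in c("GLM", "MLM")) {
      sc <- if (model == "GLM") glm_scan(y, geno, panel$Q)
            else mlm_scan(y, geno, panel$Q, panel$K)
      sc$trait <- tr; sc$year <- yr; sc$model <- model
      res_assoc[[length(res_assoc) + 1L]] <- sc
    }
  }
  res_assoc <- do.call(rbind, res_assoc)
  significant <- call_significant(res_assoc, cfgp$threshold, cfgp$consistency_min)

  # --- expression ----------------------------------------------------------
  cfge <- config$expression
  ids <- sprintf("UG%05d", seq_len(cfge$n_genes))
  deg_truth <- data.frame(
    unigene_id = ids[seq_len(cfge$n_deg)],
    genotype = rep(c("B47", "B128"), length.out = cfge$n_deg),
    tissue = rep(c("leaf", "leaf", "root", "root"), length.out = cfge$n_deg),
    log2fc = rep(c(cfge$log2fc, -cfge$log2fc), each = 2,
                 length.out = cfge$n_deg))
  expr <- simulate_expression(cfge$n_genes, expression_truth(deg_truth),
                              seed = seed + 3)
  qn <- quantile_normalize(expr$intensities)
  qc <- replicate_qc(qn, expr$samples)
  de <- do.call(rbind, lapply(c("B47", "B128"), function(g)
    do.call(rbind, lapply(c("leaf", "root"), function(ti)
      de_test(qn, expr$samples, g, ti)))))
  degs <- call_degs(de, cfge$fc_min, cfge$fdr_max)

  # --- co-localization -----------------------------------------------------
  cfgc <- config$coloc
  maps <- simulate_maps(cfgc$n_deg, cfgc$n_snp, cfgc$planted_genetic,
                        cfgc$planted_physical, seed = seed + 4,
                        max_cm = cfgc$max_cm, max_bp = cfgc$max_bp)
  gen_cand <- genetic_colocalize(maps$deg_map, maps$snp_map, cfgc$max_cm)
  phy_cand <- physical_colocalize(best_ortholog(maps$deg_hits),
                                  best_ortholog(maps$snp_hits), cfgc$max_bp)
  candidates <- combine_candidates(gen_cand, phy_cand)

  # --- outputs -------------------------------------------------------------
  write_stage(list(
    daily_physiology = do.call(rbind, daily_all),
    wue = wue_tab, water_response_fits = fits,
    genotype_comparison = comparison,
    trait_correlations = cors$table,
    association_results = res_assoc[, c("marker", "trait", "year", "model",
                                        "neg_log10_p", "var_explained")],
    significant_snps = significant,
    replicate_qc = qc, deg_records = degs,
    candidate_genes = candidates), out_dir)
  manifest <- list(package = "drylysim",
                   version = as.character(utils::packageVersion("drylysim")),
                   seed = seed, config = config,
                   n_significant_snps = nrow(significant),
                   n_degs = nrow(degs),
                   n_candidates = nrow(candidates))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(daily = do.call(rbind, daily_all), wue = wue_tab,
                 fits = fits, comparison = comparison, correlations = cors,
                 association = res_assoc, significant = significant,
                 replicate_qc = qc, degs = degs, candidates = candidates,
                 maps_truth = maps$truth, panel = panel, out_dir = out_dir))
}

#' Analyze one lysimeter run end-to-end
#'
#' Daily physiology, pretreatment WUE, plant-weight series, ETW
#' normalization, midday extraction over the drought phase, and the
#' segmented water-response fit for a single plant's traces.
#'
#' @param run A `lysimeter_run` (or an equivalent list with `weigh`,
#'   `soil`, `vpd`, `phases`, and `truth$initial_plant_weight_g`).
#' @param predawn,evening,midday Clock windows.
#' @param vpd_floor Minimum VPD for defined ETW.
#' @return List: `daily`, `wue` (fit), `points` (midday), `fit`
#'   (water-response).
#' @export
analyze_run <- function(run, predawn = c("04:30", "05:00"),
                        evening = c("19:30", "20:00"),
                        midday = c("11:00", "14:00"), vpd_floor = 0.1) {
  pre_days <- seq_len(run$phases[1])
  drought_days <- run$phases[1] + seq_len(run$phases[2])
  daily0 <- daily_physiology(run$weigh, predawn, evening)
  wue <- fit_wue(daily0, pre_days)
  daily <- daily_physiology(run$weigh, predawn, evening, wue = wue$wue)
  weight <- estimate_plant_weight(daily, run$truth$initial_plant_weight_g)
  rate <- smooth_and_rate(run$weigh)
  etw <- normalize_etw(rate, weight, run$vpd, vpd_floor)
  points <- suppressWarnings(
    extract_midday_points(etw, run$soil$swc_rel, days = drought_days, midday = midday))
  fit <- fit_segmented(points)
  list(daily = daily, wue = wue, points = points, fit = fit)
}
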