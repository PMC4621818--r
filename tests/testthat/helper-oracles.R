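# Independent brute-force oracles used across the suite.

# Benjamini-Hochberg step-up, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# all-pairs genetic co-localization filter
coloc_brute_genetic <- function(deg_map, snp_map, max_cm = 2) {
  out <- list()
  for (i in seq_len(nrow(deg_map))) for (j in seq_len(nrow(snp_map))) {
    if (deg_map$lg[i] != snp_map$lg[j]) next
    d <- abs(deg_map$pos_cm[i] - snp_map$pos_cm[j])
    if (d == 0 || d < max_cm)
      out[[length(out) + 1L]] <- data.frame(unigene_id = deg_map$entity_id[i],
                                            snp = snp_map$entity_id[j],
                                            distance_cm = d)
  }
  if (!length(out)) return(data.frame(unigene_id = character(0),
                                      snp = character(0),
                                      distance_cm = numeric(0)))
  do.call(rbind, out)
}

# all-pairs physical co-localization filter on best-hit tables
coloc_brute_physical <- function(deg_hits, snp_hits, max_bp = 1.8e6) {
  out <- list()
  for (i in seq_len(nrow(deg_hits))) for (j in seq_len(nrow(snp_hits))) {
    if (deg_hits$sseqid[i] != snp_hits$sseqid[j]) next
    gap <- max(0, max(snp_hits$sstart[j] - deg_hits$send[i],
                      deg_hits$sstart[i] - snp_hits$send[j]))
    if (gap <= max_bp)
      out[[length(out) + 1L]] <- data.frame(unigene_id = deg_hits$qseqid[i],
                                            snp = snp_hits$qseqid[j],
                                            distance_bp = gap)
  }
  if (!length(out)) return(data.frame(unigene_id = character(0),
                                      snp = character(0),
                                      distance_bp = numeric(0)))
  do.call(rbind, out)
}

pair_key <- function(d) sort(paste(d$unigene_id, d$snp))

# standard small simulated drought run used in several files
make_run <- function(truth = lysimeter_truth("G1"),
                     phases = c(5, 10, 0), step_min = 15,
                     weight_noise_sd = 0, rate_noise_cv = 0, seed = NULL) {
  climate <- simulate_climate(sum(phases), step_min = step_min, noise_sd = 0)
  simulate_lysimeter_run(truth, climate, phases = phases,
                         weight_noise_sd = weight_noise_sd,
                         rate_noise_cv = rate_noise_cv, seed = seed)
}
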