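#' Simulate genetic-map and ortholog-hit fixtures for co-localization
#'
#' Places significant SNPs and DEGs on a linkage map (cM, `n_lg` linkage
#' groups) and on a pseudo-chromosome physical assembly (bp) via synthetic
#' BLAST-style best hits, such that exactly `planted_genetic` DEG-SNP pairs
#' fall within the genetic threshold and exactly `planted_physical` pairs
#' within the physical threshold; every other DEG is guaranteed outside both
#' windows (with a safety buffer). Planted pairs use SNPs that are isolated
#' from all other SNPs, so each planted DEG co-localizes with exactly one
#' SNP.
#'
#' @param n_deg Number of DEGs to place.
#' @param n_snp Number of significant SNPs.
#' @param planted_genetic Number of DEG-SNP pairs planted inside the
#'   genetic-map window.
#' @param planted_physical Number of pairs planted inside the physical
#'   window.
#' @param seed Integer seed.
#' @param max_cm,max_bp Co-localization thresholds the planting respects.
#' @param n_lg,lg_len_cm Linkage-map geometry.
#' @param n_chrom,chrom_len_bp Physical-assembly geometry.
#' @return List: `deg_map`, `snp_map` (entity_id, lg, pos_cm), `deg_hits`,
#'   `snp_hits` (12-column BLAST outfmt-6 data frames of best orthologs),
#'   `truth` (the planted genetic and physical pair tables).
#' @export
simulate_maps <- function(n_deg = 100, n_snp = 39, planted_genetic = 7,
                          planted_physical = 7, seed = NULL,
                          max_cm = 2, max_bp = 1.8e6,
                          n_lg = 11, lg_len_cm = 80,
                          n_chrom = 20, chrom_len_bp = 5e7) {
  if (planted_genetic > min(n_deg, n_snp) || planted_physical > min(n_deg, n_snp))
    stop("cannot plant more pairs than min(n_deg, n_snp)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  snp_ids <- sprintf("S%03d", seq_len(n_snp))
  deg_ids <- sprintf("UG%05d", seq_len(n_deg))
  snp_map <- data.frame(entity_id = snp_ids,
                        lg = sample.int(n_lg, n_snp, replace = TRUE),
                        pos_cm = round(stats::runif(n_snp, 0, lg_len_cm), 2))
  buffer <- 1.5 * max_cm

  # nearest same-group neighbour distance for each SNP (Inf if alone)
  nn_cm <- vapply(seq_len(n_snp), function(k) {
    d <- abs(snp_map$pos_cm[snp_map$lg == snp_map$lg[k]] - snp_map$pos_cm[k])
    if (length(d) > 1) sort(d)[2] else Inf
  }, numeric(1))
  isolated <- which(nn_cm > buffer + max_cm &
                      snp_map$pos_cm > max_cm & snp_map$pos_cm < lg_len_cm - max_cm)
  if (length(isolated) < planted_genetic)
    stop("placement failure: too few isolated SNPs for the planted genetic pairs",
         call. = FALSE)
  gen_snps <- sample(isolated, planted_genetic)

  place_far <- function() {
    for (try in 1:2000) {
      lg <- sample.int(n_lg, 1)
      pos <- round(stats::runif(1, 0, lg_len_cm), 2)
      d <- abs(snp_map$pos_cm[snp_map$lg == lg] - pos)
      if (!length(d) || min(d) > buffer) return(c(lg, pos))
    }
    stop("placement failure: map too dense for guaranteed-far DEGs", call. = FALSE)
  }
  deg_map <- data.frame(entity_id = deg_ids, lg = NA_integer_, pos_cm = NA_real_)
  for (i in seq_len(n_deg)) {
    if (i <= planted_genetic) {
      k <- gen_snps[i]
      deg_map$lg[i] <- snp_map$lg[k]
      deg_map$pos_cm[i] <- round(snp_map$pos_cm[k] +
                                   stats::runif(1, -0.9, 0.9) * max_cm, 2)
    } else {
      lp <- place_far()
      deg_map$lg[i] <- lp[1]; deg_map$pos_cm[i] <- lp[2]
    }
  }

  # physical layer: one best ortholog hit per entity on pseudo-chromosomes
  mk_hit <- function(qid, chrom, start, len = round(stats::runif(1, 150, 1200))) {
    data.frame(qseqid = qid, sseqid = sprintf("Chr%02d", chrom),
               pident = round(stats::runif(1, 80, 99), 1), length = len,
               mismatch = 5L, gapopen = 0L, qstart = 1L, qend = len,
               sstart = round(start), send = round(start + len - 1),
               evalue = 10^(-round(stats::runif(1, 20, 80), 1)),
               bitscore = round(stats::runif(1, 100, 900), 1))
  }
  snp_hits <- do.call(rbind, lapply(seq_len(n_snp), function(k)
    mk_hit(snp_ids[k], sample.int(n_chrom, 1),
           stats::runif(1, 2.5 * max_bp, chrom_len_bp - 2.5 * max_bp))))
  pbuffer <- 1.3 * max_bp

  nn_bp <- vapply(seq_len(n_snp), function(k) {
    same <- which(snp_hits$sseqid == snp_hits$sseqid[k])
    same <- setdiff(same, k)
    if (!length(same)) return(Inf)
    min(edge_gap(snp_hits$sstart[k], snp_hits$send[k],
                 snp_hits$sstart[same], snp_hits$send[same]))
  }, numeric(1))
  p_isolated <- which(nn_bp > pbuffer + max_bp)
  if (length(p_isolated) < planted_physical)
    stop("placement failure: too few physically isolated SNP orthologs",
         call. = FALSE)
  phys_snps <- sample(p_isolated, planted_physical)

  far_phys <- function() {
    for (try in 1:2000) {
      chrom <- sample.int(n_chrom, 1)
      start <- stats::runif(1, 1, chrom_len_bp - 2000)
      same <- which(snp_hits$sseqid == sprintf("Chr%02d", chrom))
      g <- edge_gap(start, start + 1500, snp_hits$sstart[same], snp_hits$send[same])
      if (!length(g) || min(g) > pbuffer) return(list(chrom, start))
    }
    stop("placement failure: assembly too dense for guaranteed-far orthologs",
         call. = FALSE)
  }
  deg_hits <- vector("list", n_deg)
  for (i in seq_len(n_deg)) {
    if (i > planted_genetic && i <= planted_genetic + planted_physical) {
      k <- phys_snps[i - planted_genetic]
      start <- snp_hits$send[k] + stats::runif(1, 0.05, 0.9) * max_bp
      deg_hits[[i]] <- mk_hit(deg_ids[i],
                              as.integer(sub("Chr", "", snp_hits$sseqid[k])), start)
    } else {
      fp <- far_phys()
      deg_hits[[i]] <- mk_hit(deg_ids[i], fp[[1]], fp[[2]])
    }
  }
  deg_hits <- do.call(rbind, deg_hits)

  truth <- list(
    genetic_pairs = data.frame(unigene_id = deg_ids[seq_len(planted_genetic)],
                               snp = snp_ids[gen_snps]),
    physical_pairs = data.frame(
      unigene_id = deg_ids[planted_genetic + seq_len(planted_physical)],
      snp = snp_ids[phys_snps]))
  list(deg_map = deg_map, snp_map = snp_map,
       deg_hits = deg_hits, snp_hits = snp_hits, truth = truth)
}

# gap between [s1,e1] and vectors of intervals [s2,e2]; 0 when overlapping
edge_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}
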