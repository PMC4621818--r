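#' Read a tabular BLAST hit file (outfmt 6)
#'
#' Standard 12-column tab-separated dialect: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path File path.
#' @return Data frame with the 12 standard columns.
#' @export
read_blast6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = cols, stringsAsFactors = FALSE,
                           comment.char = "#")
  out
}

#' Best ortholog hit per query
#'
#' Filters hits to aligned length >= `min_len` and e-value <= `max_evalue`,
#' then keeps one hit per query: lowest e-value, ties broken by highest
#' bitscore, then longest alignment.
#'
#' @param hits BLAST outfmt-6 data frame (see [read_blast6()]).
#' @param min_len Minimum aligned length (bp).
#' @param max_evalue Maximum e-value.
#' @return Data frame with at most one row per `qseqid`; queries with no
#'   surviving hit are absent.
#' @export
best_ortholog <- function(hits, min_len = 80, max_evalue = 1e-10) {
  ok <- hits$length >= min_len & hits$evalue <= max_evalue
  h <- hits[ok, , drop = FALSE]
  if (!nrow(h)) return(h)
  h <- h[order(h$qseqid, h$evalue, -h$bitscore, -h$length), , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Co-localize DEGs with significant SNPs on the genetic map
#'
#' A (DEG, SNP) pair is a candidate when both lie on the same linkage group
#' and the DEG is coincident with the SNP (distance 0) or strictly closer
#' than `max_cm` (the LD-decay window). All qualifying pairs are retained in
#' long form; the nearest SNP per DEG is flagged.
#'
#' @param deg_map,snp_map Map tables `entity_id`, `lg`, `pos_cm`. Entries
#'   without a map position are skipped.
#' @param max_cm Genetic window, cM (strict inequality for non-coincident
#'   pairs).
#' @return Data frame `unigene_id`, `snp`, `evidence` ("genetic_map"),
#'   `lg`, `distance_cm`, `nearest`.
#' @export
genetic_colocalize <- function(deg_map, snp_map, max_cm = 2) {
  dm <- deg_map[!is.na(deg_map$lg) & !is.na(deg_map$pos_cm), ]
  sm <- snp_map[!is.na(snp_map$lg) & !is.na(snp_map$pos_cm), ]
  if (nrow(dm) < nrow(deg_map) || nrow(sm) < nrow(snp_map))
    message("entities without map positions skipped: ",
            nrow(deg_map) - nrow(dm) + nrow(snp_map) - nrow(sm))
  pairs <- merge(
    stats::setNames(dm[, c("entity_id", "lg", "pos_cm")],
                    c("unigene_id", "lg", "deg_cm")),
    stats::setNames(sm[, c("entity_id", "lg", "pos_cm")],
                    c("snp", "lg", "snp_cm")), by = "lg")
  pairs$distance_cm <- abs(pairs$deg_cm - pairs$snp_cm)
  hit <- pairs[pairs$distance_cm == 0 | pairs$distance_cm < max_cm, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(unigene_id = character(0), snp = character(0),
                      evidence = character(0), lg = integer(0),
                      distance_cm = numeric(0), nearest = logical(0)))
  hit <- hit[order(hit$unigene_id, hit$distance_cm), ]
  hit$nearest <- !duplicated(hit$unigene_id)
  data.frame(unigene_id = hit$unigene_id, snp = hit$snp,
             evidence = "genetic_map", lg = hit$lg,
             distance_cm = hit$distance_cm, nearest = hit$nearest,
             row.names = NULL)
}

#' Co-localize DEGs with significant SNPs through ortholog physical positions
#'
#' Both sides are represented by their best ortholog intervals on a common
#' assembly. A pair is a candidate when both intervals lie on the same
#' chromosome and the edge gap (distance between closest interval ends, 0
#' for overlap) is at most `max_bp` (inclusive). The midpoint distance is
#' reported alongside.
#'
#' @param deg_orthologs,snp_orthologs Best-hit tables from
#'   [best_ortholog()]; `qseqid` identifies the DEG / SNP.
#' @param max_bp Physical window, bp (inclusive).
#' @return Data frame `unigene_id`, `snp`, `evidence`
#'   ("ortholog_physical"), `chrom`, `distance_bp` (edge gap),
#'   `midpoint_bp`, `nearest`.
#' @export
physical_colocalize <- function(deg_orthologs, snp_orthologs, max_bp = 1.8e6) {
  norm <- function(h, id, pre) {
    out <- data.frame(id = h$qseqid, chrom = h$sseqid,
                      s = pmin(h$sstart, h$send), e = pmax(h$sstart, h$send))
    stats::setNames(out, c(id, "chrom", paste0(pre, c("_s", "_e"))))
  }
  pairs <- merge(norm(deg_orthologs, "unigene_id", "deg"),
                 norm(snp_orthologs, "snp", "snp"), by = "chrom")
  if (!nrow(pairs))
    return(data.frame(unigene_id = character(0), snp = character(0),
                      evidence = character(0), chrom = character(0),
                      distance_bp = numeric(0), midpoint_bp = numeric(0),
                      nearest = logical(0)))
  pairs$distance_bp <- edge_gap(pairs$deg_s, pairs$deg_e, pairs$snp_s, pairs$snp_e)
  pairs$midpoint_bp <- abs((pairs$deg_s + pairs$deg_e) / 2 -
                             (pairs$snp_s + pairs$snp_e) / 2)
  hit <- pairs[pairs$distance_bp <= max_bp, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(unigene_id = character(0), snp = character(0),
                      evidence = character(0), chrom = character(0),
                      distance_bp = numeric(0), midpoint_bp = numeric(0),
                      nearest = logical(0)))
  hit <- hit[order(hit$unigene_id, hit$distance_bp), ]
  hit$nearest <- !duplicated(hit$unigene_id)
  data.frame(unigene_id = hit$unigene_id, snp = hit$snp,
             evidence = "ortholog_physical", chrom = hit$chrom,
             distance_bp = hit$distance_bp, midpoint_bp = hit$midpoint_bp,
             nearest = hit$nearest, row.names = NULL)
}

#' Combine genetic and physical candidate lists
#'
#' Deduplicates by (unigene, SNP); a pair supported by both evidence types
#' is kept once with evidence "both".
#'
#' @param genetic,physical Outputs of [genetic_colocalize()] and
#'   [physical_colocalize()].
#' @return Data frame `unigene_id`, `snp`, `evidence`.
#' @export
combine_candidates <- function(genetic, physical) {
  g <- unique(genetic[, c("unigene_id", "snp")])
  p <- unique(physical[, c("unigene_id", "snp")])
  g$evidence <- "genetic_map"; p$evidence <- "ortholog_physical"
  all <- rbind(g, p)
  key <- paste(all$unigene_id, all$snp, sep = "\r")
  dup <- key[duplicated(key)]
  all$evidence[key %in% dup] <- "both"
  out <- all[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
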