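#' Unifoliate-senescence score (Scu) from senesced leaf-area fraction
#'
#' The 0-5 ordinal scale: 0 for no senescence; 1 for a fraction up to 20%;
#' 2, 3 and 4 for the (20, 40], (40, 60] and (60, 80] percent bands; 5 for
#' more than 80% senesced or a dead/fallen plant. The open (80, 100] band is
#' assigned 5, completing the scale.
#'
#' @param senesced_fraction Senesced fraction of leaf area, in [0, 1].
#'   Vectorized.
#' @param dead_or_fallen Logical; complete senescence regardless of
#'   fraction.
#' @return Integer score 0-5.
#' @examples
#' scu_score(0.50)           # 3
#' scu_score(0.20)           # 1 (bands are closed on the right)
#' scu_score(0, dead_or_fallen = TRUE)  # 5
#' @export
scu_score <- function(senesced_fraction, dead_or_fallen = FALSE) {
  if (any(senesced_fraction < 0 | senesced_fraction > 1, na.rm = TRUE))
    stop("'senesced_fraction' must lie in [0, 1]", call. = FALSE)
  s <- pmin(5L, as.integer(ceiling(senesced_fraction * 5)))
  s[rep_len(dead_or_fallen, length(s))] <- 5L
  s
}

#' Leaf relative water content (RWC)
#'
#' \eqn{RWC = (FW - DW) / (TW - DW) \times 100} percent, from fresh, dry and
#' turgid weights of a leaf sample.
#'
#' @param fw,dw,tw Fresh, dry and turgid weights (g). Vectorized.
#' @return RWC in percent.
#' @export
rwc <- function(fw, dw, tw) {
  if (any(tw <= dw, na.rm = TRUE))
    stop("RWC undefined: turgid weight must exceed dry weight", call. = FALSE)
  (fw - dw) / (tw - dw) * 100
}

#' Cross-year correlations of visual drought scores
#'
#' Averages replicate scores per accession within each (trait, year), then
#' computes all pairwise correlations between the resulting trait-year
#' vectors across accessions. Cells whose p-value exceeds `alpha` are masked
#' (`r_masked = NA`), mirroring the dashes of a significance-filtered
#' correlation table.
#'
#' @param scores Score table: `accession`, `trait`, `year`, `replicate`,
#'   `score`.
#' @param alpha Significance threshold for masking.
#' @param method `"pearson"` (default) or `"spearman"` (scores are ordinal).
#' @param min_shared Minimum accessions shared by a pair; pairs below are
#'   skipped with a warning.
#' @return List: `table` (long-form `var1`, `var2`, `r`, `p`, `n`,
#'   `r_masked`) and `matrix` (square `r_masked` matrix, diagonal 1).
#' @export
trait_correlations <- function(scores, alpha = 0.05,
                               method = c("pearson", "spearman"),
                               min_shared = 10) {
  method <- match.arg(method)
  agg <- stats::aggregate(score ~ accession + trait + year, scores, mean)
  agg$var <- paste0(agg$trait, agg$year)
  vars <- unique(agg$var[order(agg$year, agg$trait)])
  wide <- stats::reshape(agg[, c("accession", "var", "score")],
                         idvar = "accession", timevar = "var",
                         direction = "wide")
  colnames(wide) <- sub("^score\\.", "", colnames(wide))

  rows <- list(); skipped <- 0L
  for (i in seq_along(vars)) for (j in i:length(vars)) {
    x <- wide[[vars[i]]]; y <- wide[[vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_shared) { skipped <- skipped + 1L; next }
    if (i == j) {
      r <- 1; p <- 0
    } else {
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
      r <- unname(ct$estimate); p <- ct$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = vars[i], var2 = vars[j], r = r, p = p, n = sum(ok),
      r_masked = if (!is.na(p) && p <= alpha) r else NA_real_)
  }
  if (skipped) warning(skipped, " pair(s) skipped: fewer than ", min_shared,
                       " shared accessions")
  tab <- do.call(rbind, rows)
  m <- matrix(NA_real_, length(vars), length(vars), dimnames = list(vars, vars))
  for (k in seq_len(nrow(tab)))
    m[tab$var1[k], tab$var2[k]] <- m[tab$var2[k], tab$var1[k]] <- tab$r_masked[k]
  list(table = tab, matrix = m)
}
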