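#' Published marker-trait associations for the asparagus bean mini-core
#'
#' Reads the bundled table of SNP loci reported as significantly associated
#' with the three visual drought traits (Wt, Scu, Stg) in the 95-accession
#' Chinese asparagus bean mini-core, with the supporting
#' (experiment, model) combinations and consensus-map positions. A locus
#' associated with two traits appears on two rows.
#'
#' @param path Path to the TSV; defaults to the bundled copy.
#' @return Data frame `snp`, `trait`, `support`, `lg`, `pos_cm`, plus
#'   `support_combos`, a list column of expanded "G2011"/"M2012"-style
#'   tokens (a bare year inherits the preceding model letter, so
#'   "G2011, M2011, 2012" expands to G2011, M2011, M2012).
#' @export
read_marker_trait_table <- function(path = system.file(
  "extdata", "marker_trait_associations.tsv", package = "drylysim")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$support_combos <- lapply(tab$support, parse_support)
  tab
}

# expand "G2011, 2012, M 2012, 2014" -> c("G2011","G2012","M2012","M2014")
parse_support <- function(s) {
  tokens <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  model <- NA_character_
  out <- character(0)
  for (tk in tokens) {
    if (grepl("^[GM]", tk)) {
      model <- substr(tk, 1, 1)
      yr <- sub("^[GM]\\s*", "", tk)
      if (nzchar(yr)) out <- c(out, paste0(model, yr))
    } else if (grepl("^[0-9]{4}$", tk)) {
      if (is.na(model)) stop("bare year with no preceding model: ", s, call. = FALSE)
      out <- c(out, paste0(model, tk))
    } else stop("unparseable support token: '", tk, "'", call. = FALSE)
  }
  out
}

#' Bookkeeping summary of a marker-trait association table
#'
#' @param tab Table from [read_marker_trait_table()].
#' @return List: `n_rows`, `n_loci` (distinct SNPs), `trait_counts`
#'   (named vector of loci per trait), `multi_trait` (SNPs associated with
#'   more than one trait).
#' @export
marker_trait_summary <- function(tab) {
  cnt <- table(tab$snp)
  list(n_rows = nrow(tab),
       n_loci = length(unique(tab$snp)),
       trait_counts = vapply(split(tab$snp, tab$trait),
                             function(x) length(unique(x)), integer(1)),
       multi_trait = names(cnt)[cnt > 1])
}
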