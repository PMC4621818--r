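# Plain-text interchange: CSV for traces, TSV for matrices/tables, YAML for
# ground-truth sidecars. Everything written here round-trips through the
# matching reader.

#' @rdname trace_io
#' @export
write_weigh_trace <- function(trace, path) {
  out <- data.frame(plant_id = trace$plant_id,
                    timestamp = format(trace$timestamp, "%Y-%m-%d %H:%M:%S",
                                       tz = "UTC"),
                    weight_g = trace$weight_g,
                    irrigation_flag = as.integer(trace$irrigation_flag),
                    drainage_done = as.integer(trace$drainage_done))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write lysimeter trace CSV files
#'
#' Weigh traces carry `plant_id, timestamp, weight_g, irrigation_flag,
#' drainage_done`; soil traces `timestamp, permittivity, vwc, swc_rel, ec,
#' soil_temp`. Timestamps are UTC.
#'
#' @param trace Data frame to write.
#' @param path File path.
#' @name trace_io
#' @export
read_weigh_trace <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC")
  out$irrigation_flag <- as.logical(out$irrigation_flag)
  out$drainage_done <- as.logical(out$drainage_done)
  out
}

#' @rdname trace_io
#' @export
write_soil_trace <- function(trace, path) {
  out <- trace
  out$timestamp <- format(trace$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_soil_trace <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC")
  out
}

#' Read and write a genotype matrix as TSV
#'
#' Accessions as rows, markers as columns, header row with marker ids,
#' first column `accession`; missing calls written as `NA`.
#'
#' @param geno Accessions x markers matrix.
#' @param path File path.
#' @export
write_genotypes <- function(geno, path) {
  out <- data.frame(accession = rownames(geno), geno, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(out[, -1, drop = FALSE])
  rownames(m) <- out$accession
  storage.mode(m) <- "numeric"
  m
}

#' Write/read a generic TSV table
#' @param x Data frame.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write/read a ground-truth sidecar as YAML
#' @param truth A list (e.g. a [lysimeter_truth()]).
#' @param path File path.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  yaml::read_yaml(path)
}
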