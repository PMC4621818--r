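`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
hm_to_min <- function(x) {
  p <- strsplit(x, ":", fixed = TRUE)
  vapply(p, function(v) as.numeric(v[1]) * 60 + as.numeric(v[2]), numeric(1))
}

# minutes past midnight for a POSIXct vector (UTC-based grids)
clock_min <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

trace_day <- function(ts) as.integer(as.Date(ts, tz = "UTC") - as.Date(ts[1], tz = "UTC")) + 1L

in_clock_window <- function(ts, window) {
  m <- clock_min(ts)
  w <- hm_to_min(window)
  m >= w[1] & m < w[2]
}

grid_step_min <- function(ts) {
  d <- diff(as.numeric(ts)) / 60
  if (length(d) == 0L) stop("trace has fewer than two samples", call. = FALSE)
  if (max(abs(d - d[1])) > 1e-6) stop("timestamp grid is not regular", call. = FALSE)
  d[1]
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
}
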