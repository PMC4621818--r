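#' Simulate a diurnal greenhouse climate trace
#'
#' Sinusoidal diurnal air temperature between `t_min` and `t_max` peaking at
#' `peak_hour`, with relative humidity in anti-phase (driest at the
#' temperature peak), plus optional Gaussian noise. Defaults reflect a warm
#' Mediterranean greenhouse summer (daily max:min of 34:15 deg C).
#'
#' @param days Number of days (>= 1).
#' @param step_min Grid step in minutes; must divide 1440.
#' @param seed Optional integer seed (set before drawing noise).
#' @param t_max,t_min Daily maximum / minimum air temperature, deg C.
#' @param rh_max,rh_min Daily maximum / minimum relative humidity, percent.
#' @param peak_hour Clock hour of the temperature maximum.
#' @param noise_sd Gaussian noise s.d. added to temperature (deg C) and
#'   humidity (percentage points); humidity is clipped to [0, 100].
#' @param origin Timestamp of the first sample (UTC).
#' @return Data frame `timestamp` (POSIXct), `air_temp`, `rel_humidity`.
#' @export
simulate_climate <- function(days, step_min = 3, seed = NULL,
                             t_max = 34, t_min = 15,
                             rh_max = 85, rh_min = 35,
                             peak_hour = 14, noise_sd = 0,
                             origin = as.POSIXct("2010-08-01 00:00:00", tz = "UTC")) {
  if (days < 1 || step_min <= 0 || 1440 %% step_min != 0)
    stop("'days' must be >= 1 and 'step_min' must divide 1440", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- days * 1440L / step_min
  ts <- origin + seq(0, length.out = n, by = step_min * 60)
  h <- clock_min(ts) / 60
  phase <- cos(2 * pi * (h - peak_hour) / 24)
  temp <- (t_max + t_min) / 2 + (t_max - t_min) / 2 * phase
  rh <- (rh_max + rh_min) / 2 - (rh_max - rh_min) / 2 * phase
  if (noise_sd > 0) {
    temp <- temp + stats::rnorm(n, 0, noise_sd)
    rh <- rh + stats::rnorm(n, 0, noise_sd)
  }
  data.frame(timestamp = ts, air_temp = temp,
             rel_humidity = pmin(pmax(rh, 0), 100))
}
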