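#' Vapor pressure deficit from air temperature and relative humidity
#'
#' Computes VPD as \eqn{e_{sat}(T) (1 - RH/100)} with saturation vapor
#' pressure from the Tetens formula
#' \eqn{e_{sat}(T) = 0.6108 \exp(17.27 T / (T + 237.3))} (kPa, T in deg C).
#'
#' @param air_temp Air temperature, deg C. Vectorized.
#' @param rel_humidity Relative humidity, percent (0-100). Recycled against
#'   `air_temp`.
#' @return VPD in kPa, nonnegative.
#' @examples
#' compute_vpd(25, 50)   # ~1.58 kPa
#' compute_vpd(20, 100)  # 0
#' @export
compute_vpd <- function(air_temp, rel_humidity) {
  if (any(rel_humidity < 0 | rel_humidity > 100, na.rm = TRUE))
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  e_sat <- 0.6108 * exp(17.27 * air_temp / (air_temp + 237.3))
  e_sat * (1 - rel_humidity / 100)
}

#' Volumetric water content from probe permittivity (Topp calibration)
#'
#' Third-order polynomial calibration
#' \eqn{vwc = c_0 + c_1\epsilon + c_2\epsilon^2 + c_3\epsilon^3}.
#' Defaults are the standard Topp (1980) coefficients; site-specific
#' calibrations are passed through `coeffs`.
#'
#' @param permittivity Apparent dielectric permittivity (unitless).
#' @param coeffs Numeric length-4 vector \eqn{(c_0, c_1, c_2, c_3)}.
#' @return Volumetric water content (m3/m3), clipped to [0, 1]. The logical
#'   attribute `"clipped"` flags elements that were clipped.
#' @export
topp_vwc <- function(permittivity,
                     coeffs = c(-5.3e-2, 2.92e-2, -5.5e-4, 4.3e-6)) {
  if (!is.numeric(coeffs) || length(coeffs) != 4L || anyNA(coeffs))
    stop("'coeffs' must be 4 finite polynomial coefficients", call. = FALSE)
  v <- coeffs[1] + coeffs[2] * permittivity + coeffs[3] * permittivity^2 +
    coeffs[4] * permittivity^3
  clipped <- v < 0 | v > 1
  v <- pmin(pmax(v, 0), 1)
  attr(v, "clipped") <- clipped
  v
}

# inverse of the Topp cubic by monotone interpolation over the calibrated range
topp_permittivity <- function(vwc, coeffs = c(-5.3e-2, 2.92e-2, -5.5e-4, 4.3e-6)) {
  eps <- seq(1, 60, by = 0.05)
  v <- coeffs[1] + coeffs[2] * eps + coeffs[3] * eps^2 + coeffs[4] * eps^3
  stats::approx(v, eps, xout = vwc, rule = 2)$y
}

#' Smoothed transpiration rate from a container-weight trace
#'
#' Smooths the weight series within each irrigation-free span and returns the
#' negative first derivative, so that a positive rate means water loss.
#' Samples inside irrigation/drainage intervals are masked (`NA`) before
#' differentiation and stay masked in the output, as are the smoothing edges
#' of each span.
#'
#' @param trace Weigh trace: data frame with `timestamp` (POSIXct, regular
#'   grid), `weight_g`, and logical `irrigation_flag` marking steps from the
#'   start of an irrigation event until drainage has finished.
#' @param window_min Smoothing window, minutes (centered moving average;
#'   default 30). Must cover at least 3 grid steps.
#' @param method `"ma"` (centered moving average, default) or `"sgolay"`
#'   (Savitzky-Golay, order 2, via the signal package).
#' @return Data frame `timestamp`, `rate_g_min` (g/min, `NA` where masked).
#' @export
smooth_and_rate <- function(trace, window_min = 30, method = c("ma", "sgolay")) {
  method <- match.arg(method)
  step <- grid_step_min(trace$timestamp)
  k <- max(3L, round(window_min / step))
  if (k %% 2L == 0L) k <- k + 1L
  n <- nrow(trace)
  if (k > n) stop("smoothing window exceeds the trace span", call. = FALSE)
  masked <- if (!is.null(trace$irrigation_flag)) trace$irrigation_flag else rep(FALSE, n)

  rate <- rep(NA_real_, n)
  span_id <- cumsum(masked)          # constant within an irrigation-free run
  for (sp in split(which(!masked), span_id[!masked])) {
    if (length(sp) < max(k, 3L)) next
    w <- trace$weight_g[sp]
    ws <- if (method == "ma") {
      as.numeric(stats::filter(w, rep(1 / k, k), sides = 2))
    } else {
      if (!requireNamespace("signal", quietly = TRUE))
        stop("the 'signal' package is required for method = \"sgolay\"", call. = FALSE)
      signal::sgolayfilt(w, p = 2, n = k)
    }
    r <- rep(NA_real_, length(sp))
    i <- 2:(length(sp) - 1L)
    r[i] <- -(ws[i + 1L] - ws[i - 1L]) / (2 * step)
    rate[sp] <- r
  }
  data.frame(timestamp = trace$timestamp, rate_g_min = rate)
}

window_mean <- function(trace, day, window, step, min_frac = 0.9) {
  sel <- trace_day(trace$timestamp) == day & in_clock_window(trace$timestamp, window)
  expected <- diff(hm_to_min(window)) / step
  irr <- if (!is.null(trace$irrigation_flag)) any(trace$irrigation_flag[sel]) else FALSE
  ok <- sum(sel) >= min_frac * expected && !irr
  list(mean = if (any(sel)) mean(trace$weight_g[sel]) else NA_real_, valid = ok, n = sum(sel))
}

#' Plant daily transpiration (PDT)
#'
#' PDT for day k is the mean container weight over a predawn window minus the
#' mean over an evening window of the same day, each a 30-min average by
#' default. Days with irrigation inside a window, or with more than 10% of
#' the expected samples missing, are flagged invalid rather than dropped.
#'
#' @param trace Weigh trace (see [smooth_and_rate()]).
#' @param predawn,evening Clock windows, `c("HH:MM", "HH:MM")`.
#' @param min_frac Minimum fraction of expected samples per window.
#' @return Data frame `day`, `pdt_g`, `valid`.
#' @export
daily_transpiration <- function(trace, predawn = c("04:30", "05:00"),
                                evening = c("19:30", "20:00"), min_frac = 0.9) {
  step <- grid_step_min(trace$timestamp)
  days <- sort(unique(trace_day(trace$timestamp)))
  out <- lapply(days, function(d) {
    m <- window_mean(trace, d, predawn, step, min_frac)
    e <- window_mean(trace, d, evening, step, min_frac)
    data.frame(day = d, pdt_g = m$mean - e$mean, valid = m$valid && e$valid)
  })
  do.call(rbind, out)
}

#' Daily plant weight gain (delta-PW)
#'
#' Day-over-day difference of post-drainage morning container weights:
#' \eqn{\Delta PW_k = W_{k+1} - W_k}, each W a 30-min predawn mean taken only
#' when the drainage following the preceding irrigation event has finished.
#' Because drainage resets the pot water store to a fixed level, the
#' difference is attributed to plant biomass gain. Days without a
#' drainage-complete morning (e.g. during drought) are skipped with a
#' warning.
#'
#' @inheritParams daily_transpiration
#' @param morning Clock window for the morning weight.
#' @return Data frame `day`, `dpw_g` where `dpw_g` of day k is
#'   W(k+1) - W(k); rows only for days where both mornings qualify.
#' @export
daily_weight_gain <- function(trace, morning = c("04:30", "05:00"), min_frac = 0.9) {
  step <- grid_step_min(trace$timestamp)
  if (is.null(trace$drainage_done))
    stop("trace lacks a 'drainage_done' marker column", call. = FALSE)
  dayv <- trace_day(trace$timestamp)
  days <- sort(unique(dayv))
  cmv <- clock_min(trace$timestamp)
  w_m <- vapply(days, function(d) {
    wm <- window_mean(trace, d, morning, step, min_frac)
    # the morning counts only if an irrigation drained within the last 24 h
    recent <- (dayv == d - 1L & cmv >= hm_to_min(morning[1])) |
      (dayv == d & cmv < hm_to_min(morning[1]))
    drained <- any(trace$drainage_done[recent])
    if (wm$valid && drained) wm$mean else NA_real_
  }, numeric(1))
  ok <- !is.na(w_m[-length(w_m)]) & !is.na(w_m[-1])
  if (!all(ok)) warning(sum(!ok), " day(s) skipped: missing post-drainage morning weight")
  data.frame(day = days[-length(days)], dpw_g = diff(w_m))[ok, , drop = FALSE]
}

#' Per-day physiology table for one plant
#'
#' Combines [daily_transpiration()] and [daily_weight_gain()] into the
#' per-plant daily table with cumulative series. Cumulative gain treats
#' days without a measurable weight gain (no drainage reset) as gaining
#' `wue * pdt_g` when a water-use efficiency is supplied, otherwise 0.
#'
#' @inheritParams daily_transpiration
#' @param wue Optional water-use efficiency (g biomass per g water) used to
#'   extrapolate biomass gain on days without post-drainage mornings.
#' @return Data frame `plant_id`, `day`, `pdt_g`, `dpw_g`, `cum_transp_g`,
#'   `cum_gain_g`, `valid`.
#' @export
daily_physiology <- function(trace, predawn = c("04:30", "05:00"),
                             evening = c("19:30", "20:00"), wue = NULL,
                             min_frac = 0.9) {
  pdt <- daily_transpiration(trace, predawn, evening, min_frac)
  dpw <- suppressWarnings(daily_weight_gain(trace, predawn, min_frac))
  out <- merge(pdt, dpw, by = "day", all.x = TRUE)
  gain <- out$dpw_g
  miss <- is.na(gain)
  gain[miss] <- if (!is.null(wue)) wue * out$pdt_g[miss] else 0
  gain[is.na(gain)] <- 0
  out$cum_transp_g <- cumsum(ifelse(out$valid & !is.na(out$pdt_g), out$pdt_g, 0))
  out$cum_gain_g <- cumsum(gain)
  out$plant_id <- trace$plant_id[1] %||% NA_character_
  out[, c("plant_id", "day", "pdt_g", "dpw_g", "cum_transp_g", "cum_gain_g", "valid")]
}

#' Whole-plant water-use efficiency (WUE)
#'
#' Ordinary least-squares slope of cumulative biomass gain on cumulative
#' transpiration over the pretreatment phase; the slope is the biomass WUE
#' (g gained per g transpired). The cumulative series are rebuilt from the
#' days of the phase that carry both a valid transpiration total and a
#' measured (post-drainage) weight gain, so a morning without a drainage
#' reset cannot silently contribute a zero gain.
#'
#' @param daily Daily table from [daily_physiology()].
#' @param phase_days Integer vector of day indices to fit over (>= 3 days).
#' @return List of class `"wue_fit"`: `wue`, `intercept`, `r2`, `n_days`.
#' @export
fit_wue <- function(daily, phase_days = NULL) {
  d <- if (is.null(phase_days)) daily else daily[daily$day %in% phase_days, ]
  d <- d[d$valid & !is.na(d$pdt_g) & !is.na(d$dpw_g), ]
  if (nrow(d) < 3L)
    stop("WUE fit needs at least 3 valid days in the phase", call. = FALSE)
  x <- cumsum(d$pdt_g)
  y <- cumsum(d$dpw_g)
  if (stats::sd(x) == 0)
    stop("undefined fit: cumulative transpiration has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(wue = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n_days = nrow(d)),
            class = "wue_fit")
}

#' @export
print.wue_fit <- function(x, ...) {
  cat(sprintf("WUE fit: slope %.4f g/g (intercept %.2f g, R2 %.3f, %d days)\n",
              x$wue, x$intercept, x$r2, x$n_days))
  invisible(x)
}

#' Daily plant-weight series for normalization
#'
#' Plant weight on the morning of each day, as initial weight plus cumulative
#' gain up to the previous day. During phases without drainage resets the
#' gain comes from the WUE extrapolation in [daily_physiology()].
#'
#' @param daily Daily table from [daily_physiology()].
#' @param initial_weight_g Plant weight on the first morning (g, from config).
#' @return Data frame `day`, `plant_weight_g`.
#' @export
estimate_plant_weight <- function(daily, initial_weight_g) {
  stopifnot_scalar(initial_weight_g, "initial_weight_g")
  if (initial_weight_g <= 0)
    stop("initial plant weight must be positive", call. = FALSE)
  w <- initial_weight_g + c(0, utils::head(daily$cum_gain_g, -1))
  data.frame(day = daily$day, plant_weight_g = w)
}

#' Transpiration rate normalized to plant weight and VPD (ETW)
#'
#' \eqn{ETW(t) = rate(t) / W_{plant}(day(t)) / VPD(t)}, in
#' g g-1 kPa-1 min-1. Values are masked where VPD is below `vpd_floor`
#' (night), where the rate is masked, or where no plant weight is available.
#'
#' @param rate Data frame `timestamp`, `rate_g_min` from [smooth_and_rate()].
#' @param plant_weight Data frame `day`, `plant_weight_g` from
#'   [estimate_plant_weight()].
#' @param vpd Numeric VPD series (kPa) aligned with `rate$timestamp`.
#' @param vpd_floor Minimum VPD for a defined ETW (kPa, default 0.1).
#' @return Data frame `timestamp`, `etw`.
#' @export
normalize_etw <- function(rate, plant_weight, vpd, vpd_floor = 0.1) {
  if (any(plant_weight$plant_weight_g <= 0, na.rm = TRUE))
    stop("nonpositive plant weight", call. = FALSE)
  if (length(vpd) != nrow(rate))
    stop("'vpd' must align with the rate series", call. = FALSE)
  w <- plant_weight$plant_weight_g[match(trace_day(rate$timestamp), plant_weight$day)]
  etw <- rate$rate_g_min / w / vpd
  etw[vpd < vpd_floor] <- NA_real_
  data.frame(timestamp = rate$timestamp, etw = etw)
}
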