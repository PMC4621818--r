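#' Ground-truth physiology for one simulated plant
#'
#' Bundles the parameters that drive [simulate_lysimeter_run()]: the plateau
#' transpiration `e_max` (g water per g plant per kPa per min), the critical
#' relative soil water content `theta_cr` below which transpiration declines
#' linearly with slope `slope`, the biomass water-use efficiency `wue`
#' (g biomass per g water), and the initial plant weight.
#'
#' @param genotype_id,plant_id Identifiers.
#' @param e_max Plateau of weight- and VPD-normalized transpiration (>= 0).
#' @param theta_cr Critical relative soil water content, strictly in (0, 1).
#' @param slope Decline slope below `theta_cr` (etw units per unit SWC, > 0).
#' @param wue Biomass water-use efficiency (> 0).
#' @param initial_plant_weight_g Plant weight at the start of the run (g).
#' @return List of class `"lysimeter_truth"`.
#' @export
lysimeter_truth <- function(genotype_id, e_max = 0.002, theta_cr = 0.4,
                            slope = 0.007, wue = 0.05,
                            initial_plant_weight_g = 20,
                            plant_id = genotype_id) {
  if (theta_cr <= 0 || theta_cr >= 1)
    stop("'theta_cr' must lie strictly in (0, 1)", call. = FALSE)
  if (slope <= 0) stop("'slope' must be positive", call. = FALSE)
  if (wue <= 0) stop("'wue' must be positive", call. = FALSE)
  if (e_max < 0) stop("'e_max' must be nonnegative", call. = FALSE)
  structure(list(genotype_id = genotype_id, plant_id = plant_id,
                 e_max = e_max, theta_cr = theta_cr, slope = slope,
                 wue = wue, initial_plant_weight_g = initial_plant_weight_g),
            class = "lysimeter_truth")
}

# piecewise normalized-transpiration response to relative soil water content
etw_response <- function(swc, e_max, theta_cr, slope) {
  ifelse(swc >= theta_cr, e_max, pmax(0, e_max - slope * (theta_cr - swc)))
}

#' Simulate a gravimetric lysimeter run
#'
#' Emulates a pot-on-load-cell system: container weight decreases
#' monotonically during daytime through plant transpiration, nightly
#' irrigation during pretreatment/recovery refills the pot to capacity (the
#' excess drains through an overflow, so after every irrigation-drainage
#' cycle the system returns to its base weight plus accumulated plant
#' biomass), and no irrigation occurs during the drought phase. Transpiration
#' per minute is `etw_response(swc) * plant_weight * VPD` during daylight and
#' zero at night; biomass accumulates as `wue` times transpired water.
#'
#' @param truth A [lysimeter_truth()] object.
#' @param climate Climate trace from [simulate_climate()]; must cover the
#'   phases.
#' @param phases Named or positional integer vector
#'   `(pretreatment, drought, recovery)` in days; pretreatment >= 1.
#' @param irrigation_days Optional integer vector of days with a nightly
#'   irrigation event; defaults to all pretreatment and recovery days. An
#'   irrigation scheduled inside the drought phase is an error.
#' @param pot List of pot parameters: `water_capacity_g` (drained upper
#'   limit of the pot water store), `tare_g` (container + dry soil),
#'   `vwc_sat` (probe volumetric water content at capacity).
#' @param irrigation_time Clock time of the nightly irrigation.
#' @param drainage_min Minutes from irrigation start until drainage is
#'   complete; the trace is flagged as irrigation-disturbed in between.
#' @param weight_noise_sd Load-cell noise s.d. (g).
#' @param rate_noise_cv Multiplicative coefficient of variation on the
#'   instantaneous transpiration rate (physiological fluctuation).
#' @param daylight Clock hours `c(start, end)` of stomatal opening.
#' @param seed Optional integer seed.
#' @return List of class `"lysimeter_run"`: `weigh` (plant_id, timestamp,
#'   weight_g, irrigation_flag, drainage_done), `soil` (timestamp,
#'   permittivity, vwc, swc_rel, ec, soil_temp), `events` (irrigation
#'   ledger), `daily_truth` (per-day transpired water and biomass gain),
#'   plus `truth`, `phases`, `pot`, and the total transpiration.
#' @export
simulate_lysimeter_run <- function(truth, climate,
                                   phases = c(pretreatment = 5, drought = 10, recovery = 0),
                                   irrigation_days = NULL,
                                   pot = list(water_capacity_g = 1000, tare_g = 800, vwc_sat = 0.35),
                                   irrigation_time = "21:00", drainage_min = 60,
                                   weight_noise_sd = 0, rate_noise_cv = 0,
                                   daylight = c(6, 18), seed = NULL) {
  stopifnot(inherits(truth, "lysimeter_truth"))
  if (any(phases < 0) || phases[1] < 1)
    stop("phases must be nonnegative with pretreatment >= 1", call. = FALSE)
  n_days <- sum(phases)
  drought_window <- if (phases[2] > 0) phases[1] + seq_len(phases[2]) else integer(0)
  if (is.null(irrigation_days))
    irrigation_days <- setdiff(seq_len(n_days), drought_window)
  if (length(intersect(irrigation_days, drought_window)))
    stop("invalid schedule: irrigation event inside the drought phase", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  step <- grid_step_min(climate$timestamp)
  n <- n_days * 1440L / step
  if (nrow(climate) < n) stop("climate trace shorter than the phases", call. = FALSE)
  ts <- climate$timestamp[seq_len(n)]
  vpd <- compute_vpd(climate$air_temp[seq_len(n)], climate$rel_humidity[seq_len(n)])
  cm <- clock_min(ts)
  dayv <- trace_day(ts)
  is_day <- cm >= daylight[1] * 60 & cm < daylight[2] * 60
  irr_start <- hm_to_min(irrigation_time)
  in_irr <- cm >= irr_start & cm < irr_start + drainage_min & dayv %in% irrigation_days
  drain_done <- cm >= irr_start + drainage_min &
    cm < irr_start + drainage_min + step & dayv %in% irrigation_days

  w_noise <- if (weight_noise_sd > 0) stats::rnorm(n, 0, weight_noise_sd) else numeric(n)
  r_noise <- if (rate_noise_cv > 0) stats::rnorm(n, 0, rate_noise_cv) else numeric(n)

  cap <- pot$water_capacity_g
  water <- cap
  w_plant <- truth$initial_plant_weight_g
  weight <- numeric(n); swc <- numeric(n)
  transp_step <- numeric(n)
  refill_at <- irr_start + drainage_min   # pot back at capacity once drained
  refill_step <- dayv %in% irrigation_days & cm >= refill_at & cm < refill_at + step
  added_g <- rep(NA_real_, n)

  # the load cell sees the plant's biomass only after a drainage reset: in
  # between, weight falls solely through transpiration
  w_seen <- w_plant
  for (i in seq_len(n)) {
    if (is_day[i]) {
      e <- etw_response(water / cap, truth$e_max, truth$theta_cr, truth$slope)
      tr <- e * w_plant * vpd[i] * step * (1 + r_noise[i])
      tr <- min(max(tr, 0), water)
      water <- water - tr
      w_plant <- w_plant + truth$wue * tr
      transp_step[i] <- tr
    }
    if (refill_step[i]) {
      added_g[i] <- cap - water
      water <- cap
      w_seen <- w_plant
    }
    weight[i] <- pot$tare_g + water + w_seen + w_noise[i]
    swc[i] <- water / cap
  }
  events <- data.frame(day = dayv[refill_step], added_g = added_g[refill_step])

  daily_truth <- data.frame(
    day = seq_len(n_days),
    transp_g = as.numeric(tapply(transp_step, dayv, sum)),
    gain_g = truth$wue * as.numeric(tapply(transp_step, dayv, sum)))

  vwc <- swc * pot$vwc_sat
  soil <- data.frame(timestamp = ts,
                     permittivity = topp_permittivity(vwc),
                     vwc = vwc, swc_rel = swc,
                     ec = rep(1.2, n),
                     soil_temp = climate$air_temp[seq_len(n)] * 0.5 + 11)
  weigh <- data.frame(plant_id = truth$plant_id, timestamp = ts,
                      weight_g = weight, irrigation_flag = in_irr,
                      drainage_done = drain_done)
  structure(list(weigh = weigh, soil = soil, events = events,
                 daily_truth = daily_truth, truth = truth, phases = phases,
                 pot = pot, total_transp_g = sum(transp_step),
                 final_water_g = water, vpd = vpd),
            class = "lysimeter_run")
}
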