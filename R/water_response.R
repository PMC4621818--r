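#' Midday transpiration points across soil drying
#'
#' One point per drought day: the median weight- and VPD-normalized
#' transpiration (ETW) over the midday window against the mean relative soil
#' water content over the same window. Days with no defined ETW sample in
#' the window are omitted with a warning.
#'
#' @param etw Data frame `timestamp`, `etw` from [normalize_etw()].
#' @param swc Numeric relative soil water content aligned with
#'   `etw$timestamp`.
#' @param days Optional integer vector restricting to specific days (e.g.
#'   the drought phase).
#' @param midday Clock window, default 11:00-14:00.
#' @return Data frame `day`, `swc`, `etw`.
#' @export
extract_midday_points <- function(etw, swc, days = NULL,
                                  midday = c("11:00", "14:00")) {
  if (length(swc) != nrow(etw))
    stop("'swc' must align with the ETW series", call. = FALSE)
  dayv <- trace_day(etw$timestamp)
  sel_days <- if (is.null(days)) sort(unique(dayv)) else days
  inwin <- in_clock_window(etw$timestamp, midday)
  out <- lapply(sel_days, function(d) {
    i <- dayv == d & inwin & !is.na(etw$etw)
    if (!any(i)) return(NULL)
    data.frame(day = d, swc = mean(swc[dayv == d & inwin]),
               etw = stats::median(etw$etw[i]))
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0) warning(dropped, " day(s) omitted: no defined midday ETW")
  do.call(rbind, out)
}

segmented_rss <- function(theta, s, y) {
  # model linear in (e_max, slope) at fixed breakpoint: y = e_max - slope * h
  h <- pmax(0, theta - s)
  fit <- stats::lm.fit(cbind(1, -h), y)
  b <- fit$coefficients
  if (is.na(b[2]) || b[2] < 0) {      # hinge must decline: fall back to flat
    b <- c(mean(y), 0)
    return(list(rss = sum((y - b[1])^2), e_max = b[1], slope = 0))
  }
  list(rss = sum(fit$residuals^2), e_max = unname(b[1]), slope = unname(b[2]))
}

#' Segmented (plateau-hinge) fit of midday transpiration vs soil water
#'
#' Least-squares fit of the continuous two-segment response
#' \deqn{etw(s) = E_{max} \quad (s \ge \theta_{cr});\qquad
#'       etw(s) = E_{max} - slope\,(\theta_{cr} - s) \quad (s < \theta_{cr})}
#' The breakpoint is found by grid search over the observed SWC range
#' (candidates keep at least two points on each side), followed by local
#' refinement with [stats::optimize()]; ties in RSS break toward the
#' smallest breakpoint. If no breakpoint beats a flat line the flat fit is
#' returned with `no_breakpoint = TRUE` and `theta_cr = NA`.
#'
#' @param points Data frame `swc`, `etw` from [extract_midday_points()]
#'   (>= 5 points).
#' @param grid_step Breakpoint grid resolution in relative-SWC units.
#' @return List of class `"water_response_fit"`: `e_max`, `theta_cr`,
#'   `slope`, `rss`, `n_points`, `no_breakpoint`.
#' @export
fit_segmented <- function(points, grid_step = 0.005) {
  s <- points$swc; y <- points$etw
  ok <- is.finite(s) & is.finite(y)
  s <- s[ok]; y <- y[ok]
  n <- length(s)
  if (n < 5) stop("segmented fit needs at least 5 midday points", call. = FALSE)

  flat <- list(rss = sum((y - mean(y))^2), e_max = mean(y), slope = 0)
  ss <- sort(s)
  # candidate breakpoints must keep >= 2 points strictly below and >= 1 at/above
  lo <- ss[2] + grid_step
  hi <- ss[n - 1]
  if (lo >= hi) {
    return(structure(list(e_max = flat$e_max, theta_cr = NA_real_, slope = 0,
                          rss = flat$rss, n_points = n, no_breakpoint = TRUE),
                     class = "water_response_fit"))
  }
  grid <- seq(lo, hi, by = grid_step)
  rss <- vapply(grid, function(th) segmented_rss(th, s, y)$rss, numeric(1))
  best <- grid[which.min(rss)]           # which.min takes the first (smallest theta) tie
  refined <- stats::optimize(function(th) segmented_rss(th, s, y)$rss,
                             interval = c(max(lo, best - grid_step),
                                          min(hi, best + grid_step)))
  theta <- if (refined$objective < min(rss)) refined$minimum else best
  fit <- segmented_rss(theta, s, y)

  if (fit$slope <= 0 || fit$rss >= flat$rss - 1e-12) {
    return(structure(list(e_max = flat$e_max, theta_cr = NA_real_, slope = 0,
                          rss = flat$rss, n_points = n, no_breakpoint = TRUE),
                     class = "water_response_fit"))
  }
  structure(list(e_max = fit$e_max, theta_cr = theta, slope = fit$slope,
                 rss = fit$rss, n_points = n, no_breakpoint = FALSE),
            class = "water_response_fit")
}

#' @export
print.water_response_fit <- function(x, ...) {
  if (x$no_breakpoint) {
    cat(sprintf("flat transpiration response: E_max %.4g (no breakpoint, %d points)\n",
                x$e_max, x$n_points))
  } else {
    cat(sprintf("E_max %.4g, theta_cr %.3f, slope %.4g (RSS %.3g, %d points)\n",
                x$e_max, x$theta_cr, x$slope, x$rss, x$n_points))
  }
  invisible(x)
}

# greedy insert-absorb compact letter display from a logical "differs" matrix
cld_letters <- function(differs) {
  g <- nrow(differs)
  sets <- list(seq_len(g))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (!differs[i, j]) next
    repeat {   # split every letter set still holding the differing pair
      k <- which(vapply(sets, function(s) all(c(i, j) %in% s), logical(1)))
      if (!length(k)) break
      sets <- c(sets[-k[1]], list(setdiff(sets[[k[1]]], i)),
                list(setdiff(sets[[k[1]]], j)))
    }
    sets <- unique(lapply(sets, sort))
    proper_subset <- vapply(seq_along(sets), function(a)
      any(vapply(seq_along(sets), function(b)
        a != b && length(sets[[a]]) < length(sets[[b]]) &&
          all(sets[[a]] %in% sets[[b]]), logical(1))), logical(1))
    sets <- sets[!proper_subset & lengths(sets) > 0]
  }
  ord <- order(vapply(sets, min, numeric(1)))
  sets <- sets[ord]
  vapply(seq_len(g), function(i)
    paste(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
          collapse = ""), character(1))
}

#' Compare water-response parameters between genotypes
#'
#' Pairwise Welch t-tests per parameter across genotypes, summarised as mean
#' +/- SE with a compact letter display: genotypes sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param fits Data frame with columns `genotype`, `plant_id` and the
#'   parameter columns (default `e_max`, `theta_cr`, `slope`), one row per
#'   plant.
#' @param params Parameter columns to compare.
#' @param alpha Significance level for the letter display.
#' @param min_n Minimum plants per genotype.
#' @return Data frame `genotype`, `parameter`, `mean`, `se`, `n`, `letters`.
#' @export
compare_genotypes <- function(fits, params = c("e_max", "theta_cr", "slope"),
                              alpha = 0.05, min_n = 3) {
  gt <- unique(fits$genotype)
  if (length(gt) < 2) stop("need at least two genotypes to compare", call. = FALSE)
  cnt <- table(fits$genotype)
  if (any(cnt < 2)) stop("cannot test: a genotype has a single plant", call. = FALSE)
  if (any(cnt < min_n))
    warning("genotype(s) with fewer than ", min_n, " plants")
  out <- list()
  for (p in params) {
    vals <- split(fits[[p]], factor(fits$genotype, levels = gt))
    differs <- matrix(FALSE, length(gt), length(gt))
    for (i in seq_along(gt)[-length(gt)]) for (j in (i + 1):length(gt)) {
      pv <- tryCatch(stats::t.test(vals[[i]], vals[[j]])$p.value,
                     error = function(e) 1)
      differs[i, j] <- differs[j, i] <- is.finite(pv) && pv < alpha
    }
    out[[p]] <- data.frame(
      genotype = gt, parameter = p,
      mean = vapply(vals, mean, numeric(1)),
      se = vapply(vals, function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
      n = vapply(vals, length, integer(1)),
      letters = cld_letters(differs), row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
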