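#' Construct a growth curve
#'
#' One well's optical-density (OD595) time series.
#'
#' @param well_id well label.
#' @param times read times in hours, strictly increasing.
#' @param od OD readings, same length as `times`, finite.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(well_id, times, od) {
  stopifnot(length(times) == length(od), length(times) >= 5,
            all(diff(times) > 0), all(is.finite(od)))
  structure(list(well_id = well_id, times = as.numeric(times),
                 od = as.numeric(od)),
            class = "growth_curve")
}

#' Blank-correct and floor a growth curve
#'
#' Subtracts the blank OD and clamps readings below a positive floor to the
#' floor so logarithms are defined downstream.
#'
#' @param curve `growth_curve`.
#' @param blank_od blank (medium-only) OD, >= 0.
#' @param floor positive lower clamp (default 1e-3).
#' @return blank-corrected `growth_curve`.
#' @export
preprocess_curve <- function(curve, blank_od = 0, floor = 1e-3) {
  stopifnot(blank_od >= 0, floor > 0)
  od <- pmax(curve$od - blank_od, floor)
  if (length(od) < 5L) stop("fewer than 5 usable points")
  growth_curve(curve$well_id, curve$times, od)
}

#' Growth rate by windowed log-linear fitting
#'
#' Fits least-squares lines to ln(OD) over every contiguous window of
#' `window_points` reads and returns the maximal slope among windows whose
#' r-squared passes the quality gate — the standard maximal-specific-growth
#' procedure, which rides out lag and stationary phases without explicit
#' changepoint detection. Windows whose mean OD falls below a fraction
#' `min_od_frac` of the curve's maximum are additionally excluded: at
#' plate-reader noise levels the relative error of ln(OD) blows up near the
#' detection floor, and maximising over such windows would bias the rate
#' upward. The gate is relative, so the estimate is invariant to rescaling
#' the OD axis, and flat wells (blanks, non-growers) still return rate 0.
#'
#' @param curve `growth_curve` (blank-corrected, strictly positive OD).
#' @param window_points window length in reads (>= 3, <= curve length).
#' @param r2_min minimal r-squared for a window to qualify.
#' @param min_od_frac minimal mean window OD as a fraction of the curve
#'   maximum (see above).
#' @return list of class `growth_fit`: `rate` (h^-1), `window`
#'   (start, end indices), `r2`, `se` (NA for a single curve).
#' @export
#' @examples
#' t <- seq(0, 5, by = 0.25)
#' gc <- growth_curve("w", t, 0.01 * exp(0.5 * t))
#' growth_rate(gc)$rate
growth_rate <- function(curve, window_points = 7, r2_min = 0.98,
                        min_od_frac = 0.03) {
  n <- length(curve$od)
  stopifnot(window_points >= 3, window_points <= n)
  if (any(curve$od <= 0)) stop("OD must be strictly positive (preprocess first)")
  t <- curve$times
  y <- log(curve$od)
  n_win <- n - window_points + 1L
  slopes <- r2s <- mean_od <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- i:(i + window_points - 1L)
    tt <- t[idx]; yy <- y[idx]
    tc <- tt - mean(tt); yc <- yy - mean(yy)
    sxx <- sum(tc^2); sxy <- sum(tc * yc); syy <- sum(yc^2)
    slopes[i] <- sxy / sxx
    r2s[i] <- if (syy > 0) (sxy^2) / (sxx * syy) else 1  # flat window: perfect fit, slope 0
    mean_od[i] <- mean(curve$od[idx])
  }
  ok <- r2s >= r2_min & mean_od >= min_od_frac * max(curve$od)
  if (!any(ok)) ok <- r2s >= r2_min
  if (!any(ok)) {
    stop(sprintf("no window of %d points reaches r2 >= %.3g (best r2 = %.4f)",
                 window_points, r2_min, max(r2s)))
  }
  best <- which(ok)[which.max(slopes[ok])]
  structure(list(rate = slopes[best],
                 window = c(best, best + window_points - 1L),
                 r2 = r2s[best], se = NA_real_),
            class = "growth_fit")
}

#' Aggregate replicate growth fits
#'
#' Mean rate and standard error over replicate wells.
#'
#' @param fits list of `growth_fit` objects (>= 1).
#' @return `growth_fit` with the mean rate, `se` over wells, `n_wells`.
#' @export
aggregate_replicates <- function(fits) {
  if (length(fits) < 1L) stop("no growth fits to aggregate (quality filtering removed all wells)")
  rates <- vapply(fits, function(f) f$rate, numeric(1))
  agg <- combine_replicates(rates)
  structure(list(rate = agg$mean, window = NULL,
                 r2 = mean(vapply(fits, function(f) f$r2, numeric(1))),
                 se = agg$se, n_wells = agg$n),
            class = "growth_fit")
}

#' Growth rate for a set of replicate wells
#'
#' Convenience wrapper: preprocess, fit, and aggregate a condition's wells,
#' silently dropping wells that fail the window quality gate (an error is
#' raised only if none survive).
#'
#' @param curves list of `growth_curve` objects.
#' @param blank_od blank OD subtracted from every well.
#' @inheritParams growth_rate
#' @return aggregated `growth_fit`.
#' @export
growth_rate_replicates <- function(curves, blank_od = 0, window_points = 7,
                                   r2_min = 0.98, min_od_frac = 0.03) {
  fits <- list()
  for (cv in curves) {
    f <- tryCatch(growth_rate(preprocess_curve(cv, blank_od),
                              window_points, r2_min, min_od_frac),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  aggregate_replicates(fits)
}
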