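#' Internal body temperature at loss of equilibrium
#'
#' During a constant thermal ramp, body temperature lags water temperature
#' according to the first-order model `dTb/dt = k (Tw - Tb)` with a
#' mass-dependent rate constant `k = lag_k0 * mass^(-lag_gamma)`. Under a
#' linear ramp of rate `r` the closed form of the lag is
#' `(r/k) * (1 - exp(-k t))`, approaching the steady state `r/k`. For a
#' heating (CTmax) ramp the body is cooler than the water at LOE, so the
#' lag is subtracted; for a cooling (CTmin) ramp it is added. Large `k`
#' (small fish, fast equilibration) recovers the water temperature.
#'
#' @param water_temp_at_loe water temperature at loss of equilibrium
#'   (degC).
#' @param start_temp ramp start temperature (degC); the ramp direction is
#'   inferred from its sign relative to `water_temp_at_loe`.
#' @param ramp_rate ramp rate (degC/min), positive.
#' @param mass body mass (g), positive.
#' @param lag_k0 rate constant at 1 g (1/min).
#' @param lag_gamma mass exponent of the rate constant.
#' @return Internal body temperature at LOE (degC), the critical thermal
#'   limit. Vectorised over all arguments.
#' @export
internal_temp_at_loe <- function(water_temp_at_loe, start_temp,
                                 ramp_rate = 0.1, mass,
                                 lag_k0 = 1.2, lag_gamma = 0.33) {
  if (any(ramp_rate <= 0)) stop("ramp_rate must be positive")
  if (any(mass <= 0)) stop("mass must be positive")
  k <- lag_k0 * mass^(-lag_gamma)
  if (any(k <= 0)) stop("lag rate constant must be positive")
  t_elapsed <- abs(water_temp_at_loe - start_temp) / ramp_rate
  lag <- (ramp_rate / k) * (1 - exp(-k * t_elapsed))
  water_temp_at_loe - sign(water_temp_at_loe - start_temp) * lag
}

#' Critical thermal limits for a table of CT trials
#'
#' Applies the internal-temperature lag correction to every trial row,
#' returning the trials with a `critical_limit` column (the internal
#' temperature at LOE) and the lag coefficients recorded as attributes.
#'
#' @param trials data frame with columns `water_temp_at_loe`,
#'   `start_temp`, `ramp_rate`, `mass` (plus any metadata).
#' @param lag_k0,lag_gamma lag coefficients, see [internal_temp_at_loe()].
#' @return The input with `critical_limit` and `internal_temp_at_loe`
#'   columns appended.
#' @export
ct_limits <- function(trials, lag_k0 = 1.2, lag_gamma = 0.33) {
  need <- c("water_temp_at_loe", "start_temp", "ramp_rate", "mass")
  stopifnot(all(need %in% names(trials)))
  tb <- internal_temp_at_loe(trials$water_temp_at_loe, trials$start_temp,
                             trials$ramp_rate, trials$mass,
                             lag_k0 = lag_k0, lag_gamma = lag_gamma)
  trials$internal_temp_at_loe <- tb
  trials$critical_limit <- tb
  attr(trials, "lag_coefficients") <- c(lag_k0 = lag_k0,
                                        lag_gamma = lag_gamma)
  trials
}

# days present per calendar-year x month
month_coverage <- function(dates) {
  lt <- as.POSIXlt(dates)
  table(year = lt$year + 1900, month = lt$mon + 1)
}

#' Mean annual sea-surface-temperature extremes
#'
#' Per calendar year takes the maximum and minimum of daily SST, then
#' averages across years. Years with incomplete coverage contribute their
#' maximum only if the local summer window is sufficiently covered and
#' their minimum only if the winter window is (so a series truncated in
#' autumn still yields that year's summer maximum but not a defensible
#' winter minimum is handled by the window test, not by dropping the
#' year outright).
#'
#' @param series an `sst_series` data frame (`date`, `sst_c`).
#' @param window optional `c(start, end)` dates restricting the series.
#' @param summer_months,winter_months months defining the local seasons
#'   (defaults: June-September and January-March, northern subtropics).
#' @param min_coverage minimum fraction of season days required.
#' @return A list with `mean_annual_max`, `mean_annual_min` and `by_year`
#'   (per-year extremes with inclusion flags).
#' @export
env_extremes <- function(series, window = NULL, summer_months = 6:9,
                         winter_months = 1:3, min_coverage = 0.9) {
  stopifnot(all(c("date", "sst_c") %in% names(series)))
  s <- series
  if (!is.null(window))
    s <- s[s$date >= window[1] & s$date <= window[2], , drop = FALSE]
  if (!nrow(s)) stop("no observations in window")
  lt <- as.POSIXlt(s$date)
  yr <- lt$year + 1900
  mo <- lt$mon + 1
  years <- sort(unique(yr))
  season_ok <- function(y, months) {
    have <- sum(yr == y & mo %in% months)
    all_months <- as.POSIXlt(seq(as.Date(sprintf("%d-01-01", y)),
                                 as.Date(sprintf("%d-12-31", y)),
                                 by = "day"))$mon + 1
    have >= min_coverage * sum(all_months %in% months)
  }
  by_year <- data.frame(
    year = years,
    max = vapply(years, function(y) max(s$sst_c[yr == y]), numeric(1)),
    min = vapply(years, function(y) min(s$sst_c[yr == y]), numeric(1)),
    use_max = vapply(years, season_ok, logical(1), months = summer_months),
    use_min = vapply(years, season_ok, logical(1), months = winter_months)
  )
  if (!any(by_year$use_max) || !any(by_year$use_min))
    stop("window does not cover a complete season in any year")
  list(mean_annual_max = mean(by_year$max[by_year$use_max]),
       mean_annual_min = mean(by_year$min[by_year$use_min]),
       by_year = by_year)
}

#' Annual median and range of a sea-surface-temperature series
#'
#' @param series an `sst_series`.
#' @param min_days calendar years with fewer observations are dropped with
#'   a warning.
#' @return Data frame with one row per retained year: `year`, `median`,
#'   `range`, `n_days`.
#' @export
annual_stats <- function(series, min_days = 300) {
  stopifnot(all(c("date", "sst_c") %in% names(series)))
  yr <- as.POSIXlt(series$date)$year + 1900
  years <- sort(unique(yr))
  out <- data.frame(
    year = years,
    median = vapply(years, function(y) stats::median(series$sst_c[yr == y]),
                    numeric(1)),
    range = vapply(years, function(y) diff(range(series$sst_c[yr == y])),
                   numeric(1)),
    n_days = vapply(years, function(y) sum(yr == y), numeric(1))
  )
  short <- out$n_days < min_days
  if (any(short)) {
    warning(sum(short), " year(s) with fewer than ", min_days,
            " days dropped")
    out <- out[!short, , drop = FALSE]
  }
  out
}

#' Descriptive seasonal polynomial fit to daily SST
#'
#' Fits a fourth-order (by default) polynomial of SST on day-of-year, a
#' purely descriptive smooth of the seasonal cycle.
#'
#' @param series an `sst_series`.
#' @param degree polynomial degree.
#' @return A list with the `lm` fit, `r2` and a `predict(doy)` function.
#' @export
fit_seasonal_polynomial <- function(series, degree = 4) {
  doy <- as.POSIXlt(series$date)$yday + 1
  fit <- stats::lm(series$sst_c ~ stats::poly(doy, degree))
  list(fit = fit, r2 = summary(fit)$r.squared,
       predict = function(d) {
         unname(stats::predict(fit, newdata = data.frame(doy = d)))
       })
}

#' Thermal safety margin
#'
#' The gap between an individual's critical thermal limit and the
#' environmental extreme it experiences: in summer `CTmax - mean annual
#' maximum`, in winter `mean annual minimum - CTmin`. Negative margins
#' (environment already beyond tolerance) are preserved and flagged.
#'
#' @param critical_limit critical thermal limit(s) (degC; internal
#'   temperature at LOE).
#' @param extreme environmental extreme (degC): mean annual maximum for
#'   summer, mean annual minimum for winter.
#' @param season `"summer"` or `"winter"`.
#' @return Margin(s) in degC with attribute `flag_negative`.
#' @export
thermal_safety_margin <- function(critical_limit, extreme,
                                  season = c("summer", "winter")) {
  season <- match.arg(season)
  margin <- if (season == "summer") critical_limit - extreme
            else extreme - critical_limit
  attr(margin, "flag_negative") <- margin < 0
  margin
}
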