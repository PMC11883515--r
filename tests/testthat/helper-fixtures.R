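# shared fixtures and independent oracles used across test files

# noise-free generator settings: no sensor noise, no individual variation,
# no background, fast post-exercise recovery so late cycles sit exactly at
# SMR within double precision
noiseless_cfg <- function(...) {
  args <- list(o2_noise_sd = 0, trait_cv = 0, epoc_tau = 30,
               background_slope_pre = 0, background_slope_post = 0)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# build an mo2_series data frame directly
make_series <- function(mo2, start_times = seq(300, by = 10,
                                               length.out = length(mo2))) {
  n <- length(mo2)
  structure(data.frame(cycle_index = seq_len(n),
                       cycle_start_time = start_times,
                       mo2 = mo2, slope = -mo2, slope_r2 = rep(1, n),
                       flag_low_r2 = rep(FALSE, n),
                       flag_positive_slope = rep(FALSE, n)),
            class = c("mo2_series", "data.frame"))
}

# brute-force sort-and-interpolate quantile (linear interpolation between
# order statistics), independent of stats::quantile
quantile_oracle <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# daily sinusoidal SST series built by hand (independent of generate_sst)
sinusoid_sst <- function(mean = 27, amplitude = 9.25, years = 3,
                         phase = 227, noise_sd = 0, start_year = 2010,
                         end_date = NULL) {
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)),
               by = "day")
  if (!is.null(end_date)) dates <- dates[dates <= as.Date(end_date)]
  doy <- as.POSIXlt(dates)$yday + 1
  sst <- mean + amplitude * cos(2 * pi * (doy - phase) / 365.25)
  if (noise_sd > 0) sst <- sst + rnorm(length(dates), 0, noise_sd)
  data.frame(site = "test", date = dates, sst_c = sst)
}
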