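#' Configuration for the synthetic respirometry / thermal-limit generator
#'
#' Builds a validated list of ground-truth parameters from which every raw
#' input of the pipeline (oxygen traces, cohorts, critical-thermal-limit
#' trials and sea-surface-temperature series) can be generated. All
#' downstream estimators can then be checked by parameter recovery.
#'
#' The defaults describe a small blenny-like reef fish held at the five
#' seasonal acclimation temperatures of a hot-sea population: standard
#' metabolic rate (SMR) rises exponentially with temperature, aerobic scope
#' (AS) follows a Gaussian thermal performance curve, and maximum metabolic
#' rate (MMR) is their sum, so MMR > SMR is guaranteed wherever AS > 0.
#'
#' @param seed default integer seed recorded in the config.
#' @param species_label,region_label labels copied into generated metadata.
#' @param acclimation_temps acclimation temperatures (degrees C).
#' @param n_fish_per_cell fish per species x region x temperature cell.
#' @param mass_log_mean,mass_log_sd parameters of the lognormal body-mass
#'   distribution (log grams).
#' @param allometric_exponent_b scaling exponent applied to mass-specific
#'   trait ground truths, `trait = base(T) * mass^b`. May be a single value
#'   or a named vector with elements `SMR` and `AS`. The default -0.2 is the
#'   classic decline of mass-specific metabolic rate with body mass.
#' @param smr_tpc named vector `c(a, b)` of the exponential SMR curve
#'   `a * exp(b * T)` (mg O2 kg-1 h-1; b in 1/degC).
#' @param as_tpc named vector `c(amplitude, topt, breadth_sd)` of the
#'   Gaussian AS curve (mg O2 kg-1 h-1; degC; degC).
#' @param trait_cv between-individual coefficient of variation applied as
#'   mean-one lognormal multiplicative noise on SMR and AS ground truths.
#' @param epoc_tau time constant (minutes) of the exponential decay of
#'   post-exercise oxygen consumption toward SMR.
#' @param background_slope_pre,background_slope_post microbial background
#'   oxygen depletion slopes (mg O2 L-1 min-1, negative) at trial start and
#'   end; the generator interpolates linearly between them.
#' @param o2_saturation dissolved-oxygen saturation concentration (mg/L)
#'   restored by every flush.
#' @param o2_noise_sd Gaussian sensor noise SD (mg/L) per sample.
#' @param cycle named vector `c(total, measure, flush)` in minutes;
#'   `measure + flush` must not exceed `total`.
#' @param sample_dt sampling interval of the oxygen logger (minutes).
#' @param chamber_volume respirometry chamber volume (L).
#' @param duration_h overnight trial duration (hours).
#' @param ct_true_limit named vector `c(max, min)`: true internal critical
#'   thermal limits (degC).
#' @param ct_limit_sd between-individual SD of the true limit (degC).
#' @param lag_k0,lag_gamma internal-temperature lag coefficients: the rate
#'   constant is `k = lag_k0 * mass^(-lag_gamma)` (1/min at 1 g; unitless).
#' @param ct_ramp_rate thermal ramping rate (degC/min).
#' @param sst named vector `c(mean, amplitude, noise_sd, years)` of the
#'   sinusoid-plus-noise daily sea-surface-temperature model.
#'
#' @return A list of class `synthetic_config`.
#' @seealso [generate_o2_trace()], [generate_cohort()],
#'   [generate_ct_trial()], [generate_sst()]
#' @export
synthetic_config <- function(seed = 1L,
                             species_label = "E_pulcher",
                             region_label = "AG",
                             acclimation_temps = c(18, 22, 27, 31.5, 35.5),
                             n_fish_per_cell = 8L,
                             mass_log_mean = log(1.43),
                             mass_log_sd = 0.45,
                             allometric_exponent_b = -0.2,
                             smr_tpc = c(a = 28.6, b = 0.063),
                             as_tpc = c(amplitude = 450, topt = 29.2,
                                        breadth_sd = 11.8),
                             trait_cv = 0.10,
                             epoc_tau = 60,
                             background_slope_pre = -5e-4,
                             background_slope_post = -1e-3,
                             o2_saturation = 6.8,
                             o2_noise_sd = 0.005,
                             cycle = c(total = 10, measure = 5, flush = 5),
                             sample_dt = 1 / 12,
                             chamber_volume = 0.175,
                             duration_h = 18,
                             ct_true_limit = c(max = 39.5, min = 8.65),
                             ct_limit_sd = 0.3,
                             lag_k0 = 1.2,
                             lag_gamma = 0.33,
                             ct_ramp_rate = 0.1,
                             sst = c(mean = 27.25, amplitude = 9.25,
                                     noise_sd = 0.3, years = 10)) {
  b <- allometric_exponent_b
  if (is.null(names(b))) b <- c(SMR = b[[1]], AS = b[[1]])
  stopifnot(
    "n_fish_per_cell must be >= 1" = n_fish_per_cell >= 1,
    "SDs and CVs must be non-negative" =
      all(c(mass_log_sd, trait_cv, o2_noise_sd, ct_limit_sd,
            sst[["noise_sd"]]) >= 0),
    "measure + flush must fit within the cycle" =
      cycle[["measure"]] + cycle[["flush"]] <= cycle[["total"]],
    "epoc_tau must be positive" = epoc_tau > 0,
    "chamber volume must be positive" = chamber_volume > 0,
    "sample_dt must be positive" = sample_dt > 0,
    "AS amplitude must be positive so that MMR > SMR" =
      as_tpc[["amplitude"]] > 0,
    "Gaussian breadth must be positive" = as_tpc[["breadth_sd"]] > 0,
    "SMR scale a must be positive" = smr_tpc[["a"]] > 0,
    "ramp rate must be positive" = ct_ramp_rate > 0,
    "lag_k0 must be positive" = lag_k0 > 0,
    "at least one simulated year" = sst[["years"]] >= 1
  )
  cfg <- list(
    seed = as.integer(seed),
    species_label = species_label, region_label = region_label,
    acclimation_temps = acclimation_temps,
    n_fish_per_cell = as.integer(n_fish_per_cell),
    mass_log_mean = mass_log_mean, mass_log_sd = mass_log_sd,
    allometric_exponent_b = b,
    smr_tpc = smr_tpc, as_tpc = as_tpc, trait_cv = trait_cv,
    epoc_tau = epoc_tau,
    background_slope_pre = background_slope_pre,
    background_slope_post = background_slope_post,
    o2_saturation = o2_saturation, o2_noise_sd = o2_noise_sd,
    cycle = cycle, sample_dt = sample_dt,
    chamber_volume = chamber_volume, duration_h = duration_h,
    ct_true_limit = ct_true_limit, ct_limit_sd = ct_limit_sd,
    lag_k0 = lag_k0, lag_gamma = lag_gamma, ct_ramp_rate = ct_ramp_rate,
    sst = sst
  )
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>", x$species_label, "/", x$region_label, "\n")
  cat("  temperatures:", paste(x$acclimation_temps, collapse = ", "),
      "degC;", x$n_fish_per_cell, "fish per cell\n")
  cat("  SMR: ", x$smr_tpc[["a"]], " * exp(", x$smr_tpc[["b"]], " T);  AS: ",
      x$as_tpc[["amplitude"]], " * N(", x$as_tpc[["topt"]], ", ",
      x$as_tpc[["breadth_sd"]], ")\n", sep = "")
  invisible(x)
}

# Deterministic (noise-free) trait ground truths at temperature T for a fish
# of the given mass. MMR = SMR + AS by construction.
true_traits <- function(config, temp, mass) {
  b <- config$allometric_exponent_b
  smr <- config$smr_tpc[["a"]] * exp(config$smr_tpc[["b"]] * temp) *
    mass^b[["SMR"]]
  as_ <- config$as_tpc[["amplitude"]] *
    exp(-(temp - config$as_tpc[["topt"]])^2 /
          (2 * config$as_tpc[["breadth_sd"]]^2)) * mass^b[["AS"]]
  list(smr = smr, as_ = as_, mmr = smr + as_)
}

# mean-one lognormal multiplicative noise factor
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic intermittent-flow respirometry oxygen trace
#'
#' Simulates one overnight chamber trace of alternating measure and flush
#' phases. Oxygen uptake is held at `mmr_true` throughout the first measure
#' phase (the post-chase plateau that makes the first cycle a direct read of
#' MMR) and afterwards decays exponentially toward `smr_true` with time
#' constant `epoc_tau`. Within a measure phase oxygen declines by the exact
#' integral of the fish's uptake plus the (linearly drifting) microbial
#' background slope; each flush restores saturation. Gaussian sensor noise
#' is added to every sample.
#'
#' @param config a [synthetic_config()].
#' @param fish_mass body mass (g), must be positive.
#' @param temp trial temperature (degC).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param smr_true,mmr_true optional per-fish ground truths
#'   (mg O2 kg-1 h-1); defaults are the config's noise-free curves.
#' @param duration_h trace length in hours (default from config).
#' @param chamber_id label stored in the trace.
#'
#' @return A data frame of class `oxygen_trace` with columns `time_min`,
#'   `o2_mg_per_l`, `temp_c`, `phase`, `chamber_id`, and the generative
#'   truth stored in attribute `"truth"`.
#' @export
generate_o2_trace <- function(config, fish_mass, temp, seed = NULL,
                              smr_true = NULL, mmr_true = NULL,
                              duration_h = config$duration_h,
                              chamber_id = "ch1") {
  if (fish_mass <= 0) stop("fish_mass must be positive")
  if (!is.null(seed)) set.seed(seed)
  dt <- config$sample_dt
  cyc <- config$cycle
  if (cyc[["measure"]] < 2 * dt)
    stop("measure window shorter than 2 samples")
  if (is.null(smr_true) || is.null(mmr_true)) {
    tr <- true_traits(config, temp, fish_mass)
    if (is.null(smr_true)) smr_true <- tr$smr
    if (is.null(mmr_true)) mmr_true <- tr$mmr
  }
  total_min <- duration_h * 60
  t <- seq(0, total_min - dt, by = dt)
  tc <- t %% cyc[["total"]]                       # time within cycle
  phase <- ifelse(tc < cyc[["measure"]], "measure",
                  ifelse(tc < cyc[["measure"]] + cyc[["flush"]],
                         "flush", "wait"))
  mass_kg <- fish_mass / 1000
  v_eff <- config$chamber_volume - fish_mass / 1000  # fish displaces water
  if (v_eff <= 0) stop("fish volume exceeds chamber volume")
  tau <- config$epoc_tau
  tm <- cyc[["measure"]]                          # EPOC clock starts here
  d_mo2 <- mmr_true - smr_true

  # exact integral of MO2 (mg O2 kg-1 h-1) from 0 to time u (minutes)
  int_mo2 <- function(u) {
    plateau <- pmin(u, tm) * mmr_true
    ud <- pmax(u - tm, 0)
    plateau + smr_true * ud + d_mo2 * tau * (1 - exp(-ud / tau))
  }
  # integral of the drifting background slope (mg O2 L-1 min-1)
  bpre <- config$background_slope_pre
  bpost <- config$background_slope_post
  int_bg <- function(u) bpre * u + (bpost - bpre) * u^2 / (2 * total_min)

  phase_start <- t - tc                           # cycle start time
  # oxygen drop accumulated since the start of the current measure phase
  fish_drop <- (int_mo2(t) - int_mo2(phase_start)) * mass_kg / v_eff / 60
  bg_drop <- int_bg(t) - int_bg(phase_start)
  o2 <- config$o2_saturation - fish_drop + bg_drop
  o2[phase != "measure"] <- config$o2_saturation
  if (config$o2_noise_sd > 0)
    o2 <- o2 + stats::rnorm(length(o2), 0, config$o2_noise_sd)
  o2 <- pmax(o2, 0)

  out <- data.frame(time_min = t, o2_mg_per_l = o2, temp_c = temp,
                    phase = phase, chamber_id = chamber_id,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(smr_true = smr_true, mmr_true = mmr_true,
                             as_true = mmr_true - smr_true,
                             epoc_tau = tau, fish_mass = fish_mass,
                             chamber_volume = config$chamber_volume,
                             background_slope_pre = bpre,
                             background_slope_post = bpost,
                             o2_saturation = config$o2_saturation)
  class(out) <- c("oxygen_trace", "data.frame")
  out
}

#' Generate a synthetic cohort of fish with known trait ground truths
#'
#' Draws a cohort for one species x region across the configured
#' acclimation temperatures: lognormal body masses, mean-one lognormal
#' between-individual noise on SMR and AS ground truths (MMR = SMR + AS),
#' and optionally a full oxygen trace per fish.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @param traces if `TRUE`, also simulate an oxygen trace per fish (slower).
#' @param trait_cv override of the config's between-individual CV.
#'
#' @return A list of class `synthetic_cohort` with elements `metadata`
#'   (one row per fish: identity, mass, acclimation temperature, chamber
#'   volume, background slopes, and the `*_true` ground truths) and
#'   `traces` (named list of `oxygen_trace`, or `NULL`).
#' @export
generate_cohort <- function(config, seed = config$seed, traces = FALSE,
                            trait_cv = config$trait_cv) {
  set.seed(seed)
  cells <- expand.grid(temp = config$acclimation_temps,
                       rep = seq_len(config$n_fish_per_cell))
  cells <- cells[order(cells$temp, cells$rep), ]
  n <- nrow(cells)
  mass <- stats::rlnorm(n, config$mass_log_mean, config$mass_log_sd)
  base <- true_traits(config, cells$temp, mass)
  smr_true <- base$smr * rlnorm_cv(n, trait_cv)
  as_true <- base$as_ * rlnorm_cv(n, trait_cv)
  mmr_true <- smr_true + as_true
  meta <- data.frame(
    fish_id = sprintf("%s_%s_T%04.1f_%02d", config$species_label,
                      config$region_label, cells$temp, cells$rep),
    species = config$species_label, region = config$region_label,
    acclimation_temp = cells$temp, mass = mass,
    chamber_volume = config$chamber_volume,
    background_slope_pre = config$background_slope_pre,
    background_slope_post = config$background_slope_post,
    smr_true = smr_true, mmr_true = mmr_true, as_true = as_true,
    stringsAsFactors = FALSE
  )
  trace_list <- NULL
  if (traces) {
    trace_list <- lapply(seq_len(n), function(i) {
      generate_o2_trace(config, fish_mass = mass[i],
                        temp = meta$acclimation_temp[i],
                        smr_true = smr_true[i], mmr_true = mmr_true[i],
                        chamber_id = meta$fish_id[i])
    })
    names(trace_list) <- meta$fish_id
  }
  structure(list(metadata = meta, traces = trace_list, config = config,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$metadata), "fish,",
      length(unique(x$metadata$acclimation_temp)), "temperatures,",
      if (is.null(x$traces)) "no traces" else "with traces", "\n")
  invisible(x)
}

#' Generate a synthetic critical-thermal-limit trial
#'
#' Water temperature ramps linearly from the acclimation temperature at
#' `ct_ramp_rate`; internal body temperature follows the first-order lag
#' model `dTb/dt = k (Tw - Tb)` with `k = lag_k0 * mass^(-lag_gamma)`.
#' Loss of equilibrium (LOE) occurs when internal temperature crosses the
#' individual's true limit (config limit plus individual variation); the
#' trial records the water temperature at that moment.
#'
#' @param config a [synthetic_config()].
#' @param fish_mass body mass (g).
#' @param direction `"max"` (heating) or `"min"` (cooling).
#' @param start_temp ramp start = acclimation temperature (degC).
#' @param seed optional integer seed.
#'
#' @return A one-row data frame of class `ct_trial` with the true internal
#'   limit stored in attribute `"truth"`.
#' @export
generate_ct_trial <- function(config, fish_mass, direction = c("max", "min"),
                              start_temp, seed = NULL) {
  direction <- match.arg(direction)
  if (fish_mass <= 0) stop("fish_mass must be positive")
  if (!is.null(seed)) set.seed(seed)
  k <- config$lag_k0 * fish_mass^(-config$lag_gamma)
  r <- config$ct_ramp_rate
  limit <- config$ct_true_limit[[direction]] +
    stats::rnorm(1, 0, config$ct_limit_sd)
  sgn <- if (direction == "max") 1 else -1
  if (sgn * (limit - start_temp) <= 0)
    stop("ramp direction inconsistent with start temperature vs. true limit")
  # internal temperature under the ramp, relative displacement from start
  tb <- function(t) start_temp + sgn * (r * t - (r / k) * (1 - exp(-k * t)))
  t_max <- abs(limit - start_temp) / r + 10 / k + 100
  t_loe <- stats::uniroot(function(t) tb(t) - limit,
                          lower = 0, upper = t_max, tol = 1e-10)$root
  out <- data.frame(direction = direction, ramp_rate = r,
                    start_temp = start_temp,
                    water_temp_at_loe = start_temp + sgn * r * t_loe,
                    mass = fish_mass, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(internal_limit = limit, k = k,
                             t_loe_min = t_loe)
  class(out) <- c("ct_trial", "data.frame")
  out
}

#' Generate a synthetic daily sea-surface-temperature series
#'
#' Daily SST is an annual sinusoid (peak in mid-August) plus Gaussian
#' noise. The `"ag"` preset (mean 27.25, amplitude 9.25) emulates a
#' thermally extreme basin with an annual range near 18.5 degC; the
#' `"go"` preset (mean 26.5, amplitude 5.5) a milder one near 11 degC.
#'
#' @param config a [synthetic_config()]; its `sst` block supplies mean,
#'   amplitude, noise SD and number of years unless a preset is chosen.
#' @param seed integer seed.
#' @param preset `NULL` (use the config), `"ag"` or `"go"`.
#' @param site site label.
#' @param start_year first calendar year of the series.
#'
#' @return A data frame of class `sst_series` with columns `site`, `date`,
#'   `sst_c`.
#' @export
generate_sst <- function(config, seed = config$seed, preset = NULL,
                         site = NULL, start_year = 2010) {
  pars <- config$sst
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("ag", "go"))
    pars[c("mean", "amplitude")] <-
      if (preset == "ag") c(27.25, 9.25) else c(26.5, 5.5)
    if (is.null(site)) site <- toupper(preset)
  }
  if (is.null(site)) site <- "site1"
  set.seed(seed)
  years <- as.integer(pars[["years"]])
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)),
               by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  sst <- pars[["mean"]] +
    pars[["amplitude"]] * cos(2 * pi * (doy - 227) / 365.25) +
    stats::rnorm(length(dates), 0, pars[["noise_sd"]])
  structure(data.frame(site = site, date = dates, sst_c = sst,
                       stringsAsFactors = FALSE),
            class = c("sst_series", "data.frame"))
}

#' Write pipeline tables as delimited text
#'
#' Plain CSV writers for the generator's outputs so traces, cohorts, CT
#' trials and SST series round-trip through the documented column dialect
#' (see the data dictionary in `inst/extdata/`).
#'
#' @param x a data frame (e.g. an `oxygen_trace` or cohort metadata).
#' @param path output file path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read an oxygen trace written by [write_table_csv()]
#'
#' @param path CSV file with columns `time_min, o2_mg_per_l, temp_c,
#'   phase, chamber_id`.
#' @return An `oxygen_trace` data frame.
#' @export
read_o2_trace <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "o2_mg_per_l", "temp_c", "phase", "chamber_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("trace file missing columns: ", paste(miss, collapse = ", "))
  class(x) <- c("oxygen_trace", "data.frame")
  x
}
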