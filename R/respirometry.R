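#' Segment an oxygen trace into measurement windows
#'
#' Splits an intermittent-flow trace into its closed-chamber measurement
#' phases. Phase labels take precedence; when absent, a cycle schedule
#' (measure then flush, repeating from time zero) assigns them. Windows
#' with fewer than `min_samples` samples are dropped with a warning.
#'
#' @param trace an `oxygen_trace` data frame (columns `time_min`,
#'   `o2_mg_per_l`, optionally `phase`).
#' @param schedule optional named vector `c(total, measure)` in minutes,
#'   used only when the trace has no usable phase labels.
#' @param min_samples minimum samples per retained window.
#'
#' @return A list of data frames (one per measurement window, in time
#'   order), each carrying attributes `cycle_index` and `cycle_start_time`.
#' @export
segment_cycles <- function(trace, schedule = NULL, min_samples = 2) {
  stopifnot(all(c("time_min", "o2_mg_per_l") %in% names(trace)))
  if (!"phase" %in% names(trace)) {
    if (is.null(schedule))
      stop("trace has no phase labels and no schedule was given")
    tc <- trace$time_min %% schedule[["total"]]
    trace$phase <- ifelse(tc < schedule[["measure"]], "measure", "flush")
  }
  if (!any(trace$phase == "measure"))
    stop("no measurement windows found in trace")
  runs <- rle(trace$phase == "measure")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  if (!length(keep)) stop("no measurement windows found in trace")
  windows <- lapply(keep, function(j) trace[starts[j]:ends[j], , drop = FALSE])
  sizes <- vapply(windows, nrow, integer(1))
  if (any(sizes < min_samples)) {
    warning(sum(sizes < min_samples),
            " measurement window(s) shorter than ", min_samples,
            " samples dropped")
    windows <- windows[sizes >= min_samples]
    if (!length(windows)) stop("no measurement windows found in trace")
  }
  for (i in seq_along(windows)) {
    attr(windows[[i]], "cycle_index") <- i
    attr(windows[[i]], "cycle_start_time") <- windows[[i]]$time_min[1]
  }
  windows
}

#' Ordinary least-squares oxygen-decline slope of one window
#'
#' @param window data frame with `time_min` and `o2_mg_per_l`.
#' @return A list with `slope` (mg O2 L-1 min-1), `r2`, and `n`. A window
#'   with zero oxygen variance returns slope 0 with `r2 = NA` (degenerate).
#' @export
fit_slope <- function(window) {
  x <- window$time_min
  y <- window$o2_mg_per_l
  n <- length(x)
  if (n < 2) stop("slope fit needs at least 2 samples")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (syy == 0) return(list(slope = 0, r2 = NA_real_, n = n))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, r2 = sxy^2 / (sxx * syy), n = n)
}

#' Convert an oxygen-decline slope to mass-specific oxygen uptake
#'
#' `mo2 = (-slope) * (chamber_volume - fish_mass/1000) * 60 / (fish_mass/1000)`
#' in mg O2 kg-1 h-1; the fish is assumed to displace its mass of water
#' (density 1 g/mL). Positive slopes (oxygen rising in a sealed chamber)
#' yield negative uptake values and should be flagged by the caller.
#'
#' @param slope oxygen slope (mg O2 L-1 min-1), negative for a respiring
#'   fish.
#' @param chamber_volume chamber volume (L).
#' @param fish_mass body mass (g). Set `displacement = FALSE` for
#'   empty-chamber (background) conversions, which use the full volume.
#' @param displacement subtract the fish's volume from the chamber volume?
#' @return mass-specific oxygen uptake (mg O2 kg-1 h-1).
#' @export
compute_mo2 <- function(slope, chamber_volume, fish_mass,
                        displacement = TRUE) {
  if (any(fish_mass <= 0)) stop("fish_mass must be positive")
  v_eff <- chamber_volume - if (displacement) fish_mass / 1000 else 0
  if (any(v_eff <= 0)) stop("fish volume exceeds chamber volume")
  (-slope) * v_eff * 60 / (fish_mass / 1000)
}

#' Extract a per-cycle oxygen-uptake series from a trace
#'
#' Segments the trace, fits one OLS slope per measurement window (a single
#' vectorised pass over all windows) and converts to mass-specific uptake.
#' Windows whose fit r2 falls below `r2_threshold` are flagged, never
#' dropped; positive slopes are flagged too.
#'
#' @inheritParams segment_cycles
#' @param chamber_volume chamber volume (L).
#' @param fish_mass body mass (g).
#' @param r2_threshold flag threshold on the slope-fit r2.
#'
#' @return A data frame of class `mo2_series` with columns `cycle_index`,
#'   `cycle_start_time`, `mo2`, `slope`, `slope_r2`, `flag_low_r2`,
#'   `flag_positive_slope`.
#' @export
extract_mo2_series <- function(trace, chamber_volume, fish_mass,
                               schedule = NULL, min_samples = 2,
                               r2_threshold = 0.9) {
  stopifnot(all(c("time_min", "o2_mg_per_l") %in% names(trace)))
  if (!"phase" %in% names(trace)) {
    if (is.null(schedule))
      stop("trace has no phase labels and no schedule was given")
    tc <- trace$time_min %% schedule[["total"]]
    trace$phase <- ifelse(tc < schedule[["measure"]], "measure", "flush")
  }
  meas <- trace$phase == "measure"
  if (!any(meas)) stop("no measurement windows found in trace")
  # label contiguous measure runs
  grp <- cumsum(c(1L, diff(meas) != 0))
  g <- grp[meas]
  x <- trace$time_min[meas]
  y <- trace$o2_mg_per_l[meas]
  f <- match(g, unique(g))
  n <- as.vector(rowsum(rep(1, length(x)), f))
  short <- n < min_samples
  if (any(short))
    warning(sum(short), " measurement window(s) shorter than ",
            min_samples, " samples dropped")
  sx <- as.vector(rowsum(x, f)); sy <- as.vector(rowsum(y, f))
  sxx <- as.vector(rowsum(x^2, f)); syy <- as.vector(rowsum(y^2, f))
  sxy <- as.vector(rowsum(x * y, f))
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  slope <- ifelse(vy == 0, 0, cxy / vx)
  r2 <- ifelse(vy == 0, NA_real_, cxy^2 / (vx * vy))
  start <- tapply(x, f, min)
  keep <- !short
  if (!any(keep)) stop("no measurement windows found in trace")
  out <- data.frame(
    cycle_index = seq_len(sum(keep)),
    cycle_start_time = as.vector(start)[keep],
    mo2 = compute_mo2(slope[keep], chamber_volume, fish_mass),
    slope = slope[keep],
    slope_r2 = r2[keep],
    stringsAsFactors = FALSE
  )
  out$flag_low_r2 <- !is.na(out$slope_r2) & out$slope_r2 < r2_threshold
  out$flag_positive_slope <- out$slope > 0
  class(out) <- c("mo2_series", "data.frame")
  out
}

#' Maximum metabolic rate from an uptake series
#'
#' MMR is the uptake of the first measurement cycle after the exhaustive
#' chase — the stated protocol rule — not the maximum over cycles. The
#' max-over-cycles alternative is available behind `use_max`.
#'
#' @param series an `mo2_series`.
#' @param use_max take the maximum over all cycles instead (default off).
#' @return `mmr_raw` (mg O2 kg-1 h-1).
#' @export
estimate_mmr <- function(series, use_max = FALSE) {
  if (!nrow(series)) stop("empty uptake series")
  if (use_max) return(max(series$mo2))
  series$mo2[which.min(series$cycle_index)]
}

#' Standard metabolic rate from an uptake series
#'
#' SMR is the `q` quantile (default the 20th percentile, linear
#' interpolation between order statistics) of per-cycle uptake over cycles
#' starting at or after `exclude_hours` (half-open: a cycle starting
#' exactly at the boundary is included). The alternative reading — the
#' mean of the lowest fraction `q` of values — is available via
#' `method = "mean_lowest"`.
#'
#' @param series an `mo2_series`.
#' @param exclude_hours hours excluded from the start of the trial, while
#'   post-exercise oxygen consumption is still elevated.
#' @param q quantile (or lowest fraction) used.
#' @param method `"quantile"` (default) or `"mean_lowest"`.
#' @param min_cycles minimum cycles required after exclusion.
#' @return `smr_raw` (mg O2 kg-1 h-1).
#' @export
estimate_smr <- function(series, exclude_hours = 5, q = 0.20,
                         method = c("quantile", "mean_lowest"),
                         min_cycles = 10) {
  method <- match.arg(method)
  keep <- series$cycle_start_time >= exclude_hours * 60
  x <- series$mo2[keep]
  if (length(x) < min_cycles)
    stop("only ", length(x), " cycles remain after excluding the first ",
         exclude_hours, " h (need >= ", min_cycles, ")")
  if (method == "quantile")
    stats::quantile(x, probs = q, type = 7, names = FALSE)
  else
    mean(sort(x)[seq_len(max(1L, ceiling(q * length(x))))])
}

#' Background-correct raw SMR and MMR
#'
#' Empty-chamber (microbial) oxygen-depletion slopes measured before and
#' after the trial are converted to the fish's mass-specific units using
#' the full chamber volume, then the pre-trial background is deducted from
#' MMR (measured at trial start) and the post-trial background from SMR
#' (measured overnight). Negative corrected values are flagged, not
#' dropped.
#'
#' @param mmr_raw,smr_raw raw trait values (mg O2 kg-1 h-1).
#' @param bg_pre_slope,bg_post_slope empty-chamber slopes
#'   (mg O2 L-1 min-1, negative for microbial consumption).
#' @param chamber_volume chamber volume (L).
#' @param fish_mass body mass (g).
#' @return A list with `mmr_corrected`, `smr_corrected`,
#'   `background_pre`, `background_post` (mass-specific equivalents) and
#'   `flag_negative`.
#' @export
correct_background <- function(mmr_raw, smr_raw, bg_pre_slope,
                               bg_post_slope, chamber_volume, fish_mass) {
  bg_pre <- compute_mo2(bg_pre_slope, chamber_volume, fish_mass,
                        displacement = FALSE)
  bg_post <- compute_mo2(bg_post_slope, chamber_volume, fish_mass,
                         displacement = FALSE)
  mmr_c <- mmr_raw - bg_pre
  smr_c <- smr_raw - bg_post
  list(mmr_corrected = mmr_c, smr_corrected = smr_c,
       background_pre = bg_pre, background_post = bg_post,
       flag_negative = (mmr_c < 0) | (smr_c < 0))
}

#' Aerobic scope
#'
#' The difference between background-corrected maximum and standard
#' metabolic rates. Negative scope (MMR below SMR, a protocol failure) is
#' flagged and retained.
#'
#' @param mmr_corrected,smr_corrected corrected traits (mg O2 kg-1 h-1).
#' @return Aerobic scope (mg O2 kg-1 h-1) with attribute `flag_negative`.
#' @export
aerobic_scope <- function(mmr_corrected, smr_corrected) {
  stopifnot(is.finite(mmr_corrected), is.finite(smr_corrected))
  as_ <- mmr_corrected - smr_corrected
  attr(as_, "flag_negative") <- as_ < 0
  as_
}

#' Full trait extraction for one fish
#'
#' Runs the whole respirometry chain on one trace: segment, slope-fit,
#' convert to mass-specific uptake, estimate MMR (first cycle) and SMR
#' (low quantile after the exclusion window), background-correct, and
#' compute aerobic scope.
#'
#' @inheritParams extract_mo2_series
#' @inheritParams estimate_smr
#' @param fish_id,species,region,acclimation_temp metadata copied into the
#'   output row.
#' @param bg_pre_slope,bg_post_slope empty-chamber slopes
#'   (mg O2 L-1 min-1).
#' @param use_max_mmr take MMR as the maximum cycle instead of the first.
#' @return A one-row data frame of class `metabolic_traits`.
#' @export
extract_traits <- function(trace, chamber_volume, fish_mass,
                           fish_id = "fish1", species = NA_character_,
                           region = NA_character_,
                           acclimation_temp = NA_real_,
                           bg_pre_slope = 0, bg_post_slope = 0,
                           schedule = NULL, exclude_hours = 5, q = 0.20,
                           method = "quantile", min_cycles = 10,
                           use_max_mmr = FALSE) {
  series <- extract_mo2_series(trace, chamber_volume, fish_mass,
                               schedule = schedule)
  mmr_raw <- estimate_mmr(series, use_max = use_max_mmr)
  smr_raw <- estimate_smr(series, exclude_hours = exclude_hours, q = q,
                          method = method, min_cycles = min_cycles)
  corr <- correct_background(mmr_raw, smr_raw, bg_pre_slope, bg_post_slope,
                             chamber_volume, fish_mass)
  as_ <- aerobic_scope(corr$mmr_corrected, corr$smr_corrected)
  out <- data.frame(
    fish_id = fish_id, species = species, region = region,
    acclimation_temp = acclimation_temp, mass = fish_mass,
    smr_raw = smr_raw, mmr_raw = mmr_raw,
    smr_corrected = corr$smr_corrected, mmr_corrected = corr$mmr_corrected,
    aerobic_scope = as.numeric(as_),
    background_pre = corr$background_pre,
    background_post = corr$background_post,
    flag_negative_scope = as.numeric(as_) < 0,
    flag_mmr_below_smr = corr$mmr_corrected < corr$smr_corrected,
    stringsAsFactors = FALSE
  )
  class(out) <- c("metabolic_traits", "data.frame")
  out
}

#' Extract traits for a whole synthetic cohort
#'
#' Convenience wrapper applying [extract_traits()] to every trace of a
#' [generate_cohort()] result (the cohort must have been generated with
#' `traces = TRUE`).
#'
#' @param cohort a `synthetic_cohort` with traces.
#' @param ... passed to [extract_traits()].
#' @return A `metabolic_traits` data frame, one row per fish, with the
#'   cohort's ground-truth columns merged in for recovery checks.
#' @export
extract_traits_cohort <- function(cohort, ...) {
  if (is.null(cohort$traces))
    stop("cohort was generated without traces; rerun with traces = TRUE")
  meta <- cohort$metadata
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    extract_traits(cohort$traces[[meta$fish_id[i]]],
                   chamber_volume = meta$chamber_volume[i],
                   fish_mass = meta$mass[i], fish_id = meta$fish_id[i],
                   species = meta$species[i], region = meta$region[i],
                   acclimation_temp = meta$acclimation_temp[i],
                   bg_pre_slope = meta$background_slope_pre[i],
                   bg_post_slope = meta$background_slope_post[i], ...)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, meta[, c("fish_id", "smr_true", "mmr_true", "as_true")],
               by = "fish_id", sort = FALSE)
  class(out) <- c("metabolic_traits", "data.frame")
  out
}
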