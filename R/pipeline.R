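#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable the downstream stages are allowed to see: the
#' per-region synthetic configurations (or input paths for user data),
#' the SMR estimator settings, the internal-temperature lag coefficients,
#' the regional seasonal acclimation map, and the statistics policy. The
#' config is serialised into every output directory so a run can be
#' reproduced from its manifest.
#'
#' @param seed master integer seed.
#' @param regions named list of [synthetic_config()] objects, one per
#'   region. The defaults emulate a hot-basin ("AG") population measured
#'   at 18-35.5 degC and a milder ("GO") one without the 35.5 degC cell,
#'   with identical physiology apart from the sea-surface-temperature
#'   climate (a null scenario for regional trait tests).
#' @param seasonal_map named list giving each region's winter and summer
#'   acclimation temperatures (degC).
#' @param q,exclude_hours SMR estimator settings (see [estimate_smr()]).
#' @param lag_k0,lag_gamma internal-temperature lag coefficients.
#' @param stats_policy `"auto"`, `"lm"` or `"permanova"`.
#' @param n_perm permutations for the PERMANOVA path.
#' @param out_dir optional output directory; `NULL` keeps results in
#'   memory only.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       regions = list(
                         AG = synthetic_config(
                           region_label = "AG",
                           acclimation_temps = c(18, 22, 27, 31.5, 35.5)),
                         GO = synthetic_config(
                           region_label = "GO",
                           acclimation_temps = c(18, 22, 27, 31.5))),
                       seasonal_map = list(
                         AG = c(winter = 18, summer = 35.5),
                         GO = c(winter = 22, summer = 31.5)),
                       q = 0.20, exclude_hours = 5,
                       lag_k0 = 1.2, lag_gamma = 0.33,
                       stats_policy = "auto", n_perm = 999,
                       out_dir = NULL) {
  stopifnot(identical(sort(names(regions)), sort(names(seasonal_map))))
  structure(list(seed = as.integer(seed), regions = regions,
                 seasonal_map = seasonal_map, q = q,
                 exclude_hours = exclude_hours, lag_k0 = lag_k0,
                 lag_gamma = lag_gamma, stats_policy = stats_policy,
                 n_perm = n_perm, out_dir = out_dir),
            class = "run_config")
}

# stable md5 of a serialised object (version-pinned serialisation)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Summarise thermal safety margins by species, region and season
#'
#' Computes per-cell means and standard errors, the per-species regional
#' gap (mild-region mean minus hot-region mean), the cross-species mean
#' gap as the unweighted mean of the per-species gaps, and the
#' cross-species seasonal grand mean per region as the unweighted mean of
#' the per-species means. Unweighted averaging of per-species summaries
#' (rather than pooling individuals) is deliberate: it gives every
#' species the same voice regardless of sample size.
#'
#' @param records data frame with columns `species`, `region`, `season`
#'   and `margin` (one row per fish; cells holding a single summary value
#'   are accepted, their SE is `NA`).
#' @param region_order `c(hot, mild)`: the gap is `mild - hot`.
#' @return A list with `cells` (per species x region x season mean, SE,
#'   n), `gaps` (per species x season), and `seasonal` (per season: mean
#'   gap and per-region grand means).
#' @export
summarize_tsm <- function(records, region_order = c("AG", "GO")) {
  stopifnot(all(c("species", "region", "season", "margin") %in%
                  names(records)),
            all(region_order %in% records$region))
  agg <- stats::aggregate(margin ~ species + region + season,
                          data = records,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  cells <- data.frame(agg[c("species", "region", "season")],
                      mean = agg$margin[, "mean"],
                      se = agg$margin[, "sd"] / sqrt(agg$margin[, "n"]),
                      n = agg$margin[, "n"])
  hot <- region_order[1]; mild <- region_order[2]
  gaps <- list(); seasonal <- list()
  for (season in unique(cells$season)) {
    cs <- cells[cells$season == season, ]
    sp <- intersect(cs$species[cs$region == hot],
                    cs$species[cs$region == mild])
    if (!length(sp)) next
    hot_means <- vapply(sp, function(s)
      cs$mean[cs$species == s & cs$region == hot], numeric(1))
    mild_means <- vapply(sp, function(s)
      cs$mean[cs$species == s & cs$region == mild], numeric(1))
    gaps[[season]] <- data.frame(species = sp, season = season,
                                 hot_mean = hot_means,
                                 mild_mean = mild_means,
                                 gap = mild_means - hot_means,
                                 stringsAsFactors = FALSE)
    seasonal[[season]] <- data.frame(
      season = season, mean_gap = mean(mild_means - hot_means),
      grand_mean_hot = mean(hot_means),
      grand_mean_mild = mean(mild_means), stringsAsFactors = FALSE)
  }
  list(cells = cells, gaps = do.call(rbind, unname(gaps)),
       seasonal = do.call(rbind, unname(seasonal)))
}

#' Run the full synthetic-to-comparison pipeline
#'
#' Executes every stage in order on seeded synthetic inputs: cohort
#' generation with oxygen traces per region, respirometry trait
#' extraction, allometric mass adjustment, thermal performance curve and
#' Q10 fitting per region, critical-thermal-limit trials with internal
#' temperature lag, sea-surface-temperature extremes and thermal safety
#' margins, the TSM summary, and regional comparisons at shared
#' acclimation temperatures. Stage failures are logged and skipped
#' without aborting unrelated stages. When `config$out_dir` is set, all
#' tables plus a manifest (seed, config hash, package version) are
#' written as delimited text.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_result` with elements `traits`,
#'   `scaling`, `tpc_fits`, `q10`, `ct_trials`, `tsm_records`,
#'   `tsm_summary`, `comparisons`, `env`, `manifest`, and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      note("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }
  regions <- names(config$regions)

  # 1. cohorts with traces, trait extraction
  traits <- stage("traits", {
    rows <- lapply(seq_along(regions), function(i) {
      rg <- regions[i]
      cohort <- generate_cohort(config$regions[[rg]],
                                seed = config$seed + i, traces = TRUE)
      extract_traits_cohort(cohort, exclude_hours = config$exclude_hours,
                            q = config$q)
    })
    do.call(rbind, rows)
  })
  if (is.null(traits) || !nrow(traits)) stop("no traits extracted")
  note("extracted traits for ", nrow(traits), " fish")

  # 2. allometric mass adjustment
  adj <- stage("mass_adjust", mass_adjust_traits(traits))
  if (!is.null(adj)) traits <- adj$traits

  # 3. TPC fits and Q10 per region
  tpc_fits <- stage("tpc", {
    fits <- list()
    for (rg in regions) {
      sel <- traits$region == rg
      fits[[paste0(rg, "_SMR")]] <-
        fit_exponential(traits$acclimation_temp[sel], traits$smr_adj[sel])
      fits[[paste0(rg, "_MMR")]] <-
        fit_poly2(traits$acclimation_temp[sel], traits$mmr_adj[sel])
      fits[[paste0(rg, "_AS")]] <-
        fit_gaussian(traits$acclimation_temp[sel], traits$as_adj[sel])
    }
    fits
  })
  q10_tab <- stage("q10", q10_table(traits, t1 = 22, t2 = 31.5))

  # 4. SST, environmental extremes
  env <- stage("environment", {
    lapply(seq_along(regions), function(i) {
      rg <- regions[i]
      sst <- generate_sst(config$regions[[rg]], seed = config$seed + 100 + i,
                          preset = tolower(rg), site = rg)
      list(sst = sst, extremes = env_extremes(sst),
           annual = annual_stats(sst))
    }) |> stats::setNames(regions)
  })

  # 5. CT trials at seasonal acclimation temps, TSM records
  set.seed(config$seed + 500)
  tsm <- stage("tsm", {
    recs <- list(); trials <- list()
    for (rg in regions) {
      smap <- config$seasonal_map[[rg]]
      scfg <- config$regions[[rg]]
      ext <- env[[rg]]$extremes
      for (season in c("summer", "winter")) {
        direction <- if (season == "summer") "max" else "min"
        start_temp <- smap[[season]]
        extreme <- if (season == "summer") ext$mean_annual_max
                   else ext$mean_annual_min
        for (j in seq_len(scfg$n_fish_per_cell)) {
          mass <- stats::rlnorm(1, scfg$mass_log_mean, scfg$mass_log_sd)
          tr <- generate_ct_trial(scfg, mass, direction = direction,
                                  start_temp = start_temp)
          cl <- internal_temp_at_loe(tr$water_temp_at_loe, tr$start_temp,
                                     tr$ramp_rate, tr$mass,
                                     lag_k0 = config$lag_k0,
                                     lag_gamma = config$lag_gamma)
          fid <- sprintf("%s_%s_%s_%02d", scfg$species_label, rg, season, j)
          trials[[fid]] <- data.frame(fish_id = fid,
                                      species = scfg$species_label,
                                      region = rg, season = season,
                                      tr, critical_limit = cl,
                                      stringsAsFactors = FALSE)
          recs[[fid]] <- data.frame(
            fish_id = fid, species = scfg$species_label, region = rg,
            season = season, critical_limit = cl,
            environmental_extreme = extreme,
            margin = thermal_safety_margin(cl, extreme, season),
            stringsAsFactors = FALSE)
        }
      }
    }
    list(trials = do.call(rbind, unname(trials)),
         records = do.call(rbind, unname(recs)))
  })
  tsm_summary <- if (!is.null(tsm))
    stage("tsm_summary", summarize_tsm(tsm$records,
                                       region_order = regions[1:2]))

  # 6. regional comparisons at shared temperatures only
  comparisons <- stage("comparisons", {
    shared <- Reduce(intersect, lapply(config$regions,
                                       function(cfg) cfg$acclimation_temps))
    missing_cells <- setdiff(
      unique(unlist(lapply(config$regions,
                           function(cfg) cfg$acclimation_temps))), shared)
    if (length(missing_cells))
      note("temperatures not shared across regions excluded from ",
           "comparisons: ", paste(missing_cells, collapse = ", "))
    sub <- traits[traits$acclimation_temp %in% shared, ]
    out <- list()
    for (col in c("smr_adj", "mmr_adj", "as_adj")) {
      out[[col]] <- compare_traits(sub, col,
                                   temperature = "acclimation_temp",
                                   region = "region",
                                   policy = config$stats_policy,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 900)
    }
    # regional TSM t-tests per season
    if (!is.null(tsm)) {
      for (season in c("summer", "winter")) {
        r <- tsm$records[tsm$records$season == season, ]
        out[[paste0("tsm_", season)]] <-
          two_sample_test(r$margin[r$region == regions[1]],
                          r$margin[r$region == regions[2]])
      }
    }
    out
  })

  manifest <- list(package_version = as.character(
                     utils::packageVersion("thermoscope")),
                   seed = config$seed, config_hash = config_hash(
                     config[setdiff(names(config), "out_dir")]),
                   timestamp = NA)  # timestamp excluded from hash & identity
  res <- structure(list(traits = traits,
                        scaling = if (!is.null(adj)) adj$scaling,
                        tpc_fits = tpc_fits, q10 = q10_tab,
                        ct_trials = if (!is.null(tsm)) tsm$trials,
                        tsm_records = if (!is.null(tsm)) tsm$records,
                        tsm_summary = tsm_summary,
                        comparisons = comparisons, env = env,
                        manifest = manifest, log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$traits), "fish;",
      length(x$tpc_fits), "TPC fits;",
      if (!is.null(x$tsm_records)) nrow(x$tsm_records) else 0,
      "TSM records\n")
  if (!is.null(x$tsm_summary$seasonal)) {
    print(x$tsm_summary$seasonal)
  }
  invisible(x)
}

# write all tables + manifest as delimited text
write_pipeline_result <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x))
      write_table_csv(x, file.path(config$out_dir, paste0(name, ".csv")))
  }
  w(res$traits, "traits")
  w(res$scaling, "scaling_fits")
  w(res$q10, "q10")
  w(res$ct_trials, "ct_trials")
  w(res$tsm_records, "tsm_records")
  if (!is.null(res$tsm_summary)) {
    w(res$tsm_summary$cells, "tsm_cells")
    w(res$tsm_summary$gaps, "tsm_gaps")
    w(res$tsm_summary$seasonal, "tsm_seasonal")
  }
  man <- res$manifest
  writeLines(c(paste0("package_version: ", man$package_version),
               paste0("seed: ", man$seed),
               paste0("config_hash: ", man$config_hash)),
             file.path(config$out_dir, "manifest.txt"))
  writeLines(res$log, file.path(config$out_dir, "run_log.txt"))
  invisible(config$out_dir)
}
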