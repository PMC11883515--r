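#' Fit the allometric mass-scaling of a metabolic trait
#'
#' Regresses log10(trait) on log10(body mass), pooling regions and
#' acclimation temperatures within one species x trait, and records the
#' arithmetic mean mass of the included fish — the pivot to which values
#' are later adjusted. Non-positive trait values cannot be log-transformed
#' and are excluded with a warning.
#'
#' @param values trait values (mg O2 kg-1 h-1), same length as `masses`.
#' @param masses body masses (g).
#' @param species,trait labels stored in the fit ("SMR", "MMR" or "AS").
#'   Critical thermal limits are absolute temperatures and must never be
#'   mass-scaled; passing `trait` matching "ct" is an error.
#' @param log_space fit in log10-log10 space (default); `FALSE` fits a
#'   linear-space power law via the same OLS on untransformed values and
#'   is provided for sensitivity only.
#'
#' @return An object of class `scaling_fit`: list with `species`, `trait`,
#'   `exponent_b`, `intercept_log10a`, `r2`, `mean_mass`, `n`.
#' @export
fit_mass_scaling <- function(values, masses, species = NA_character_,
                             trait = NA_character_, log_space = TRUE) {
  stopifnot(length(values) == length(masses))
  if (!is.na(trait) && grepl("^ct", tolower(trait)))
    stop("critical thermal limits are not mass-scaled")
  ok <- is.finite(values) & is.finite(masses) & masses > 0
  if (any(ok & values <= 0)) {
    warning(sum(ok & values <= 0),
            " non-positive trait value(s) excluded before log transform")
    ok <- ok & values > 0
  }
  v <- values[ok]; m <- masses[ok]
  if (length(unique(m)) < 3)
    stop("need at least 3 distinct body masses")
  if (stats::var(m) == 0) stop("all masses identical; exponent undefined")
  fit <- if (log_space) stats::lm(log10(v) ~ log10(m))
         else stats::lm(v ~ m)
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  resp <- if (log_space) log10(v) else v
  sst <- sum((resp - mean(resp))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(species = species, trait = trait, exponent_b = b,
                 intercept_log10a = a, r2 = r2,
                 mean_mass = mean(m), n = length(v),
                 log_space = log_space),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("<scaling_fit> ", x$species, " ", x$trait,
      ": b = ", signif(x$exponent_b, 4),
      ", r2 = ", signif(x$r2, 3),
      ", mean mass = ", signif(x$mean_mass, 4), " g (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Adjust a trait value to the species' mean body mass
#'
#' `adjusted = value * (mean_mass / mass)^exponent_b`, removing the fitted
#' mass dependence so fish of different sizes become comparable at the
#' common pivot mass. At `mass == mean_mass` the value is unchanged; with
#' `exponent_b == 0` all values are unchanged.
#'
#' @param value trait value(s).
#' @param mass body mass(es) (g), positive.
#' @param fit a [fit_mass_scaling()] result.
#' @return Adjusted value(s).
#' @export
adjust_to_mean_mass <- function(value, mass, fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (any(mass <= 0)) stop("mass must be positive")
  value * (fit$mean_mass / mass)^fit$exponent_b
}

#' Mass-adjust all metabolic traits of a trait table
#'
#' For each species x trait (SMR, MMR, AS), fits the pooled mass scaling
#' and appends mass-adjusted columns (`smr_adj`, `mmr_adj`, `as_adj`).
#' Critical thermal limits never pass through here.
#'
#' @param traits a `metabolic_traits` data frame (needs `species`, `mass`
#'   and the corrected trait columns).
#' @param columns named character vector mapping trait labels to columns.
#' @return A list with `traits` (the input plus adjusted columns) and
#'   `scaling` (a data frame of the fits, one row per species x trait).
#' @export
mass_adjust_traits <- function(traits,
                               columns = c(SMR = "smr_corrected",
                                           MMR = "mmr_corrected",
                                           AS = "aerobic_scope")) {
  stopifnot(all(c("species", "mass") %in% names(traits)),
            all(columns %in% names(traits)))
  out <- traits
  adj_cols <- c(SMR = "smr_adj", MMR = "mmr_adj", AS = "as_adj")
  fits <- list()
  for (sp in unique(traits$species)) {
    sel <- traits$species == sp
    for (tr in names(columns)) {
      fit <- fit_mass_scaling(traits[[columns[[tr]]]][sel],
                              traits$mass[sel], species = sp, trait = tr)
      out[[adj_cols[[tr]]]][sel] <-
        adjust_to_mean_mass(traits[[columns[[tr]]]][sel],
                            traits$mass[sel], fit)
      fits[[paste(sp, tr)]] <-
        data.frame(species = sp, trait = tr, exponent_b = fit$exponent_b,
                   intercept_log10a = fit$intercept_log10a, r2 = fit$r2,
                   mean_mass = fit$mean_mass, n = fit$n,
                   stringsAsFactors = FALSE)
    }
  }
  list(traits = out, scaling = do.call(rbind, unname(fits)))
}
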