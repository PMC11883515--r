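new_tpc_fit <- function(trait, model, params, r2, n, converged,
                        notes = character()) {
  structure(list(trait = trait, model = model, params = params, r2 = r2,
                 n = n, converged = converged, notes = notes),
            class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("<tpc_fit> ", x$trait, " ~ ", x$model, ": ",
      paste(names(x$params), signif(unlist(x$params), 5), sep = " = ",
            collapse = ", "),
      "; r2 = ", signif(x$r2, 3), ", n = ", x$n,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Predicted trait values from a fitted thermal performance curve
#'
#' @param object a `tpc_fit`.
#' @param temps temperatures (degC) at which to evaluate the curve.
#' @param ... unused.
#' @return Predicted trait values.
#' @export
predict.tpc_fit <- function(object, temps, ...) {
  p <- object$params
  switch(object$model,
         exponential = p$a * exp(p$b * temps),
         poly2 = p$c0 + p$c1 * temps + p$c2 * temps^2,
         gaussian = p$amplitude *
           exp(-(temps - p$topt)^2 / (2 * p$breadth_sd^2)),
         stop("unknown model: ", object$model))
}

#' Minimal diagnostic plot of a thermal performance curve fit
#'
#' @param x a `tpc_fit`.
#' @param temps,values the data that were fitted.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tpc_fit <- function(x, temps, values, ...) {
  graphics::plot(temps, values, xlab = "Temperature (degC)",
                 ylab = x$trait, ...)
  tt <- seq(min(temps), max(temps), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

r2_original_scale <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(if (all(abs(obs - pred) < 1e-12)) 1 else NA_real_)
  1 - sum((obs - pred)^2) / sst
}

check_tpc_input <- function(temps, values, min_distinct) {
  stopifnot(length(temps) == length(values))
  ok <- is.finite(temps) & is.finite(values)
  if (!all(ok)) {
    warning(sum(!ok), " non-finite point(s) dropped")
  }
  if (length(unique(temps[ok])) < min_distinct)
    stop("need at least ", min_distinct, " distinct temperatures")
  list(temps = temps[ok], values = values[ok])
}

#' Fit an exponential thermal performance curve
#'
#' Fits `value = a * exp(b * T)` by nonlinear least squares, initialised
#' from the log-linear OLS solution (which requires positive values). If
#' the log-linear solution already fits exactly it is returned as-is;
#' otherwise the optimiser refines it, with up to `restarts` jittered
#' restarts before flagging non-convergence. r2 is reported on the
#' original scale and can be negative.
#'
#' @param temps temperatures (degC), at least 3 distinct.
#' @param values positive trait values.
#' @param trait label stored in the fit.
#' @param restarts jittered restarts after an optimiser failure.
#' @return A `tpc_fit` with params `a`, `b`.
#' @export
fit_exponential <- function(temps, values, trait = "SMR", restarts = 5) {
  d <- check_tpc_input(temps, values, 3)
  if (any(d$values <= 0)) stop("exponential fit requires positive values")
  init_fit <- stats::lm(log(d$values) ~ d$temps)
  start <- list(a = exp(unname(stats::coef(init_fit)[1])),
                b = unname(stats::coef(init_fit)[2]))
  pred0 <- start$a * exp(start$b * d$temps)
  if (sum((d$values - pred0)^2) < 1e-18 * sum(d$values^2)) {
    return(new_tpc_fit(trait, "exponential", start, 1, length(d$values),
                       TRUE, "exact log-linear solution"))
  }
  df <- data.frame(T = d$temps, v = d$values)
  fit <- NULL
  for (i in 0:restarts) {
    st <- if (i == 0) start else
      lapply(start, function(p) p * exp(stats::runif(1, -0.2, 0.2)))
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ a * exp(b * T), data = df, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(new_tpc_fit(trait, "exponential", start,
                       r2_original_scale(d$values, pred0),
                       length(d$values), FALSE,
                       "optimiser failed; log-linear initialisation reported"))
  }
  p <- as.list(stats::coef(fit))
  new_tpc_fit(trait, "exponential", p,
              r2_original_scale(d$values, p$a * exp(p$b * d$temps)),
              length(d$values), TRUE)
}

#' Fit a second-order polynomial thermal performance curve
#'
#' Exact closed-form OLS quadratic `value = c0 + c1 T + c2 T^2`, the
#' standard description of a dome-shaped maximum-metabolic-rate curve.
#' The vertex (temperature of the extremum and its value) is reported
#' when the curvature is non-zero.
#'
#' @inheritParams fit_exponential
#' @return A `tpc_fit` with params `c0`, `c1`, `c2` and (when defined)
#'   `vertex_temp`, `vertex_value`.
#' @export
fit_poly2 <- function(temps, values, trait = "MMR") {
  d <- check_tpc_input(temps, values, 3)
  fit <- stats::lm(d$values ~ d$temps + I(d$temps^2))
  if (anyNA(stats::coef(fit))) stop("rank-deficient quadratic design")
  cf <- unname(stats::coef(fit))
  p <- list(c0 = cf[1], c1 = cf[2], c2 = cf[3])
  if (abs(p$c2) > 0) {
    p$vertex_temp <- -p$c1 / (2 * p$c2)
    p$vertex_value <- p$c0 - p$c1^2 / (4 * p$c2)
  }
  new_tpc_fit(trait, "poly2", p,
              r2_original_scale(d$values, stats::fitted(fit)),
              length(d$values), TRUE)
}

#' Fit a Gaussian thermal performance curve
#'
#' Fits `value = amplitude * exp(-(T - topt)^2 / (2 breadth_sd^2))`, the
#' standard dome for aerobic scope, by bounded nonlinear least squares.
#' Initialisation: `topt` at the temperature with the largest binned mean,
#' `amplitude` at that mean, `breadth_sd` at half the temperature span.
#' Bounds: `breadth_sd` in (0, 50], `topt` within the span +/- 10 degC.
#' A fit ending on a bound, or failing after jittered restarts, is
#' flagged unconverged — never silently reported. With exactly three
#' distinct temperatures the three-parameter fit is an interpolation and
#' is flagged as exact.
#'
#' @inheritParams fit_exponential
#' @return A `tpc_fit` with params `amplitude`, `topt`, `breadth_sd`.
#' @export
fit_gaussian <- function(temps, values, trait = "AS", restarts = 5) {
  d <- check_tpc_input(temps, values, 3)
  n_distinct <- length(unique(d$temps))
  binned <- tapply(d$values, d$temps, mean)
  bin_t <- as.numeric(names(binned))
  span <- diff(range(d$temps))
  start <- list(amplitude = max(binned),
                topt = bin_t[which.max(binned)],
                breadth_sd = max(span / 2, 1))
  lower <- c(amplitude = 1e-9, topt = min(d$temps) - 10,
             breadth_sd = 1e-6)
  upper <- c(amplitude = Inf, topt = max(d$temps) + 10, breadth_sd = 50)
  df <- data.frame(T = d$temps, v = d$values)
  fit <- NULL
  for (i in 0:restarts) {
    st <- if (i == 0) start else list(
      amplitude = start$amplitude * exp(stats::runif(1, -0.2, 0.2)),
      topt = start$topt + stats::runif(1, -2, 2),
      breadth_sd = start$breadth_sd * exp(stats::runif(1, -0.3, 0.3)))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ amplitude * exp(-(T - topt)^2 / (2 * breadth_sd^2)),
        data = df, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  notes <- character()
  if (n_distinct == 3) notes <- c(notes, "exact 3-point interpolation")
  if (is.null(fit)) {
    return(new_tpc_fit(trait, "gaussian", start, NA_real_,
                       length(d$values), FALSE,
                       c(notes, "optimiser failed after restarts")))
  }
  p <- as.list(stats::coef(fit))
  at_bound <- p$breadth_sd >= upper[["breadth_sd"]] - 1e-6 ||
    p$breadth_sd <= lower[["breadth_sd"]] + 1e-6 ||
    p$topt <= lower[["topt"]] + 1e-6 || p$topt >= upper[["topt"]] - 1e-6
  if (at_bound) notes <- c(notes, "parameter at bound")
  new_tpc_fit(trait, "gaussian", p,
              r2_original_scale(d$values, predict(
                new_tpc_fit(trait, "gaussian", p, NA, 0, TRUE), d$temps)),
              length(d$values), converged = !at_bound, notes)
}

#' Fit a thermal performance curve of a chosen family
#'
#' Dispatcher over [fit_exponential()] (SMR), [fit_poly2()] (MMR) and
#' [fit_gaussian()] (aerobic scope).
#'
#' @inheritParams fit_exponential
#' @param model `"exponential"`, `"poly2"` or `"gaussian"`.
#' @param group_means fit on temperature-group means rather than
#'   individual fish values (figure-reproduction mode).
#' @param ... passed to the underlying fitter (e.g. `restarts`).
#' @return A `tpc_fit`.
#' @export
fit_tpc <- function(temps, values,
                    model = c("gaussian", "exponential", "poly2"),
                    trait = NULL, group_means = FALSE, ...) {
  model <- match.arg(model)
  if (group_means) {
    mm <- tapply(values, temps, mean)
    temps <- as.numeric(names(mm))
    values <- as.numeric(mm)
  }
  if (is.null(trait))
    trait <- switch(model, exponential = "SMR", poly2 = "MMR",
                    gaussian = "AS")
  switch(model,
         exponential = fit_exponential(temps, values, trait, ...),
         poly2 = fit_poly2(temps, values, trait),
         gaussian = fit_gaussian(temps, values, trait, ...))
}

#' Q10 temperature coefficient
#'
#' The factor by which a rate changes per 10 degC:
#' `q10 = (r2/r1)^(10/(t2 - t1))`, oriented so that `t2 > t1` (inputs are
#' swapped internally if given in the other order).
#'
#' @param r1,r2 rates at temperatures `t1`, `t2`; must be positive.
#' @param t1,t2 temperatures (degC); must differ.
#' @return The dimensionless Q10. Vectorised.
#' @export
q10 <- function(r1, r2, t1, t2) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("rates must be positive")
  if (any(t1 == t2)) stop("temperatures must differ")
  swap <- t1 > t2
  if (any(swap)) {
    tmp_r <- r1; tmp_t <- t1
    r1 <- ifelse(swap, r2, r1); t1 <- ifelse(swap, t2, t1)
    r2 <- ifelse(swap, tmp_r, r2); t2 <- ifelse(swap, tmp_t, t2)
  }
  (r2 / r1)^(10 / (t2 - t1))
}

#' Q10 between two temperatures from a fitted curve
#'
#' @param fit a `tpc_fit`.
#' @param t1,t2 temperatures (degC).
#' @return Q10 computed from the fitted curve's predicted rates.
#' @export
q10_from_fit <- function(fit, t1, t2) {
  q10(predict(fit, t1), predict(fit, t2), t1, t2)
}

#' Q10 table from group-mean trait values
#'
#' Computes Q10 for each species x region x trait between two acclimation
#' temperatures, using group-mean trait values at those temperatures (the
#' default comparison over a commonly experienced range).
#'
#' @param traits trait table with `species`, `region`,
#'   `acclimation_temp` and trait value columns.
#' @param t1,t2 the two acclimation temperatures compared.
#' @param columns named vector mapping trait labels to columns.
#' @return Data frame with one row per species x region x trait.
#' @export
q10_table <- function(traits, t1 = 22, t2 = 31.5,
                      columns = c(SMR = "smr_adj", MMR = "mmr_adj",
                                  AS = "as_adj")) {
  cells <- unique(traits[, c("species", "region")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- traits$species == cells$species[i] &
      traits$region == cells$region[i]
    for (tr in names(columns)) {
      v1 <- traits[[columns[[tr]]]][sel & traits$acclimation_temp == t1]
      v2 <- traits[[columns[[tr]]]][sel & traits$acclimation_temp == t2]
      if (!length(v1) || !length(v2)) next
      m1 <- mean(v1); m2 <- mean(v2)
      if (m1 <= 0 || m2 <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = cells$species[i], region = cells$region[i], trait = tr,
        t1 = t1, t2 = t2, rate1 = m1, rate2 = m2,
        q10 = q10(m1, m2, t1, t2), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
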