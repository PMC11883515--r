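#' Shapiro-Wilk normality gate
#'
#' Tests a sample (typically model residuals) for normality and reports
#' whether it passes at the conventional 0.05 level, the gate used to
#' decide between the parametric and permutation analysis paths.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @param alpha gate level.
#' @return A list with `W`, `p` and `pass` (`p > alpha`).
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", n, ")")
  if (stats::var(x) == 0) stop("sample has zero variance")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, pass = sw$p.value > alpha)
}

#' Tukey ladder-of-powers transformation
#'
#' Searches the classic ladder lambda in \{-2, -1, -0.5, 0, 0.5, 1, 2\}
#' (0 means log; negative powers are negated to preserve order) and picks
#' the power whose transformed sample has the largest Shapiro-Wilk W.
#' Exact ties break toward lambda = 1 (no transformation). Samples with a
#' non-positive minimum are shifted by `1 - min(y)` first, and the shift
#' is recorded.
#'
#' @param y numeric sample.
#' @param grid candidate powers.
#' @return A list with `lambda`, `y_trans`, `shift`, and `W_table`.
#' @export
tukey_ladder <- function(y, grid = c(-2, -1, -0.5, 0, 0.5, 1, 2)) {
  y <- y[is.finite(y)]
  shift <- if (min(y) <= 0) 1 - min(y) else 0
  ys <- y + shift
  apply_power <- function(l) {
    if (l == 0) log(ys)
    else if (l > 0) ys^l
    else -(ys^l)
  }
  W <- vapply(grid, function(l) {
    z <- apply_power(l)
    if (!all(is.finite(z)) || stats::var(z) == 0) return(-Inf)
    unname(stats::shapiro.test(z)$statistic)
  }, numeric(1))
  best <- max(W)
  lambda <- if (any(grid == 1 & W == best)) 1 else grid[which.max(W)]
  list(lambda = lambda, y_trans = apply_power(lambda), shift = shift,
       W_table = data.frame(lambda = grid, W = W))
}

#' Factorial linear model with ANOVA table
#'
#' Fits `response ~ temperature * region` (plus an optional covariate,
#' used for critical thermal limits where body mass enters the model
#' instead of being scaled out) and returns the Type-II ANOVA table by
#' default. If any temperature x region cell is empty the interaction is
#' inestimable and is dropped with a warning.
#'
#' @param data data frame.
#' @param response name of the response column.
#' @param temperature,region names of the factor columns (coerced to
#'   factors).
#' @param covariate optional name of a numeric covariate (e.g. mass).
#' @param ss_type `"II"` (default) or `"I"` sums of squares.
#' @return A list with `model` (the `lm`), `anova` (the table),
#'   `coefficients` and `note`.
#' @export
linear_model_anova <- function(data, response, temperature = "temperature",
                               region = "region", covariate = NULL,
                               ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  d <- data
  d[[temperature]] <- factor(d[[temperature]])
  d[[region]] <- factor(d[[region]])
  if (nlevels(d[[temperature]]) < 2 || nlevels(d[[region]]) < 2)
    stop("each factor needs at least 2 levels present")
  note <- character()
  cells <- table(d[[temperature]], d[[region]])
  rhs <- paste(temperature, "*", region)
  if (any(cells == 0)) {
    warning("empty temperature x region cell(s): interaction dropped")
    rhs <- paste(temperature, "+", region)
    note <- "interaction dropped (empty cells)"
  }
  if (!is.null(covariate)) rhs <- paste(rhs, "+", covariate)
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = d)
  tab <- if (ss_type == "II") car::Anova(fit, type = 2)
         else stats::anova(fit)
  list(model = fit, anova = tab,
       coefficients = summary(fit)$coefficients, note = note)
}

# Gower-centred inner-product matrix of squared Euclidean distances;
# tr(H G) partitions the among-group sum of squares (McArdle & Anderson).
gower_G <- function(y) {
  y <- as.matrix(y)
  d2 <- as.matrix(stats::dist(y))^2
  n <- nrow(d2)
  cm <- diag(n) - matrix(1 / n, n, n)
  -0.5 * cm %*% d2 %*% cm
}

# sequential hat matrices for a list of term-wise design columns
seq_hats <- function(blocks, n) {
  hats <- list()
  X <- matrix(1, n, 1)
  h_prev <- X %*% solve(crossprod(X)) %*% t(X)
  ranks <- integer(0)
  for (b in blocks) {
    X <- cbind(X, b)
    qx <- qr(X)
    Xr <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    h <- Xr %*% solve(crossprod(Xr)) %*% t(Xr)
    hats[[length(hats) + 1L]] <- h - h_prev
    ranks <- c(ranks, qx$rank - sum(ranks) - 1L)
    h_prev <- h
  }
  list(deltas = hats, h_full = h_prev, ranks = ranks)
}

#' Permutational (multivariate) analysis of variance
#'
#' A from-scratch PERMANOVA on Euclidean distances: the total sum of
#' squared distances is partitioned by sequentially added model terms, a
#' pseudo-F is formed against the residual, and its null distribution is
#' obtained by unrestricted permutation of the observations. The p value
#' is `(1 + #\{permuted F >= observed F\}) / (1 + n_perm)`. For a
#' univariate response the one-way pseudo-F is numerically identical to
#' the classical ANOVA F.
#'
#' @param response numeric vector or matrix (rows = observations).
#' @param factors a single grouping vector/factor, or a data frame of
#'   factors; with two or more factors, main effects are entered in
#'   column order followed by the full interaction (sequential SS).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param exact for a one-way two-group design only: enumerate all
#'   distinct group assignments instead of sampling; the p value is the
#'   fraction of all assignments (including the observed one) with
#'   `F >= observed`.
#' @return A data frame of class `permanova_fit` with one row per term
#'   plus residual and total; attributes record `n_perm`, `seed` and the
#'   permutation scheme.
#' @export
permanova <- function(response, factors, n_perm = 9999, seed = NULL,
                      exact = FALSE) {
  y <- as.matrix(response)
  n <- nrow(y)
  if (is.data.frame(factors)) {
    fl <- lapply(factors, factor)
  } else {
    fl <- list(group = factor(factors))
  }
  if (any(vapply(fl, nlevels, integer(1)) < 2))
    stop("every factor needs at least 2 levels")
  stopifnot(all(vapply(fl, length, integer(1)) == n))
  G <- gower_G(y)
  ss_total <- sum(diag(G))
  if (ss_total < 1e-12)
    stop("all observations identical: total sum of squares is zero")
  # term blocks: main effects in order, then the full interaction
  blocks <- lapply(fl, function(f) stats::model.matrix(~f)[, -1, drop = FALSE])
  term_names <- names(fl)
  if (length(fl) > 1) {
    inter <- interaction(fl, drop = TRUE)
    full <- stats::model.matrix(~inter)[, -1, drop = FALSE]
    blocks <- c(blocks, list(full))
    term_names <- c(term_names, paste(names(fl), collapse = ":"))
  }
  sh <- seq_hats(blocks, n)
  df_res <- n - sum(sh$ranks) - 1L
  if (df_res < 1) stop("no residual degrees of freedom")
  ss_term <- vapply(sh$deltas, function(h) sum(h * G), numeric(1))
  ss_res <- sum((diag(n) - sh$h_full) * G)
  f_obs <- (ss_term / sh$ranks) / (ss_res / df_res)

  expl_full <- sh$h_full - matrix(1 / n, n, n)
  stat_for <- function(perm) {
    gp <- G[perm, perm]
    st <- vapply(sh$deltas, function(h) sum(h * gp), numeric(1))
    sr <- ss_total - sum(expl_full * gp)
    (st / sh$ranks) / (sr / df_res)
  }

  if (exact) {
    if (length(fl) != 1 || nlevels(fl[[1]]) != 2)
      stop("exact enumeration supported for one-way two-group designs only")
    g <- fl[[1]]
    pos1 <- which(g == levels(g)[1])
    pos2 <- which(g != levels(g)[1])
    combos <- utils::combn(n, length(pos1))
    f_all <- apply(combos, 2, function(ix) {
      perm <- integer(n)
      perm[pos1] <- ix
      perm[pos2] <- setdiff(seq_len(n), ix)
      stat_for(perm)
    })
    p <- mean(f_all >= f_obs[1] - 1e-12)
    n_used <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- numeric(length(f_obs))
    for (i in seq_len(n_perm)) {
      fp <- stat_for(sample.int(n))
      exceed <- exceed + (fp >= f_obs - 1e-12)
    }
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- n_perm
  }
  out <- data.frame(
    term = c(term_names, "Residual", "Total"),
    df = c(sh$ranks, df_res, n - 1L),
    ss = c(ss_term, ss_res, ss_total),
    pseudo_f = c(f_obs, NA_real_, NA_real_),
    p = c(p, rep(NA_real_, length(f_obs) - length(p)), NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_used
  attr(out, "seed") <- seed
  attr(out, "scheme") <- "unrestricted permutation of raw observations"
  class(out) <- c("permanova_fit", "data.frame")
  out
}

#' Pairwise two-group PERMANOVAs with FDR adjustment
#'
#' Runs a two-group [permanova()] for every pair of group levels and
#' adjusts the p values by Benjamini-Hochberg.
#'
#' @param response numeric vector or matrix.
#' @param groups grouping factor.
#' @param n_perm permutations per pair.
#' @param seed integer seed; each pair gets a derived sub-seed.
#' @return A data frame with one row per pair: `group1`, `group2`,
#'   `pseudo_f`, `p_raw`, `p_adjusted`.
#' @export
pairwise_permanova <- function(response, groups, n_perm = 999,
                               seed = NULL) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  y <- as.matrix(response)
  prs <- utils::combn(levels(g), 2)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    sel <- g %in% prs[, j]
    sub_seed <- if (is.null(seed)) NULL else seed + j
    fit <- permanova(y[sel, , drop = FALSE], droplevels(g[sel]),
                     n_perm = n_perm, seed = sub_seed)
    data.frame(group1 = prs[1, j], group2 = prs[2, j],
               pseudo_f = fit$pseudo_f[1], p_raw = fit$p[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p_raw)
  out
}

#' Pairwise contrasts of cell means from a fitted linear model
#'
#' Estimated-marginal-means contrasts (via emmeans) of the levels of one
#' factor, with t statistics from the model residual variance and
#' Benjamini-Hochberg adjustment across the contrast family. The raw p
#' vector is reported alongside the adjusted one.
#'
#' @param model a fitted `lm` (e.g. from [linear_model_anova()]).
#' @param specs factor name (or emmeans specs) defining the cells.
#' @param by optional conditioning factor name.
#' @return A data frame with `contrast`, `estimate`, `se`, `df`,
#'   `t_ratio`, `p_raw`, `p_adjusted`.
#' @export
pairwise_contrasts <- function(model, specs, by = NULL) {
  emm <- emmeans::emmeans(model, specs = specs, by = by)
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = "none")
  tab <- as.data.frame(summary(ctr))
  out <- data.frame(contrast = as.character(tab$contrast),
                    estimate = tab$estimate, se = tab$SE, df = tab$df,
                    t_ratio = tab$t.ratio, p_raw = tab$p.value,
                    stringsAsFactors = FALSE)
  if (!is.null(by) && !is.null(tab[[by]])) out[[by]] <- tab[[by]]
  out$p_adjusted <- bh_fdr(out$p_raw)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, returned in the
#' original order. Adjusted values are never smaller than the raw ones.
#'
#' @param p p values in \[0, 1\].
#' @return Adjusted p values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sample comparison (t or Mann-Whitney)
#'
#' Two-tailed two-sample tests used for regional contrasts: a
#' pooled-variance Student's t by default (Welch available) or a
#' Mann-Whitney U, exact when the smaller group has at most 8
#' observations and the data are tie-free, otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y the two samples.
#' @param flavor `"t"` or `"mann_whitney"`.
#' @param var_equal pooled-variance t (default) vs Welch.
#' @return A one-row data frame: `test_name`, `statistic`, `df`, `p_raw`,
#'   `method_notes`.
#' @export
two_sample_test <- function(x, y, flavor = c("t", "mann_whitney"),
                            var_equal = TRUE) {
  flavor <- match.arg(flavor)
  if (flavor == "t") {
    if (length(x) < 2 || length(y) < 2) stop("t test needs n >= 2 per group")
    if (stats::var(x) == 0 && stats::var(y) == 0)
      stop("zero variance in both groups")
    ht <- stats::t.test(x, y, var.equal = var_equal)
    notes <- if (var_equal) "pooled-variance Student t, two-tailed"
             else "Welch t, two-tailed"
  } else {
    ties <- any(duplicated(c(x, y)))
    exact <- min(length(x), length(y)) <= 8 && !ties
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    notes <- paste0("Mann-Whitney U, two-tailed, ",
                    if (exact) "exact" else
                      "normal approximation with tie correction")
  }
  data.frame(test_name = flavor,
             statistic = unname(ht$statistic),
             df = if (!is.null(ht$parameter)) unname(ht$parameter)
                  else NA_real_,
             p_raw = ht$p.value, method_notes = notes,
             stringsAsFactors = FALSE)
}

#' Model-selection cascade for trait comparisons
#'
#' The logged analysis policy used per species x trait: fit the factorial
#' linear model; if the Shapiro-Wilk gate on its residuals fails, apply
#' the Tukey ladder transformation to the response and refit; if the gate
#' still fails, fall back to a PERMANOVA on the untransformed response.
#' Every step is recorded in `method_notes`.
#'
#' @param data data frame with the response and factor columns.
#' @param response response column name.
#' @param temperature,region factor column names.
#' @param covariate optional covariate column name (e.g. mass for
#'   critical thermal limits).
#' @param policy `"auto"` (the cascade), `"lm"` or `"permanova"`.
#' @param n_perm,seed PERMANOVA settings.
#' @return A list with `path` (the branch taken), `result` (the model or
#'   permanova table), `normality` and `method_notes`.
#' @export
compare_traits <- function(data, response, temperature = "acclimation_temp",
                           region = "region", covariate = NULL,
                           policy = c("auto", "lm", "permanova"),
                           n_perm = 999, seed = NULL) {
  policy <- match.arg(policy)
  notes <- character()
  run_permanova <- function() {
    fl <- data.frame(temperature = factor(data[[temperature]]),
                     region = factor(data[[region]]))
    if (nlevels(fl$region) < 2) fl <- fl["temperature"]
    permanova(data[[response]], fl, n_perm = n_perm, seed = seed)
  }
  if (policy == "permanova") {
    return(list(path = "permanova", result = run_permanova(),
                normality = NULL,
                method_notes = "policy = permanova (forced)"))
  }
  lm1 <- linear_model_anova(data, response, temperature, region, covariate)
  gate1 <- normality_gate(stats::residuals(lm1$model))
  notes <- c(notes, sprintf("lm residuals Shapiro-Wilk p = %.4g", gate1$p))
  if (gate1$pass || policy == "lm")
    return(list(path = "lm", result = lm1, normality = gate1,
                method_notes = paste(notes, collapse = "; ")))
  tl <- tukey_ladder(data[[response]])
  d2 <- data
  d2[[response]] <- tl$y_trans
  notes <- c(notes, sprintf("Tukey ladder lambda = %g (shift %g)",
                            tl$lambda, tl$shift))
  lm2 <- linear_model_anova(d2, response, temperature, region, covariate)
  gate2 <- normality_gate(stats::residuals(lm2$model))
  notes <- c(notes, sprintf("transformed residuals p = %.4g", gate2$p))
  if (gate2$pass)
    return(list(path = "lm_transformed", result = lm2, normality = gate2,
                transformation = tl,
                method_notes = paste(notes, collapse = "; ")))
  notes <- c(notes, "fell back to PERMANOVA")
  list(path = "permanova", result = run_permanova(), normality = gate2,
       method_notes = paste(notes, collapse = "; "))
}
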