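test_that("normality gate: level on normal data, power on skewed data,
           guards", {
  set.seed(21)
  pass_normal <- mean(replicate(300, normality_gate(rnorm(50))$pass))
  expect_gte(pass_normal, 0.90)
  fail_exp <- mean(replicate(200, !normality_gate(rexp(100))$pass))
  expect_gte(fail_exp, 0.95)
  expect_error(normality_gate(rep(1, 10)), "zero variance")
  expect_error(normality_gate(rnorm(2)), "3 <= n")
})

test_that("Tukey ladder recovers log for lognormal data and prefers the
           identity for normal data", {
  set.seed(22)
  log_hits <- mean(replicate(100, {
    tukey_ladder(rlnorm(60, 0, 1.5))$lambda == 0
  }))
  expect_gte(log_hits, 0.9)
  id_hits <- mean(replicate(100, tukey_ladder(rnorm(60))$lambda == 1))
  expect_gt(id_hits, 0.5)
  # zero in the sample triggers the documented shift
  tl <- tukey_ladder(c(0, rlnorm(30)))
  expect_equal(tl$shift, 1)
  expect_true(all(is.finite(tl$y_trans)))
})

test_that("factorial linear model: balance equivalence, empty-cell
           fallback, covariate entry", {
  set.seed(23)
  d <- expand.grid(temperature = c(22, 27, 31.5), region = c("AG", "GO"),
                   rep = 1:6)
  d$y <- rnorm(nrow(d)) + as.numeric(d$temperature) * 0.1
  m1 <- linear_model_anova(d, "y", ss_type = "I")
  m2 <- linear_model_anova(d, "y", ss_type = "II")
  # balanced design: Type-I and Type-II sums of squares agree
  ss1 <- m1$anova[["Sum Sq"]][1:3]
  ss2 <- m2$anova[["Sum Sq"]][1:3]
  expect_equal(sort(ss1), sort(ss2), tolerance = 1e-9)

  d2 <- d[!(d$temperature == 31.5 & d$region == "GO"), ]
  expect_warning(m3 <- linear_model_anova(d2, "y"), "interaction dropped")
  expect_false(any(grepl(":", rownames(m3$anova))))

  d$mass <- rlnorm(nrow(d))
  m4 <- linear_model_anova(d, "y", covariate = "mass")
  expect_true("mass" %in% rownames(m4$anova))
})

test_that("factorial model detects a planted region effect", {
  set.seed(24)
  d <- expand.grid(temperature = c(22, 27, 31.5), region = c("AG", "GO"),
                   rep = 1:10)
  d$y <- rnorm(nrow(d)) + ifelse(d$region == "GO", 2, 0)
  m <- linear_model_anova(d, "y")
  p_region <- m$anova[["Pr(>F)"]][rownames(m$anova) == "region"]
  expect_lt(p_region, 0.001)
})

test_that("univariate PERMANOVA pseudo-F is the classical ANOVA F", {
  set.seed(25)
  for (i in 1:5) {
    y <- rnorm(24)
    g <- sample(rep(letters[1:3], 8))
    pf <- permanova(y, g, n_perm = 19, seed = i)
    f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(pf$pseudo_f[1], f_aov, tolerance = 1e-9)
  }
})

test_that("exact two-group enumeration equals the brute-force oracle", {
  set.seed(26)
  y <- rnorm(8)
  g <- rep(c("a", "b"), each = 4)
  fit <- permanova(y, g, exact = TRUE)
  expect_equal(attr(fit, "n_perm"), choose(8, 4))
  # independent oracle: classical F over all 70 assignments
  f_of <- function(ix) {
    gg <- rep("b", 8); gg[ix] <- "a"
    summary(aov(y ~ factor(gg)))[[1]]$`F value`[1]
  }
  f_all <- apply(combn(8, 4), 2, f_of)
  f_obs <- f_of(1:4)
  expect_equal(fit$pseudo_f[1], f_obs, tolerance = 1e-9)
  expect_equal(fit$p[1], mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("two-factor PERMANOVA matches vegan's sequential partition", {
  set.seed(27)
  d <- expand.grid(temp = c(22, 27, 31.5), region = c("AG", "GO"),
                   rep = 1:5)
  d$y <- rnorm(nrow(d)) + ifelse(d$region == "GO", 1, 0)
  fit <- permanova(d$y, d[, c("temp", "region")], n_perm = 99, seed = 1)
  ref <- vegan::adonis2(dist(d$y) ~ factor(temp) * factor(region),
                        data = d, permutations = 99, by = "terms")
  expect_equal(fit$ss[1:4], ref$SumOfSqs[1:4], tolerance = 1e-9)
  expect_equal(fit$pseudo_f[1:3], ref$F[1:3], tolerance = 1e-9)
})

test_that("PERMANOVA is seeded-reproducible and rejects degenerate input", {
  set.seed(28)
  y <- rnorm(12); g <- rep(c("a", "b"), 6)
  f1 <- permanova(y, g, n_perm = 199, seed = 99)
  f2 <- permanova(y, g, n_perm = 199, seed = 99)
  expect_identical(f1$p, f2$p)
  expect_error(permanova(rep(1, 12), g, n_perm = 19), "identical")
  expect_error(permanova(y, rep("a", 12), n_perm = 19), "2 levels")
})

test_that("pairwise contrasts: combinatorics and the BH inequality", {
  set.seed(29)
  d <- data.frame(temperature = factor(rep(c(18, 22, 27, 31.5, 35.5), 8)),
                  region = factor(rep(c("AG", "GO"), each = 20)))
  d$y <- rnorm(40)
  m <- linear_model_anova(d, "y")
  ctr <- pairwise_contrasts(m$model, "temperature")
  expect_equal(nrow(ctr), 10)  # choose(5, 2)
  expect_true(all(ctr$p_adjusted >= ctr$p_raw - 1e-12))

  pp <- pairwise_permanova(d$y, d$temperature, n_perm = 99, seed = 1)
  expect_equal(nrow(pp), 10)
  expect_true(all(pp$p_adjusted >= pp$p_raw))
})

test_that("a single divergent temperature cell drives its contrasts below
           the FDR threshold", {
  set.seed(30)
  hits <- replicate(40, {
    d <- expand.grid(temperature = factor(c(18, 22, 27, 31.5)),
                     region = factor(c("AG", "GO")), rep = 1:4)
    d$y <- rnorm(nrow(d), sd = 1) +
      ifelse(d$temperature == "31.5", 4, 0)
    m <- linear_model_anova(d, "y")
    ctr <- pairwise_contrasts(m$model, "temperature")
    div <- grepl("31.5", ctr$contrast)
    all(ctr$p_adjusted[div] < 0.05) && all(ctr$p_adjusted[!div] >= 0.05)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("BH adjustment: hand fixtures and brute-force equivalence", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("two-sample tests: pooled-t fixture, identical samples,
           Mann-Whitney enumeration", {
  r <- two_sample_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p_raw, 0.288, tolerance = 1e-2)

  x <- c(1.3, 2.1, 0.7, 1.8)
  same <- two_sample_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)

  mw <- two_sample_test(c(1, 2), c(3, 4), flavor = "mann_whitney")
  expect_equal(mw$p_raw, 1 / 3, tolerance = 1e-12)  # 2 * 1/6 arrangements
  expect_match(mw$method_notes, "exact")

  expect_error(two_sample_test(rep(1, 3), rep(1, 3)), "zero variance")
})

test_that("the auto policy cascades lm -> transform -> PERMANOVA with a
           full note trail", {
  set.seed(32)
  d <- expand.grid(acclimation_temp = c(22, 27, 31.5),
                   region = c("AG", "GO"), rep = 1:8)
  d$y <- rnorm(nrow(d)) + 5
  r1 <- compare_traits(d, "y", n_perm = 99, seed = 1)
  expect_equal(r1$path, "lm")
  expect_match(r1$method_notes, "Shapiro-Wilk")

  # heavy lognormal response: the ladder usually rescues normality
  d$z <- rlnorm(nrow(d), 0, 2)
  r2 <- compare_traits(d, "z", n_perm = 99, seed = 1)
  expect_true(r2$path %in% c("lm_transformed", "permanova"))

  r3 <- compare_traits(d, "z", policy = "permanova", n_perm = 99, seed = 1)
  expect_equal(r3$path, "permanova")
  expect_s3_class(r3$result, "permanova_fit")
})
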