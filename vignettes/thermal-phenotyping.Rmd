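---
title: "Methods: thermal phenotyping from respirometry and critical thermal limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscope)
```

## The measurement model

Intermittent-flow respirometry yields, for each fish, an overnight
sequence of sealed *measure* phases separated by *flush* phases. In a
sealed phase of a chamber of volume $V$ (L) holding a fish of mass $M$
(g), oxygen declines at a rate set by the fish's uptake plus microbial
background respiration. The package's estimator chain is:

1. **Segmentation** (`segment_cycles`): phase labels partition the
   trace; windows shorter than two samples are dropped with a warning.
   Variable-length measure windows are first-class, because real
   protocols cut a measure phase short once oxygen saturation falls to
   ~80 % — the labels, not arithmetic, define the windows whenever
   labels exist.
2. **Slope fitting** (`fit_slope`): OLS of O$_2$ on time per window.
   A window with zero oxygen variance returns slope 0 with an `NA`
   $r^2$ rather than failing; windows with $r^2 < 0.9$ are flagged,
   never silently removed.
3. **Conversion** (`compute_mo2`):
   $\dot M O_2 = -b\,(V - M/1000)\cdot 60/(M/1000)$ in
   mg O$_2$ kg$^{-1}$ h$^{-1}$. The fish is assumed to displace its
   own mass of water (density 1 g mL$^{-1}$). Positive slopes are
   physically impossible for a respiring fish and are flagged with the
   sign preserved.
4. **MMR** (`estimate_mmr`): the uptake of the *first* cycle after the
   exhaustive chase — a protocol-fidelity rule, not the maximum over
   cycles. The max-cycle alternative exists behind `use_max` and is
   off by default.
5. **SMR** (`estimate_smr`): the 0.20 quantile (linear interpolation
   between order statistics, the common scientific-software default)
   of per-cycle uptake over cycles starting at or after the 5-h
   exclusion boundary. The boundary is half-open: a cycle starting at
   exactly 300 min is included. "Lowest 20th percentile" admits a
   second reading — the mean of the lowest 20 % of values — which is
   implemented (`method = "mean_lowest"`) but not the default, since
   the quantile reading is the one recommended in the respirometry
   methods literature.
6. **Background correction** (`correct_background`): empty-chamber
   slopes measured before and after the trial are converted with the
   *full* chamber volume and deducted asymmetrically — the pre-trial
   blank from MMR (measured at trial start) and the post-trial blank
   from SMR (measured overnight, when microbial growth has
   progressed). Negative corrected values are flagged, kept.
7. **Aerobic scope** is the exact identity
   $AS = MMR_c - SMR_c$; negative scope is flagged, kept.

## Allometric mass adjustment

Each metabolic trait is regressed as $\log_{10}(\text{trait})$ on
$\log_{10}(M)$ per species (`fit_mass_scaling`), pooling regions and
acclimation temperatures; the fitted exponent $b$ adjusts every fish to
the species' arithmetic mean mass:
$\text{adj} = \text{value}\cdot(\bar M/M)^b$. Log–log space is the
standard for metabolic allometry and is the default; a linear-space
option exists for sensitivity. Two caveats are deliberate design
decisions rather than established facts: the regression space and the
pooling level are conventions, and both are documented switches. On
temperature-structured data the pooled exponent absorbs any chance
correlation between mass and temperature; the package's recovery
checks therefore estimate the exponent either within a single
temperature cell or after dividing value and mass by their
temperature-cell geometric means. Critical thermal limits are absolute
temperatures and are **never** mass-scaled (`fit_mass_scaling` refuses
`trait = "CT*"`); mass instead enters their linear models as a
covariate.

## Thermal performance curves and Q10

Three families (`fit_exponential`, `fit_poly2`, `fit_gaussian`):
exponential $a e^{bT}$ for SMR, an exact closed-form OLS quadratic for
MMR, and the Gaussian $A \exp(-(T-T_{opt})^2/2\sigma^2)$ for aerobic
scope. Numerical choices:

* the exponential fit is initialised from the log-linear OLS solution
  and returned directly when that solution is already exact;
* the Gaussian initialises $T_{opt}$ at the temperature with the
  largest binned mean, amplitude at that mean, and breadth at half the
  temperature span, with bounds $\sigma \in (0, 50]$ and $T_{opt}$
  within the span $\pm 10$ °C; a fit ending on a bound (e.g. on flat
  data) is flagged unconverged, never silently reported;
* both nonlinear fitters make up to 5 jittered restarts before
  declaring non-convergence; $r^2$ is computed on the original scale
  ($1 - SS_{res}/SS_{tot}$) and may be negative;
* fits on individual fish are the default; `group_means = TRUE`
  reproduces figure-style fits on temperature-cell means — which of
  the two a published figure used is often unstated, so both exist.

`q10` implements $(R_2/R_1)^{10/(T_2-T_1)}$, oriented internally so
$T_2 > T_1$. The default comparison (`q10_table`) uses group-mean
trait values at two acclimation temperatures (22 and 31.5 °C, the
range two study regions share); a fitted-curve Q10 (`q10_from_fit`)
is the alternative.

## Critical thermal limits and safety margins

Under a constant ramp $r$ the first-order lag model
$dT_b/dt = k(T_w - T_b)$, $k = k_0 M^{-\gamma}$, has the closed form
$T_b = T_w - (r/k)(1 - e^{-kt})$ (lag added, not subtracted, on
cooling ramps). `internal_temp_at_loe` evaluates it at the observed
water temperature at loss of equilibrium; the tests verify the closed
form against numerical ODE integration to $10^{-6}$ °C across
$r \in \{0.05, 0.1, 0.2\}$ °C min$^{-1}$, $k \in [0.01, 10]$
min$^{-1}$, $t \in [1, 300]$ min. The published lag coefficients this
model descends from are not recoverable from summary sources, so
$k_0 = 1.2$ min$^{-1}$ at 1 g and $\gamma = 0.33$ are order-of-
magnitude defaults for small fish, required config rather than
constants: every result table records the coefficients used, and the
$k \to \infty$ limit reproduces raw water-temperature limits for
sensitivity analysis.

Environmental extremes (`env_extremes`) are per-calendar-year maxima
and minima of daily SST averaged across years. A partial year
contributes its maximum only if the local summer window (default
June–September) is at least 90 % covered, and its minimum only under
the analogous winter rule (January–March) — so a series truncated in
autumn still yields that year's summer maximum. Both windows are
configurable, which keeps the rule hemisphere-agnostic. Safety margins
are computed **per individual** (summer: $CT_{max}$ − mean annual
maximum; winter: mean annual minimum − $CT_{min}$), then summarised;
negative margins are preserved and flagged.

`summarize_tsm` aggregates: per-cell mean ± SE, per-species regional
gap (mild minus hot region), the cross-species mean gap as the
*unweighted* mean of per-species gaps, and per-region grand means as
unweighted means of species means. Unweighted averaging is the choice
that treats species as the replicate; sample-size weighting would let
the best-sampled species dominate. One known quirk of this arithmetic:
for one published set of winter per-species means the unweighted grand
mean and gap differ by a few hundredths of a degree from the summary
values quoted alongside them (the corresponding summer values agree
exactly); the package reproduces the arithmetic, not the quote.

## The comparison layer

The per-trait analysis policy (`compare_traits`, `policy = "auto"`) is
an explicit, logged cascade: fit the factorial linear model
(temperature × region, Type-II SS); Shapiro–Wilk gate on residuals at
$\alpha = 0.05$; on failure, Tukey ladder-of-powers transform
($\lambda \in \{-2,-1,-\tfrac12,0,\tfrac12,1,2\}$, $\lambda$ chosen by
maximal Shapiro–Wilk $W$, ties toward the identity, automatic positive
shift recorded when the sample touches zero) and refit; on a second
failure, PERMANOVA. Every step lands in `method_notes`.

The PERMANOVA is written from scratch: Gower-centred squared Euclidean
distances, sequential sums of squares via hat-matrix differences,
pseudo-F against the residual, and unrestricted permutation of raw
observations with $p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$. For a
univariate response the one-way pseudo-F is numerically identical to
the classical ANOVA F, and for two groups of 4 the exact mode
enumerates all 70 assignments — both identities are tested, along with
agreement of the sequential partition with an independent
implementation. Temperature is treated as a categorical factor
(discrete acclimation groups), Type-II sums of squares are the default
for unbalanced ecology designs (Type-I available), and the t-test
default is pooled-variance Student's t (Welch behind a flag) — all
three are documented assumptions where the source protocols are
silent. Multiple comparisons use Benjamini–Hochberg step-up
(`bh_fdr`, delegating to the standard implementation and verified
against a brute-force step-up in the tests).

## What the synthetic generator emulates — and what it does not

`synthetic_config` holds the generative counterpart of every estimated
quantity. Defaults, chosen once as field-realistic values for a small
blenny-like reef fish:

| parameter | default | why |
|---|---|---|
| SMR curve $a e^{bT}$ | $a = 28.6$, $b = 0.063$ | back-computed from a printed SMR of ~115 mg O₂ kg⁻¹ h⁻¹ at 22 °C and Q10 ≈ 1.9 |
| AS Gaussian | $A = 450$, $T_{opt} = 29.2$, $\sigma = 11.8$ °C | printed Gaussian fit parameters for the hot-basin population |
| body mass | lognormal, median 1.43 g, CV ≈ 47 % | printed species mass distribution |
| chamber volume | 0.175 L | the small-species chamber |
| cycle | 10 min = 5 measure + 5 flush, 5-s sampling | 10-min cycle protocol; 5 s is a typical optode logging rate |
| trial length | 18 h | "16–20 h overnight" |
| EPOC decay $\tau$ | 60 min | makes the 5-h exclusion window meaningful (recovery ~99 % complete at 5 τ) |
| sensor noise | 0.005 mg L⁻¹ SD per sample | optode-grade noise |
| background slopes | −5×10⁻⁴ → −1×10⁻³ mg L⁻¹ min⁻¹, linear drift | microbial growth over the trial; makes pre/post corrections differ |
| between-individual CV | 10 % (mean-one lognormal on SMR and AS) | no variance components are published; this is a stated default, not an inference |
| allometric exponent | −0.2 on mass-specific rates | classic mass-specific metabolic scaling |
| CT limits | 39.5 / 8.65 °C ± 0.3 | printed hot-basin CT$_{max}$; winter CT$_{min}$ consistent with a printed winter margin |
| SST presets | hot basin 27.25 ± 9.25 °C, mild basin 26.5 ± 5.5 °C, noise 0.3 | annual ranges near 18.5 and 11 °C |

Oxygen traces hold uptake at MMR throughout the *first* measure phase
(a post-chase plateau) and decay exponentially toward SMR afterwards.
The plateau is what makes the first-cycle rule an exact read of MMR in
the noiseless limit — with a decay starting at $t = 0$ no slope-based
estimator could ever return MMR exactly, and the zero-noise identity
tests would be meaningless. Within measure phases oxygen follows the
exact integral of uptake plus the drifting background; flushes restore
saturation (default 6.8 mg L⁻¹, typical of warm seawater — absolute
oxygen levels are a generator choice, as only slopes matter
downstream).

Not emulated: chamber mixing hydrodynamics, sensor drift or
calibration error, autocorrelated noise, handling-stress effects
beyond the EPOC term, or any satellite-product structure beyond a
sinusoid plus white noise. Consequently, passing recovery tests shows
the estimators are correct *for the stated generative model*; they say
nothing about, e.g., robustness to drifting optodes or poorly mixed
chambers.

## Problem sizes and numerical tolerances

The test suite and the acceptance script size their simulations to run
comfortably on a single CPU: noiseless recovery uses one 5-temperature
× 8-fish cohort (tolerance 10⁻⁶ relative; the chain actually achieves
~10⁻¹⁰ because the zero-noise cohort also zeroes the background and
shortens the EPOC time constant to 30 min so that no residual
recovery signal survives the 5-h exclusion); noisy recovery uses 100–200
replicate cohorts with 12-h traces; the PERMANOVA null calibration uses
500–2000 univariate two-group simulations with 199 permutations each;
oracle-equivalence checks (SMR quantile, Benjamini–Hochberg) use 1000
random instances at 10⁻¹² tolerance. The drifting background sets a
floor of ~1–2 % on absolute SMR accuracy that no pre/post correction
scheme can remove — visible in the noisy-recovery medians — which is a
property of the measurement design, not of the estimator.

## Known limitations

* MMR from the whole first measure phase; rolling-window maximum-slope
  MMR is out of scope.
* Euclidean distances only in the PERMANOVA; no mixed or random
  effects anywhere.
* No alternative TPC families (Sharpe–Schoolfield, Brière) and no
  model competition.
* The seasonal SST polynomial (`fit_seasonal_polynomial`) is purely
  descriptive.
* Real-data ingestion is limited to the documented CSV dialect; no
  instrument-native or satellite formats.
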