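# thermoscope

Thermal phenotyping of reef fishes: from raw intermittent-flow
respirometry traces and critical-thermal-limit trials to
population-level comparisons of metabolic performance and thermal
safety margins.

The package is aimed at comparative ecophysiologists who measure
whole-animal aerobic metabolism and thermal tolerance across
temperatures, populations or species, and who want the entire
computational chain — trait extraction, mass correction, curve fitting
and statistics — as tested, reusable functions rather than one-off
scripts. A seeded synthetic-data generator emulates every raw input
with known ground truth, so each estimator can be validated by
parameter recovery before it ever touches real data.

## What it computes

**Respirometry.** Intermittent-flow traces alternate sealed *measure*
phases and *flush* phases. Within each measure phase the oxygen decline
slope *b* (mg O2 L⁻¹ min⁻¹) is fitted by OLS and converted to a
mass-specific uptake rate

    ṀO₂ = −b · (V − M/1000) · 60 / (M/1000)   [mg O2 kg⁻¹ h⁻¹]

with chamber volume *V* (L) and body mass *M* (g). Maximum metabolic
rate (MMR) is the ṀO₂ of the first cycle after the exhaustive chase;
standard metabolic rate (SMR) is the 20th percentile of cycles after a
5-h exclusion window; both are background-corrected (pre-trial blank
for MMR, post-trial blank for SMR) and aerobic scope is
AS = MMR − SMR.

**Allometry.** Each trait is regressed as log₁₀(trait) on log₁₀(mass)
per species; values are adjusted to the species mean mass by
`value · (M̄/M)^b`. Critical thermal limits are never mass-scaled —
mass instead enters their models as a covariate.

**Thermal performance curves and Q10.** SMR ~ a·e^{bT} (exponential),
MMR ~ quadratic, AS ~ amplitude·exp(−(T−T_opt)²/2σ²) (Gaussian), with
Q10 = (R₂/R₁)^{10/(T₂−T₁)}.

**Critical thermal limits.** During a 0.1 °C min⁻¹ ramp the body lags
the water by the first-order model dT_b/dt = k(T_w − T_b) with
k = k₀·M^(−γ); the internal temperature at loss of equilibrium is the
critical limit. Thermal safety margins compare that limit with the
mean annual SST extreme: summer TSM = CT_max − mean annual maximum,
winter TSM = mean annual minimum − CT_min.

**Statistics.** Shapiro–Wilk normality gating, Tukey
ladder-of-powers transformation, factorial linear models
(temperature × region, Type-II SS), a from-scratch permutation ANOVA
(pseudo-F on Euclidean distances, Anderson-style), estimated-marginal-
means pairwise contrasts, Benjamini–Hochberg FDR, and two-tailed
t / Mann–Whitney tests.

## Worked example

```r
library(thermoscope)

cfg   <- synthetic_config(duration_h = 12)          # small blenny-like fish
trace <- generate_o2_trace(cfg, fish_mass = 1.43, temp = 27, seed = 42)
traits <- extract_traits(trace, chamber_volume = 0.175, fish_mass = 1.43,
                         bg_pre_slope  = cfg$background_slope_pre,
                         bg_post_slope = cfg$background_slope_post,
                         acclimation_temp = 27)
round(traits[, c("smr_raw", "smr_corrected", "mmr_corrected",
                 "aerobic_scope")], 1)
#>   smr_raw smr_corrected mmr_corrected aerobic_scope
#> 1   149.6         142.2         561.6         419.3

q10(100, 150, 22, 31.5)
#> [1] 1.532
```

The trace was generated with a true SMR of 145.9 and true MMR of
557.6 mg O2 kg⁻¹ h⁻¹: the raw SMR (149.6) carries the microbial
background, the corrected value (142.2) is within ~3 % of truth under
the default sensor noise, and aerobic scope is the difference of the
corrected traits. The Q10 of 1.532 says the rate rises ~53 % per 10 °C
over the 22.0–31.5 °C span.

For an end-to-end run (two regions, traits → mass adjustment → TPC
fits → Q10 → CT limits → safety margins → comparisons):

```r
res <- run_pipeline(run_config(seed = 1))
res$tsm_summary$seasonal    # per-season regional gaps and grand means
```

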