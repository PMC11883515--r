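# Data dictionary

Column dialect of every delimited-text table the package reads or writes.
All tables are plain CSV with a header row.

## Oxygen trace (`generate_o2_trace`, `read_o2_trace`)

| column       | unit / values                 | meaning                              |
|--------------|-------------------------------|--------------------------------------|
| time_min     | minutes from trial start      | sample timestamp, strictly increasing|
| o2_mg_per_l  | mg O2 / L                     | dissolved-oxygen concentration       |
| temp_c       | degC                          | water temperature                    |
| phase        | measure / flush / wait        | respirometry cycle phase             |
| chamber_id   | text                          | chamber or fish label                |

## Cohort metadata (`generate_cohort`)

| column                | unit            | meaning                                  |
|-----------------------|-----------------|------------------------------------------|
| fish_id               | text            | unique fish label                        |
| species, region       | text            | grouping labels                          |
| acclimation_temp      | degC            | acclimation / trial temperature          |
| mass                  | g               | body mass                                |
| chamber_volume        | L               | respirometry chamber volume              |
| background_slope_pre  | mg O2 L-1 min-1 | empty-chamber slope before the trial     |
| background_slope_post | mg O2 L-1 min-1 | empty-chamber slope after the trial      |
| smr_true, mmr_true, as_true | mg O2 kg-1 h-1 | generative ground truths (synthetic only) |

## Metabolic traits (`extract_traits`)

One row per fish: `fish_id`, `species`, `region`, `acclimation_temp`,
`mass` (g), `smr_raw`, `mmr_raw`, `smr_corrected`, `mmr_corrected`,
`aerobic_scope`, `background_pre`, `background_post`
(all rates in mg O2 kg-1 h-1), plus the flags `flag_negative_scope` and
`flag_mmr_below_smr`. Mass-adjusted columns `smr_adj`, `mmr_adj`,
`as_adj` are appended by `mass_adjust_traits`.

## Critical-thermal-limit trials (`generate_ct_trial`, `ct_limits`)

| column            | unit      | meaning                                    |
|-------------------|-----------|--------------------------------------------|
| direction         | max / min | heating or cooling ramp                    |
| ramp_rate         | degC/min  | constant ramp rate (default 0.1)           |
| start_temp        | degC      | acclimation temperature at ramp start      |
| water_temp_at_loe | degC      | water temperature at loss of equilibrium   |
| mass              | g         | body mass                                  |
| critical_limit    | degC      | internal temperature at LOE (computed)     |

## Sea-surface temperature (`generate_sst`)

| column | unit | meaning                  |
|--------|------|--------------------------|
| site   | text | reef / site label        |
| date   | ISO date | daily observation    |
| sst_c  | degC | sea-surface temperature  |

## Thermal safety margins (`run_pipeline`)

One row per fish: `fish_id`, `species`, `region`, `season`
(summer/winter), `critical_limit` (degC), `environmental_extreme` (degC,
mean annual maximum for summer, mean annual minimum for winter), and
`margin` (degC; summer: limit - extreme, winter: extreme - limit).
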