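# moonflight

Geolocator-based analysis of seabird autumn migration: how breeding
phenology shapes migratory timing, stopover use and night flight under
moonlight.

Long-lived pelagic seabirds such as shearwaters breed late into the
season and then migrate across the equator to their wintering grounds.
Archival geolocators (GLS tags) record two streams per bird-year —
ambient light, from which position can be inferred, and wet/dry
immersion, from which behaviour can be classified — and the analysis
question is how a bird's breeding schedule (its lay date and the
departure date it forces) propagates into its migratory strategy: how
long it travels, how much it stops over to refuel, how productive its
stopover sites are, and how much it flies at night, especially under
moonlight. `moonflight` implements that entire analysis as a tested R
pipeline, for movement ecologists working with threshold light-level
geolocation and immersion loggers.

## What the package does

* **Threshold geolocation** (`detect_twilights`, `estimate_position`,
  `build_track`, `calibrate_sun_elevation`, `detect_migration_window`):
  twilights from light-threshold crossings; longitude from the timing of
  local apparent noon/midnight corrected by the equation of time
  (15°/h); latitude from day length inverted at a calibrated sun
  elevation angle (default −4.5°), masked ±15 days around the equinoxes;
  bi-daily positions; 3-day rolling-mean longitude; automated migration
  start/end detection from sustained longitudinal change.
* **Activity classification** (`bin_scores`, `classify_bin`,
  `split_day_night`, `daily_metrics`, `birdday_table`): 10-min immersion
  scores 0–200; score 0 = flight, 1–199 = foraging, 200 = rest;
  day/night splitting against detected twilights with pro-rata handling
  of straddling bins; per bird-day/night flight and foraging hours with
  moonlight covariates.
* **Stopover detection** (`fit_mixture_em`, `assign_stopover_days`,
  `segment_stopovers`): a two-component normal mixture over pooled daily
  flight hours fitted by EM; days with posterior probability > 0.66 of
  the low-flight component are stopovers; run-length segmentation with
  track centroids.
* **Astronomy** (`sun_altitude`, `day_length`, `twilight_times`,
  `moon_illumination`, `moon_windows`): a self-contained analytic
  solar/lunar ephemeris (no data files) for day/night splitting,
  latitude inversion, moon illuminated fraction and moon-up windows.
* **Chlorophyll context** (`box_mean`, `stopover_chl_ratio`): mean
  chlorophyll-a in a 0.08°-half-width box around each stopover relative
  to the Patagonian-shelf wintering box (36–46°S, 54–66°W) over the same
  days.
* **Model suite** (`fit_lmm`, `lrt`, `bootstrap_ci`, `icc`,
  `run_model_suite`): ten gaussian mixed models (ML, random intercepts
  for bird and year) linking departure date, moonlight and colony to
  flight, foraging, stopover and duration responses, with
  likelihood-ratio tests, 1000-draw parametric bootstrap CIs and
  intra-class correlations.
* **Synthetic populations with ground truth** (`population_params`,
  `simulate_population`, `render_light`, `render_immersion`,
  `render_chl_grid`): simulated migrating birds — lay-date-driven
  departures, stopover schedules, moonlit night flight, great-circle
  routes — rendered down to raw light and immersion samples, so the
  whole pipeline is validated by parameter recovery.

The core statistical object is the bird-day/night table: one row per
bird × date × phase with flight/foraging hours, phase length, moonlight
covariates and a stopover flag. Models are gaussian LMMs of the form,
e.g., night flight hours ~ moon + departure + moon×departure + colony +
(1|bird) + (1|year), fitted by maximum likelihood, with significance
from likelihood-ratio tests (χ² = 2Δlogℒ) and percentile CIs from
parametric draws of the fixed-effect sampling distribution.

## Worked example

```r
library(moonflight)
cfg <- run_config(params = population_params(n_birds = 12, n_years = 1),
                  seed = 1, n_boot = 500)
res <- run_all(cfg)
print(res)
```

```
Pipeline result: 12 complete tracks ( 0 excluded )
Mixture components (whole-day flight hours): low 1.88 / high 11.73
Phenology summary:
                          mean    min max
migration_start         255.08 245.00 266
migration_end           281.67 265.00 293
duration_days            26.58  20.00  37
stopover_number           3.42   2.00   5
total_stopover_days       8.58   5.00  12
stopover_length_days      2.56   2.20   3
days_between_stopovers    3.31   1.50   7
max_continuous_flight_h   8.97   7.67  10
lay_days_apr26            5.50   3.00   8
```

All 12 synthetic tracks passed QC (a detected migration start and end).
The EM mixture separated stopover days (≈1.9 h of flight per day) from
travel days (≈11.7 h). The phenology summary is in day-of-year
(migration start 255 ≈ 12 September) and days; the birds stopped 3–4
times for ≈8.6 days in total, matching the generator's configured
stopover budget. The model report (`res$suite$report`) then gives, e.g.
for the moonlight model on this small run:

```
   model_id                     term estimate   ci_lo   ci_hi   chisq        p
10        2               night_moon  3.90400  1.2195  6.2397  8.4251 0.003701
32        5            dep_days_aug1 -0.22168 -0.3091 -0.1346 13.9114 0.000192
```

— night flight increases by ≈3.9 h from new to full moon (CI [1.2, 6.2],
wide at 12 birds; the generating effect is 3.245), and each day of later
departure costs ≈0.22 stopover days (generating −0.156). At the
validation scale (100 birds × 2 years) both recover within 10%; see the
methods vignette (`vignettes/methods.Rmd`) for the generating model and
design rationale.

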