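# antseep

Methane micro-seepage analysis for continuously monitored red wood-ant
nests.

Red wood-ant (*Formica polyctena*) mounds cluster along tectonic fault
traces, and the methane inside them can come from two very different
places: microbial decomposition of nest material (strongly ^13^C-depleted,
δ¹³C-CH₄ near −70 ‰ VPDB) or thermogenic/abiotic gas migrating up fault
networks (δ¹³C-CH₄ near −35 ‰). `antseep` is an R toolkit for the analysis
chain of a continuous in-situ campaign at such a nest — a 1-Hz cavity
ring-down record of CH₄ and δ¹³C-CH₄, a fixed "AntCam" watching the mound,
a weather station, harmonic earth tides and a micro-earthquake catalogue —
and for generating synthetic campaigns with known ground truth on which
every stage is testable.

## What it computes

* **Source attribution by Keeling plot.** Under two-reservoir mass balance
  (background `C_a`, `δ_a`; source `δ_s`),

  `δ_obs = δ_s + C_a (δ_a − δ_s) / C_obs`,

  so OLS of δ¹³C on `1/CH₄` estimates the source signature as its
  intercept (`keeling_fit()`).
* **Robust anomaly detection.** CH₄ peaks above `median + k·MAD` (raw MAD,
  `k = 2`), δ¹³C peaks by a symmetric MAD-deviation rule (or the literal
  `< −35 ‰ / > 0 ‰` rule), and coincidence windows where both series are
  anomalous and persist (`mad_threshold()`, `coincident_peaks()`).
* **Ant activity from frames.** Mutual-information registration over
  integer translations, masked absolute-difference sums, and per-sensor
  polynomial calibration — degree 1 by day, degree 3 by night
  (`register_translation()`, `activity_raw()`, `fit_calibration()`).
* **Environmental statistics.** Weather PCA, sequential-ANOVA regression of
  responses on the first three PCs, additive time-series decomposition,
  lagged cross-correlation, harmonic earth tides (M2/S2/K1/O1), and 2-D
  Gaussian kernel density of epicentres.
* **Synthetic campaigns.** `scenario_config()` / `scenario_preset()`
  describe a full campaign (sources, schedules, noise, weather, tides,
  frames, seed); identical configurations generate bit-identical data.

## Worked example

Run the complete campaign analysis on the shipped two-source scenario
(8 days at 1 Hz, four microbial and four fault-related injection events,
instrument-level noise):

```r
library(antseep)
cfg <- scenario_preset("two-source", seed = 5, frame_rate = 1/300)
rep <- run_campaign(cfg)
print(rep)
#> Campaign report
#>   nest samples: 691200; ambient: 43200; weather rows: 2304
#>   CH4 thresholds (median + k*MAD): nest 1.827, ambient 1.827 ppm
#>   coincident peak windows: 8
#>   pooled Keeling intercept: -48.7 permil [-49.0, -48.4]
#>   intercept cluster centres: -69.2, -37.1 permil
#>   weather PCA cumulative variance (3 PCs): 0.51 0.68 0.85
```

All eight injected events are recovered as coincident CH₄/δ¹³C windows.
The per-window Keeling intercepts split cleanly into the two configured
end members (the pooled fit across both sources is a mixture and sits
between them — that is why intercepts are clustered per window):

```r
rep$keeling$per_window[, c("window", "intercept", "se", "n")]
#>   window intercept         se    n
#> 1      1 -69.40685 0.16630803 3370
#> 2      2 -37.30704 0.15484763 2703
#> 3      3 -69.08307 0.09423311 3870
#> 4      4 -37.14411 0.08773917 3373
#> 5      5 -69.23920 0.13870267 3478
#> 6      6 -37.12378 0.12946466 2861
#> 7      7 -69.01522 0.08305850 4008
#> 8      8 -36.94475 0.08356247 3265
```

The cluster centres −69.2 ‰ and −37.1 ‰ recover the configured microbial
(−69 ‰) and fault-related (−37 ‰) signatures. The report also carries the
weather PCA/ANOVA tables, the activity decomposition, and the
cross-correlations of activity and earth tides against the gas series;
`run_campaign(..., out_dir = "out")` writes the JSON report and CSV side
tables.

Field data are read with `read_hf305()` (gas/weather/activity CSV
dialects, schema-checked), frames with `read_frames()` (PNG directories,
`frame_<epoch-ms>_<D|N>.png`).

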