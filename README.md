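# laborHRV

Maternal heart rate variability (HRV) versus time to delivery: an
end-to-end, fully testable R implementation of the analysis pipeline.

## The problem

The estimated due date predicts the onset of labor poorly; physiological
markers of the autonomic shift that precedes delivery could do better.
Short-term maternal HRV is such a candidate: it can be extracted
non-invasively from a direct maternal ECG, or from an abdominal
electrohysterogram (EHG) in which the maternal ECG rides on uterine
activity as interference. This package implements the complete analysis
chain for cohorts of late-pregnancy recordings:

* **R-peak extraction** — zero-phase Butterworth high-pass (5 Hz EHG /
  0.5 Hz ECG), amplitude normalization to a maximum of 1, local-maximum
  detection above a relative threshold (default 0.4) with a 250 ms
  refractory period, and selection of one usable 5-minute segment
  (beginning of the record favored, later windows on noise).
* **RR conditioning** — running-median ectopic flagging (±20%, physiologic
  screen 250–2000 ms) and duration-preserving run-mean correction.
* **HRV indices** — mean RR, SDNN, RMSSD (ms); 4 Hz spline tachogram,
  Welch-style averaged periodogram (Hann, 150 s segments, 50% overlap),
  band powers over VLF [0.0033–0.04], LF [0.04–0.15], HF [0.15–0.4] Hz
  reported as ln(ms²), and the raw-power LF/HF ratio.
* **Cohort statistics** — exclusion of induced/cesarean deliveries and
  poor-quality records; time to delivery
  `ttd = ga_delivery − ga_recording` (decimal weeks); Monte-Carlo
  Lilliefors normality gate; Spearman correlations (exact permutation
  p for n ≤ 9, t-approximation above; Fisher-z CI with the Bonett–Wright
  standard error `sqrt((1 + r²/2)/(n − 3))`).
* **Synthetic data** — integral pulse frequency modulation (IPFM) RR
  generator (beats at integer crossings of
  `∫(1 + Σ aᵢ sin(2π fᵢ t + φᵢ))/T̄ dt`), Gaussian-QRS ECG and EHG
  synthesizers with ground truth attached, ectopic injection, and cohort
  generation with Spearman correlations planted through a Gaussian copula —
  so every stage is verifiable with no external data.

## Worked example

Simulate one subject with known spectral content, synthesize its ECG, and
run the extraction chain:

```r
library(laborHRV)
sim <- generate_rri_ipfm(tachogram_spec(mean_rr = 800,
  modulations = list(c(0.10, 0.03), c(0.25, 0.05)), duration = 310, seed = 7))
rec <- synthesize_ecg(sim$beat_times, fs = 1000, noise_sd = 0.05, seed = 7)
out <- process_recording(rec)
out$metrics
#> <hrv_metrics> RR 800.0 ms | SDNN 31.6 ms | RMSSD 32.6 ms | VLF -3.55 | LF 5.64 | HF 6.54 (Ln ms^2) | LF/HF 0.41
```

The mean RR recovers the planted 800 ms; the HF tone (amplitude 0.05 ×
800 ms) corresponds to a band power of (0.05·800)²/2 = 800 ms², i.e.
ln ≈ 6.68, and the pipeline reports 6.54 (the small deficit is
integrate-and-fire plus taper attenuation). A whole cohort with planted
rank correlations (+0.55 for LF/HF vs TTD, −0.50 for RMSSD vs TTD):

```r
co <- generate_cohort(cohort_spec(30, seed = 42))
res <- run_pipeline(co$recordings, pipeline_config(seed = 42))
res
#> <pipeline_result> 30 subjects retained (excluded: 0 induced, 0 cesarean, 0 poor R peaks)
#>
#> Correlations of HRV metrics with gestational outcomes (primary outcome: time to delivery)
#>
#> RR (ms)    785.19 +- 38.03   ttd: r = -0.35 [-0.63, +0.03] p = 0.06184
#> SDNN (ms)   23.64 +-  8.40   ttd: r = -0.40 [-0.67, -0.03] p = 0.0292
#> RMSSD (ms)  20.67 +-  8.59   ttd: r = -0.50 [-0.74, -0.15] p = 0.004526
#> VLF (Ln)     4.31 +-  0.03   ttd: r = +0.24 [-0.13, +0.56] p = 0.1954
#> LF (Ln)      5.05 +-  0.91   ttd: r = -0.18 [-0.51, +0.19] p = 0.3292
#> HF (Ln)      5.39 +-  0.99   ttd: r = -0.53 [-0.76, -0.19] p = 0.002533
#> LF/HF        0.82 +-  0.42   ttd: r = +0.61 [+0.30, +0.81] p = 0.0003014
```

The planted correlations surface at the cohort level: RMSSD comes out at
r = −0.50 and LF/HF at +0.61 against time to delivery, within the sampling
dispersion of Spearman's rho at n = 30.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/laborhrv.R simulate --n 10 --seed 7 --out sim/
Rscript inst/scripts/laborhrv.R run-all --input sim/ --out results/
Rscript inst/scripts/laborhrv.R hrv --input sim/S001.csv
```

## Documentation

The methods vignette (`vignettes/maternal-hrv-pipeline.Rmd`) documents the
models, every tunable parameter with its default and rationale, the
numerical choices, what the synthetic generators do and do not emulate, and
known limitations.
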