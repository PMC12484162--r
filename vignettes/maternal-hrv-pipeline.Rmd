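---
title: "Maternal HRV and time to delivery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal HRV and time to delivery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laborHRV)
```

## The problem

Short-term maternal heart rate variability (HRV) in the third trimester is a
candidate marker for the approach of labor: autonomic tone shifts as delivery
nears, and beat-to-beat interval statistics measure that shift
non-invasively. The analysis this package implements correlates per-subject
HRV indices, extracted from a single 5-minute segment of either an abdominal
electrohysterogram (EHG, in which the maternal ECG appears as interference)
or a direct maternal ECG, with *time to delivery* (TTD): gestational age at
delivery minus gestational age at recording, in decimal weeks.

The pipeline has four stages, each an exported function group:

1. **Signal extraction** — zero-phase high-pass filtering, amplitude
   normalization, thresholded R-peak detection with a refractory period,
   5-minute segment selection, and automated ectopic-beat handling.
2. **HRV metrics** — mean RR, SDNN, RMSSD; spline-resampled tachogram,
   Welch-style spectral estimate, VLF/LF/HF band powers and the LF/HF ratio.
3. **Cohort statistics** — exclusion filters, TTD, a Monte-Carlo Lilliefors
   normality gate, Spearman correlations with confidence intervals.
4. **Synthetic data** — seeded generators for every input the other stages
   consume, with ground truth attached, so the whole chain is verifiable
   without clinical recordings.

## The beat generator: IPFM

Real RR series are emulated with the integral pulse frequency modulation
(IPFM) model: a beat fires at each integer crossing of

$$\int_0^{t_k} \frac{1 + \sum_i a_i \sin(2\pi f_i t + \phi_i)}{\bar T}\,dt = k,$$

with mean interval $\bar T$ and sinusoidal rate modulations $(f_i, a_i)$.
IPFM is used because it gives *direct control of spectral content*: a tone
at $f$ produces a spectral line at $f$ in the interval series, so band-power
code can be tested against planted truth. The integral is accumulated on a
1 ms grid with linear interpolation of crossing times; the residual timing
error is far below 1 ms, and an unmodulated run is metronomic to numerical
precision (SDNN $\approx 10^{-11}$ ms).

One subtlety matters when planting band powers: the interval series samples
the modulation by integrating it over each beat, which attenuates a tone at
$f$ by $\mathrm{sinc}(\pi f \bar T)$ — about 0.94 at 0.25 Hz versus 0.99 at
0.10 Hz for $\bar T = 0.8$ s. Equal *rate* amplitudes therefore do not give
equal *interval-series* band powers (the ratio is biased by ~13%). Wherever
the package plants a target band power or LF/HF ratio it works on the
interval-series scale, and tests that compare "matched" tones pre-compensate
amplitudes by $1/\mathrm{sinc}$.

```{r ipfm}
sim <- generate_rri_ipfm(tachogram_spec(800, list(c(0.25, 0.05)), 300, 1))
sim$truth$true_metrics
```

## Waveform synthesis

A beat is rendered as a single Gaussian pulse (default FWHM 20 ms); full
P-QRS-T morphology adds nothing to R-peak logic and is omitted. Pulse
centers are snapped to the nearest sample so the sampled maximum equals the
nominal amplitude exactly; the snap error is at most half a sample, well
under the 10 ms tolerance used when scoring detections. The EHG synthesizer
layers, onto a scaled pulse train: uterine contraction bursts (band-limited
noise in 0.1–3 Hz, the physiological uterine-EMG range, under raised-cosine
envelopes of 30–60 s, 2 events per 5 min by default), sinusoidal baseline
wander (0.02 Hz), and white noise. The achieved ECG-to-background power
ratio is reported in the ground truth; the default specification realizes
roughly 12 dB, a record with clearly visible R peaks. The generators emulate
the *structure* real records have (QRS over slow uterine activity, drift,
broadband noise, premature beats); they do not mimic the noise distribution
of any particular clinical database, so passing tests demonstrate
correctness of the machinery, not field performance on real EHG.

## Extraction parameters

| Parameter | Default | Why |
|---|---|---|
| High-pass cutoff (EHG) | 5 Hz | uterine activity and wander lie ≪ 5 Hz; QRS energy 10–40 Hz |
| High-pass cutoff (ECG) | 0.5 Hz | only drift removal needed on clean ECG |
| Filter | Butterworth order 4, forward–backward | zero phase, so peak timing is not shifted |
| Detection threshold | 0.4 × normalized max | on a max-1 signal, rejects background while keeping R peaks |
| Refractory period | 250 ms | 240 bpm ceiling; taller candidate wins |
| Segment | 300 s, non-overlapping from t = 0 | minimum recommended length for frequency-domain HRV; start of record favored, later windows used only if the first is too noisy |
| Segment quality gate | ≤ 5% corrected beats, ≥ 150 beats | windows failing every criterion exclude the record ("poorly detectable R peaks") |
| Ectopic flag | > 20% deviation from running median of 5 preceding unflagged intervals | automated surrogate for manual review (below) |
| Physiologic screen | 250–2000 ms | hard artifact bounds, always flagged |

The Butterworth design was checked numerically at the most demanding
operating point (0.5 Hz cutoff at 1000 Hz sampling, normalized frequency
0.001): the order-4 filter is stable there, and its stopband attenuation at
cutoff/10 exceeds 97.5% while a tone at 10× cutoff passes within 1%.

### Ectopic handling

Manual beat-by-beat review is not reproducible, so flagging is automated: a
premature beat produces a short interval followed by a compensatory pause,
both deviating far more than 20% from the local running median, so both are
flagged. Correction replaces each maximal flagged run by equal intervals
summing to the run's duration — the run mean. This reading is
duration-preserving (total series time is conserved to machine precision)
and idempotent; an alternative (neighbor interpolation) would not conserve
duration and was rejected. On injected ectopics with prematurity 0.6 the
flagger recovers ≥ 95% of planted flags, and correction restores the
time-domain metrics of the uncorrupted series.

## Spectral estimation

The corrected RR series is cubic-spline interpolated at 4 Hz (comfortably
above twice the 0.4 Hz upper band edge), each interval anchored at the beat
that ends it, linearly detrended, and analyzed with an averaged modified
periodogram: Hann-tapered 150 s segments at 50% overlap, one-sided density
scaled so its integral recovers the series variance (verified within 10%
for tones, 15% for white noise). Band powers are trapezoidal integrals of
the density over VLF 0.0033–0.04, LF 0.04–0.15 and HF 0.15–0.4 Hz, reported
as natural logs of the raw power in ms² — magnitudes 4–7 on realistic
records, matching conventional reporting — and LF/HF is the ratio of raw
(not log) powers. A 300 s segment covers barely one cycle of the VLF lower
edge, so VLF carries a `vlf_low_reliability` flag and no inference should
rest on it; tests that check VLF placement use 1200 s records with 300 s
windows, where the resolution (0.0033 Hz) actually resolves the band.

## Cohort statistics

**Exclusions.** Subjects delivering by induction or cesarean section are
removed (their timing is clinically, not physiologically, determined), as
are records failing the quality screen. The filter is idempotent and
order-independent and reproduces the documented rosters: 45 → 25 (4 induced,
6 cesarean, 10 poor R peaks) and 52 → 12 (40 non-physiological deliveries).

**Normality gate.** Because mean and variance are estimated from the
sample, the classical KS null is invalid; the Lilliefors test used here
draws its p-value from a seeded Monte-Carlo null (default 10,000 replicates
of the same sample size, same estimation step). The statistic matches the
standard implementation in `nortest` exactly; the Monte-Carlo null keeps
the type-I error at nominal level (verified at n = 50 over 2,000
replicates). HRV variables typically fail this gate, which is why the
correlation layer is rank-based.

**Spearman correlation.** Rho is the product-moment correlation of
mid-ranks (average ranks for ties). For n ≤ 9 the two-sided p-value is
exact, by full enumeration of all n! orderings (10! is already too large to
enumerate routinely); above that a t-approximation on n − 2 degrees of
freedom is used. The 95% CI uses the Fisher z transform with the
Bonett–Wright standard error $\sqrt{(1 + \rho^2/2)/(n-3)}$, the standard
choice for Spearman. No multiple-testing correction is applied by default —
the analysis is exploratory and reports all indices — but Benjamini–Hochberg
adjusted p-values are available (`adjust = "BH"`).

```{r spearman}
spearman_with_ci(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
```

## Planted cohorts and calibration

`generate_cohort()` draws TTD uniformly on 0–9.3 weeks (the span observed
in late-third-trimester cohorts of this kind) and ties true RMSSD and LF/HF
to TTD through a Gaussian copula: a planted Spearman $\rho_s$ is converted
to the latent Pearson correlation $2\sin(\pi\rho_s/6)$, and monotone
marginal transforms (truncated normal for RMSSD around 25 ± 13 ms,
log-normal for LF/HF around 0.7) preserve the rank correlation. Subject
dispersion *is* the copula's residual noise, and the achieved sample rho of
the true parameters is documented in the truth table's `planted` attribute.
Per-subject IPFM tone amplitudes then realize each subject's RMSSD and
LF/HF (tones at 0.01, 0.10, 0.25 Hz; the RMSSD of a tone of interval
amplitude $A$ at $f$ is $\sqrt2\,A\,|\sin(\pi f \bar T)|$, inverted to set
amplitudes), so the full signal pipeline can be run end to end against
planted cohort-level truth. With planted $\rho = +0.55$ (LF/HF) and
$-0.50$ (RMSSD) at n = 200, the pipeline's estimates land within ±0.15, the
sampling dispersion of Spearman's rho at that n.

Two calibration checks run on generator ground-truth metrics rather than
synthesized waveforms: the 200-replicate null-cohort false-positive rate at
n = 37 and the Lilliefors type-I sweep. The signal stage is separately
shown to recover SDNN/RMSSD within 5% (noise-free, 20 seeds) and to detect
beats with sensitivity/PPV ≥ 0.99 at ≥ 10 dB, so it is effectively an
identity on these statistics and cannot manufacture rank correlation under
the null; skipping waveform synthesis there keeps thousands of replicate
cohorts tractable. Problem sizes used throughout the checks: 5-minute
records at 200–1000 Hz, cohorts of 37 (null) and 200 (planted), 1,000
random series for the time-domain oracle, 2,000 + 10,000 replicates for the
Lilliefors calibration.

## Degenerate inputs and tie-breaks

* All-zero signals cannot be normalized; flat or sub-threshold signals
  raise an explicit "no peaks" error rather than returning an empty series.
* Two detection candidates inside one refractory window: the taller wins.
* A flagged run covering the whole series is unusable and errors.
* Constant samples error in both the Lilliefors test (zero SD) and Spearman
  (undefined ranks); a zero-width TTD range with a planted effect warns.
* Ectopic sites are sampled non-adjacent so flagged runs never merge and
  correction is unambiguous.

## Known limitations

* Automated ectopic flagging approximates, but is not, expert manual
  review; a review file of flagged beats can be emitted for override.
* VLF from 5-minute segments is reported for completeness only.
* Synthetic EHG exercises the detector's operating envelope; it is not a
  statistical model of any real electrode montage, skin preparation, or
  gestational-age-dependent noise. Field performance must be established on
  real recordings.
* The t-approximation for Spearman p at n > 9 is standard but approximate;
  exact enumeration is used wherever it is feasible.
* Single-channel processing only: no multi-electrode fusion, no fetal
  R-peak separation, no real-time operation.
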