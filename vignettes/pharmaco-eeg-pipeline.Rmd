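---
title: "Methods: filter-bank band power and rank-based longitudinal tests for pharmaco-EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: filter-bank band power and rank-based longitudinal tests for pharmaco-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmaeeg)
```

## Scope

`pharmaeeg` quantifies drug-induced changes in rodent cortical EEG as
band-power time courses and tests them with nonparametric rank-based
statistics for longitudinal factorial designs. The intended study shape is
a two-genotype mouse cohort (e.g. a receptor-subunit knockout line versus
wild-type littermates, n of order 8 + 9) recorded for a 24-h baseline and
then, per treatment, a 1-h pretreatment plus 5-h post-injection session.
Because raw recordings from such studies are rarely deposited, the package
ships a synthetic EEG/EMG generator with known ground truth; all
statistical guarantees are demonstrated on it.

## Spectral pipeline

Raw signals (typically 1000 Hz) are downsampled to the 200-Hz analysis
rate after an anti-alias FIR (Blackman window, 301 taps, cutoff 80 Hz,
stopband reaching the new Nyquist). The spectral decomposition is a bank
of 70 narrow bandpass FIR filters: low cutoffs 1.0 to 97.6 Hz in 1.4-Hz
steps, high cutoffs 2.6 to 99.2 Hz, i.e. constant 1.6-Hz widths with
0.2-Hz overlap between neighbours. Kernels are linear-phase Hamming-window
designs with 401 taps (2 s of support), enough to resolve the 1.6-Hz
passbands at the low end; filtering is zero-phase (FFT convolution with
reflection padding, group delay of (taps−1)/2 samples compensated
exactly). Each filtered channel is Hilbert-transformed and instantaneous
power is defined as the squared magnitude of the analytic signal
(envelope²). The choice between envelope and envelope² is not observable
in the package's outputs: every reported quantity is ratio-normalized, so
a monotone redefinition of "power" cancels for narrowband signals; we fix
envelope² so that power scales as amplitude squared, which the tests
assert.

Power is summarized as the median over each 4-s epoch (800 samples), the
robust statistic that tolerates brief residual artifacts. Epochs flagged
by an artifact mask keep their row indices but are excluded from every
downstream bin mean; artifact removal happens at this epoch stage rather
than by excising raw signal, so filter state is never discontinuous.
Masks can be supplied externally (TSV, 0-based `epoch_index`) or produced
by the built-in detector: an epoch is flagged when the EEG peak deviation
exceeds 6 robust SDs (MAD-based) or the epoch EMG RMS exceeds 6 times the
median epoch RMS. The EMG criterion captures movement artifacts with weak
EEG expression; both thresholds are exposed.

## Bands, binning and normalization

Filter-bank channels are averaged (unweighted) into seven bands by the
half-open rule "center frequency in [lo, hi)": delta 1–4, theta 4–8,
alpha 8–12, sigma 10–15, beta 12–30, gamma1 30–50, gamma2 50–100 Hz.
Sigma deliberately overlaps alpha and beta, so a channel (e.g. centered at
10.2 Hz) may contribute to two bands; the bands are computed independently
and the "total power" used for baseline normalization is the band sum,
counting shared channels in each band they belong to. Half-open ranges
make edge behaviour exact; with the default bank no center falls on an
edge.

Two normalizations mirror the two study arms:

* **Baseline (24-h) arm** — epochs are averaged into 1-h bins and each
  band is divided by the total over the seven bands in the same bin;
  normalized rows sum to 1 per bin (asserted to 1e−12).
* **Treatment arm** — epochs are averaged into 10-min bins anchored at
  the injection, and each band is divided by its own epoch-weighted mean
  over the pretreatment window [−60, 0) min; pretreatment means of the
  output are 1 by construction (asserted to 1e−9).

Bins with no kept epochs propagate as missing values with `n_epochs = 0`;
nothing is interpolated, and the statistics layer handles missingness
explicitly. Acute (0–2 h) and subacute (2–5 h) summaries are
epoch-weighted means over their windows.

## Rank-based longitudinal statistics

All observations of a dataset are ranked jointly with midranks (ties get
the mean of covered positions). The estimand per design cell is the
relative treatment effect (RTE) `(mean midrank − 0.5)/N`, a
probability-scale quantity whose observation-weighted mean is exactly 0.5.
Two designs are supported: one whole-plot factor × time (genotype ×
time; "F1-LD-F1") and two whole-plot factors × time (treatment ×
genotype × time; "F2-LD-F1"), with subjects — or subject-sessions in
crossover treatment studies — as independent units. Effects are expressed
as Kronecker contrasts of the cell RTE vector; the covariance of the cell
mean-rank vector is estimated from subject-level rank vectors per group,
block-diagonal across groups.

Two statistics are computed for every effect:

* **Wald-type (WTS)** — the quadratic form against the estimated
  covariance, chi-square reference with the contrast rank as df. This is
  the statistic whose df pattern matches the "χ², df = levels − 1"
  reporting convention of pharmaco-EEG papers. Known liberal at small n.
* **ANOVA-type (ATS)** — trace-normalized quadratic form with Box-type
  approximation for the numerator df. Effects involving time use the
  scaled chi-square (χ²_f/f) reference; purely whole-plot effects
  (genotype, treatment, their interaction) additionally get a
  Satterthwaite denominator df and an F(f, f0) reference. The denominator
  df matters: with groups of 8 and 9, the χ²/f reference makes the
  whole-plot ATS measurably liberal (null rejection near 0.075), while
  F(f, f0) restores nominal behaviour — the package's Monte-Carlo
  calibration tests assert rejection in [0.025, 0.085] and
  Kolmogorov–Smirnov uniformity of null p-values. This is the standard
  recommendation for between-subject contrasts in rank-based longitudinal
  models and is the package's default headline statistic.

Missing cells are handled by available-case estimation: pairwise-complete
covariances scaled by the pairwise/marginal counts, then projected onto
the positive-semidefinite cone by eigenvalue truncation (a no-op for
complete data; pairwise covariance matrices are otherwise not guaranteed
PSD and can produce negative trace normalizations). Entirely empty cells
are dropped from the contrast and named in the result's `note`; deleting
a subject changes the reported `n`. Nothing is imputed silently.

Multiplicity control is Bonferroni throughout, `p_c = min(1, m·p)` with
the cap-at-1 convention; families are the seven bands for omnibus tests
and the time bins tested within one band for per-bin post-hocs (rank-sum
comparisons with normal approximation). Corrected p-values map to the
three-tier severity convention (* p < 0.05, ** p < 0.001, *** p < 0.0001)
used in the report figures. Holm or FDR alternatives are deliberately out
of scope to keep parity with the field's reporting convention.

## The synthetic generator

The generator has two levels that share one effect model.

**Signal level** (`generate_recording`, `make_study`): each EEG channel is
a sum of per-band oscillators — white noise spectrally confined to
`center ± bandwidth/2` (band-limited noise rather than pure tones, so
band edges behave realistically), scaled so RMS equals `amplitude/√2` —
plus 1/f^a background noise (a = 1 by default). Amplitudes are modulated
by: a per-band genotype multiplier; a per-subject log-normal random
effect (SD 0.2 on the log scale, drawn once per subject) creating
realistic between-subject variance; and a drug profile evaluated in
minutes since injection. Artifacts arrive as a Poisson process (default
5/h), add half-second 10-robust-SD bursts to both EEG channels with a
coincident EMG burst, and are recorded in a ground-truth event log and
epoch mask. One master seed determines everything; per-recording streams
are derived by stable hashing of (subject, session), so adding a subject
never perturbs the others.

Drug profiles are per-band *amplitude* gain trajectories: linear ramp
from onset to peak, plateau to offset, exponential return to 1 (30-min
time constant), multiplied by an injection-stress transient (suppression
of delta–beta, increment of the gammas) that decays with a 10-min time
constant and is therefore maximal in the first 10-min bin — the vehicle
response. Spectral power scales as gain². The library profiles encode the
qualitative pharmacology: a delta/theta superagonist-like profile (delta
amplitude gain 2.0, theta 1.5, peak 30 min), a stimulant-like broadband
suppression (amplitude 0.75 everywhere except gamma1, sustained through
the acute window), and vehicle (stress only). The source study reports no
quantitative effect sizes, so these magnitudes are free parameters chosen
once as plausible; all acceptance is therefore *parameter recovery*
(does the pipeline detect the injected structure?) rather than value
matching.

**Summary level** (`simulate_band_study`): draws per-bin band powers
directly from the same model — baseline band power × genotype gain² ×
subject effect² × bin-averaged drug gain² × log-normal bin noise
(SD 0.15) — without synthesizing raw signal. Monte-Carlo calibration and
power studies run at this level (hundreds of replicates in seconds);
signal-level fidelity (that the spectral chain recovers band structure,
gains appearing squared, artifact exclusion) is established separately on
full recordings. What summary-level simulations cannot show: filter
leakage between bands, edge effects, artifact-detector interactions —
those are covered by the signal-level tests only, and real data will
additionally contain vigilance-state structure the generator does not
model at all.

## Problem sizes and numerical choices

Simulation-based checks use deliberate scales chosen to exercise the
study conditions while staying cheap: calibration uses 17 subjects
(8 + 9) × 24 one-hour bins × 500 replicates at the summary level; power
checks use 50 replicates of two-treatment crossover studies; signal-level
checks use minutes-to-hours of 200-Hz signal (the generator can produce
the full 24-h/1000-Hz sessions, which are simply larger). Zero-phase
filtering reflects the signal at the edges; the generalized inverses in
the statistics use an SVD pseudoinverse with tolerance 1e−10 relative to
the largest singular value; Bonferroni and tier thresholds are exact
comparisons.

Defaults worth knowing: analysis channel is the frontal EEG
(config-selectable — the source methodology does not state which
derivation was analyzed); epoch length 4 s; detector thresholds
`k_eeg = k_emg = 6`; treatment bins 10 min, baseline bins 1 h; windows
acute [0, 120) and subacute [120, 300) min. In crossover treatment
studies the independent unit defaults to (subject, session), matching the
"n ≈ subjects × treatments" accounting convention of the field's reports;
a subject-level unit can be used by passing a subject identifier instead.

## Limitations

No vigilance-state scoring or state-dependent spectra; no pharmacokinetic
realism beyond gain trajectories; no receptor-level modeling; no
confidence intervals for RTEs; EDF support covers the 16-bit
integer-second uniform-rate subset the pipeline writes. Printed
statistics from any particular animal study are not reproducible without
its raw data; the package's claims are the structural and calibration
properties its tests compute.
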