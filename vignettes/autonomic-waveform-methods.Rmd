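---
title: "Methods: quality-gated autonomic indices from ECG and ABP waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality-gated autonomic indices from ECG and ABP waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`autonomiq` computes subject-level autonomic-function indices from continuous
electrocardiogram (ECG) and arterial blood pressure (ABP) waveforms recorded
in intensive care, and classifies *early autonomic dysfunction* (eAD) from
their age/sex-standardized values. Long recordings are tiled into fixed
analysis segments (default 3600 s); each segment is quality-gated, beats are
detected and labeled, and five indices are computed per segment:

* **RMSSD** (ms) — root mean square of successive differences of sinus
  inter-beat intervals, a short-term vagal index;
* **LF power** (ms²) and **LF/HF** — Lomb-Scargle band powers of the
  beat-interval series over 0.04–0.15 Hz and 0.15–0.4 Hz;
* **heart rate turbulence** — turbulence onset (TO, %) and slope
  (TS, ms/beat) of the sinus response after premature ventricular
  contractions (PVCs), with TS operationalized as "the" HRT index and TO
  kept as an auxiliary value (normative statements for HRT are typically
  phrased as a TS bound, e.g. TS above 2.5 ms/beat);
* **baroreflex sensitivity** — phase-rectified signal averaging (PRSA) of RR
  around systolic-pressure-increase anchors, plus an
  autoregressive-exogenous (ARX) LF spectral gain.

Subject values are aggregated across quality-passing segments in the first
24 h (median by default; the mean is available), standardized per index
against an (age bin, sex) reference stratum, flagged when `|z| > 2.5`
(strict, two-sided), and the subject is classified eAD when **3 or more of
the 5** indices are flagged. The z-scores are retained as continuous
measures. Records without usable ECG run through an ABP-only path in which
pulse-to-pulse intervals (PPI) replace RR everywhere and HRT is structurally
missing (PVCs cannot be identified reliably without ECG).

Because the directionality of LF-power and LF/HF abnormality in acute brain
injury is genuinely ambiguous (plausible physiological arguments exist for
both elevated and depressed values), the classification rule is two-sided on
`|z|`; the per-index direction (`low`/`high`) is reported but never used by
the rule.

# Signal quality gate

**ECG image classification.** Each segment's leads are rasterized in the
standard paper-ECG layout (25 mm/s, 10 mm/mV, configurable px/mm, default
10 s per strip) with grid marks, mimicking a clinician's visual read. The
similarity of two multi-lead images is the mean over all M×M lead-strip
pairs of the global structural similarity index

$$\mathrm{SSIM}(x,y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
  {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)},$$

with the standard stabilization constants $C_i = (K_i L)^2$, $K_1 = 0.01$,
$K_2 = 0.03$, and $L$ the dynamic range. (One sometimes sees $K_2 \gg 1$
quoted; that reading breaks SSIM's boundedness, so the standard small
constant is the default and the literal value remains configurable.)
Templates are built per quality group (`good`/`poor`) by average-linkage
agglomerative clustering on `1 − SSIM` (3 clusters per group by default; the
count is a config key because no principled value exists), each cluster
represented by the member with maximal mean within-cluster SSIM (ties to the
lowest index). A linear-discriminant classifier on SSIM-to-template feature
vectors assigns `good`/`poor`. When training labels are absent, the initial
partition comes from 2-means clustering of each image's mean similarity to
the others.

**Lead selection.** For good segments the analysis lead maximizes a
composite of three per-lead signal quality indices: bSQI (consensus fraction
of beats agreed within 150 ms between the package's QRS detector and an
independent amplitude-threshold picker), sSQI (periodogram power fraction in
5–14 Hz relative to 1–40 Hz — the QRS-energy convention), and kSQI (excess
kurtosis). Each SQI is min–max scaled across leads and combined by weights
(default equal; the weighting is an expert-knowledge dial, so it is a config
key). Ties break to the lowest lead index.

**ABP pulse validation.** Pulses (onset-delimited, onset = minimum in the
0.5 s before each systolic peak) are spline-resampled to P = 100 samples and
standardized to zero mean, unit SD. A reference library of valid pulses is
decomposed by SVD; the signal subspace keeps the leading right-singular
directions capturing ≥ 95% of energy, and a pulse's score is the ratio of
signal-subspace to residual energy. The acceptance threshold is the
*minimum* ratio over the reference library, so every reference pulse is
valid by construction and anything resembling a library pulse passes. A
segment passes the gate when its ECG image is `good` **and** ≥ 80%
(configurable) of its ABP pulses are valid. The packaged reference library
is synthetic (the package renders ABP from a parametric pulse family and
harvests detector-extracted pulses, mirroring how test pulses are produced);
any user library of pulse vectors plugs in through `fitAbpSubspace()`.

# Beat detection and PVC labeling

**R peaks.** The ECG is band-passed 0.5–17 Hz (zero-phase Butterworth),
convolved with a zero-sum enhancement mask (−1 flanks, +2k center,
k = 50 ms of samples — a QRS upstroke span), min–max normalized within 2-s
windows advancing by 1 s, scanned in consecutive 0.3-s ranges with a
normalized threshold of 0.5, and the R peak is the absolute extremum of the
filtered signal within 0.24 s of each fiducial. Candidates from overlapping
windows are deduplicated by a 0.2-s refractory (largest amplitude wins). The
printed "0.5 mV" threshold is interpreted in *normalized* units since it is
applied after min-max normalization to 1 — the two statements are otherwise
contradictory. Window edges are zero-padded.

**Systolic peaks and onsets.** The ABP is Savitzky–Golay smoothed (0.2-s
window, order 3); per-window maxima above the pulsatile midline with a 0.3-s
refractory give systolic peaks, whose smoothed amplitude is the sBP sample.
A signal whose smoothed range is below 5 units is treated as non-pulsatile.

**PVC rules.** With at least 10 beats for a stable median-beat template,
stage 1 flags candidates satisfying ≥ 2 of: half-height QRS width > 120 ms,
amplitude > 1.5× the median beat amplitude, correlation with the median
template < 0.9 (all config keys — the underlying morphological rules are
qualitative). Stage 2 rejects false positives: a solitary candidate whose
correlation with the median beat is ≥ 0.9 is demoted; with multiple
candidates, widths (cW) are measured at three-fourths the height of the
smallest candidate, and a candidate is kept only when its morphology
deviation (1 − correlation) exceeds the median deviation of *all* beats and
its cW exceeds the median-beat template's cW at the same level. Anchoring
both thresholds to the full beat population (rather than to the candidate
subset) is a deliberate design choice: candidate-internal medians/means
necessarily demote about half of any set of near-identical genuine
ectopics, which contradicts the intent of rejecting only normal-shaped
false positives. Beats whose morphology window is truncated at a record
edge are never candidates. Detection metrics (Sen/Spec/Acc/F1) match beats
within 150 ms, with PVC as the positive class.

# HRT, HRV, BRS, coherence

**HRT.** A segment's HRT is computed only when more than 10 PVCs were
detected (the gate counts detected PVCs before eligibility filtering). Per
PVC event, eligibility demands 2 sinus RR before the coupling interval and
15 sinus RR after the compensatory interval, a coupling interval shorter
than the preceding sinus RR, and a compensatory interval longer than it; the
classical ±20% reference-interval filters are available behind
`strict = TRUE`. Then

$$TO = 100\cdot\frac{(RR_1+RR_2)-(RR_{-2}+RR_{-1})}{RR_{-2}+RR_{-1}},$$

and TS is the maximum least-squares slope over the 11 windows of 5
consecutive intervals within RR₁..RR₁₅ (negative when all windows decline).
Segment TO/TS are means over eligible events; with none, HRT is missing
with a reason.

**Spectra.** Because beat intervals are irregularly sampled, band powers
use the classical Lomb-Scargle periodogram (tau-shifted form) of the
mean-subtracted series — no interpolation — scaled to a one-sided density
(2·P·mean beat period) whose integral approximates the series variance, on
a fixed grid 0.003–0.5 Hz, step 0.001 Hz (configurable). Bands are
half-open at the shared edge (LF [0.04, 0.15), HF [0.15, 0.4]); LF/HF is
reported missing when HF < 10⁻⁶ ms² to avoid division blow-up. Note the
fixed 1-mHz grid overestimates the band power of a *pure line spectrum*
whose Fejér lobe (width ≈ 1/T) is narrower than the grid step — for
hour-long segments this affects idealized sinusoidal fixtures, not
broadband physiological variability; ratios such as LF/HF are unaffected.

**PRSA-BRS.** Anchors are beats whose sBP strictly increased (equal values
are not anchors), excluding anchors within L beats of either edge; windows
of 2L+1 RR values (L = 15, i.e. 15 beats on each side — the natural reading
of the windowing once offsets span −L..L) are averaged into the PRSA
profile X(l), and

$$BRS = \tfrac14\,(X_0 + X_1 - X_{-1} - X_{-2}).$$

Under a ±1-mmHg random-walk sBP with gain G and small jitter the estimator's
conditional-expectation value is exactly G/2 (the anchor conditions one
increment; the rest average out), which the tests use as an oracle.

**ARX-BRS.** The model $RR_k = \sum_{i=1}^{N} a_i RR_{k-i} +
\sum_{j=0}^{N} b_j sBP_{k-j} + e_k$ (one shared order N = 8, b starting at
lag 0) is fitted by least squares on mean-removed series; fits with an
unstable AR polynomial are reported missing with a diagnostic. The index is
the *plain* LF-band PSD ratio $\alpha_{LF} = P_{RR}(LF)/P_{BP}(LF)$
evaluated from the fitted model's spectra (ARX output spectrum over an AR
estimate of the sBP input spectrum). The conventional α-index is the square
root; both are reported (`alpha_sqrt`), and classification uses the plain
ratio as printed. The plain form is scale-*covariant* (multiplying RR
deviations by c multiplies it by c²) — a property the tests verify — so its
units are ms²/mmHg².

**Coherence.** PPI and sBP series are cubic-interpolated to a uniform 4-Hz
grid, passed through a Gaussian kernel whose −3 dB point is 10 Hz on the
continuous representation (at 4 Hz sampling this kernel is narrower than
one sample and acts as identity — the 10-Hz figure is retained as stated
even though beat-derived variability lives far below it), and compared by
Welch magnitude-squared coherence (120-s segments, 50% overlap, Hann).
Welch averaging over K segments bounds the coherence bias of independent
series near 1/K, which the tests exploit.

# Standardization and classification

The reference table (`inst/extdata/reference_ranges_synthetic.csv`, columns
`age_lo,age_hi,sex,index,mean,sd,source`) ships as an explicitly *synthetic
stand-in*: RMSSD, TS and BRS strata derive from published normal ranges
(RMSSD 19–75 ms, TS > 2.5 ms/beat, BRS 4.87–34.07) read as mean ± 2 SD, and
the LF-power / LF/HF strata are plausible placeholders; no clinically
validated normative claim is made, and any user table with the same columns
replaces it. Age bins are decades (20–89) with nearest-bin fallback outside
the table. A missing index is conservatively counted non-abnormal.
`dailyTrajectory()` repeats the aggregation per 24-h bin over the first five
days.

# The synthetic generator

The generator exists so every stage has ground truth. RR-domain additive
modulation was chosen over integral-pulse-frequency modulation because it
gives closed-form oracles:
$RR_k = RR_0 + A_{LF}\sin(2\pi f_{LF}t_k) + A_{HF}\sin(2\pi f_{HF}t_k) +
\varepsilon_k$ with cumulative beat times. Defaults describe a healthy
adult: RR₀ = 850 ms, LF 30 ms at 0.10 Hz, HF 40 ms at 0.25 Hz, jitter SD
5 ms — RMSSD then sits mid-range of the 19–75 ms normal span by the
sinusoid-difference closed form. PVCs are injected with coupling fraction
0.6 of the preceding RR and a *full compensatory pause*
(compI = 2·RR − couplI, the classical electrophysiology convention), then
an early acceleration of 20 ms followed by per-beat lengthening (default
8 ms/beat over 10 beats) whose increment is the TS truth under zero
modulation. The sBP processes are a ±1 mmHg/beat random walk and a
1 mmHg/beat triangular ramp, both bounded at ±15 mmHg so RR stays positive
at physiological gains; closed-loop RR is regenerated as
$RR_k = RR_0 + G\,(sBP_k - sBP_0) + \varepsilon_k$. The default gain is
G = 15 ms/mmHg, the midpoint of the adult spontaneous-BRS span. Waveforms
are rendered from Gaussian-bump P-QRS-T templates (ectopics wide >120 ms at
half height, 1.8× amplitude, discordant, no P wave) at 250 Hz ECG / 125 Hz
ABP, with one ABP pulse per beat whose systolic amplitude equals the
requested sBP. Corruption adds white noise, baseline wander (< 0.5 Hz),
flatline stretches and motion bursts with a truth mask.

What the generator does *not* emulate: respiration mechanics and
IPFM-style modulation (an IPFM mode is a flag, not the default),
arrhythmias beyond isolated PVCs, vasomotor sBP dynamics beyond the simple
processes, electrode-pop and pacing artifacts. Passing tests therefore
demonstrate correctness of the computational pipeline on signals with known
structure, not clinical performance on real ICU waveforms.

Cohorts are drawn at two levels: index-level (subject index values sampled
from healthy or displaced reference distributions — the default for testing
the classification chain at scale) and spec-level (full generator
specifications per subject for end-to-end runs).

# Numerical choices and problem sizes

Zero-variance inputs are rejected or produce defined missing values
(flat ECG → no beats; flat ABP pulse → invalid; zero-variance sBP in ARX →
error). A pulse lying exactly in the signal subspace receives a large
sentinel ratio and is valid. Ties break deterministically (lowest index)
throughout. WFDB I/O uses the format-16 subset with per-channel integer
gains near 30000/max|x|, so round-trip error is below 1/gain; beat
annotations are plain text `time_s,label`. The test suite runs on scaled
fixtures — tens of seconds to a few minutes of waveform at 125–250 Hz,
tachograms of 10²–10³ beats, 1-h tachograms only where the segment gate
itself is under test — sizes chosen so the full suite completes in well
under a minute while every decision rule is exercised at its boundary.

# Known limitations

* The eAD classification is only as meaningful as the reference table; the
  packaged table is a labeled synthetic stand-in.
* The rule-based PVC detector targets isolated wide-complex ectopics;
  bigeminy, couplets and non-PVC arrhythmias are out of scope, and a
  plug-in hook accepts any external segment classifier.
* The ARX estimator assumes an open-loop sBP→RR transfer; closed-loop
  identification beyond the printed model form is not attempted.
* Quality gating rejects segments; it never repairs artifacts.
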