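---
title: "Methods: the Polyscore risk markers, their computation, and the synthetic validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Polyscore risk markers, their computation, and the synthetic validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The score and its constituents

The Polyscore is a composite cardiac risk score for patients with a
30-minute supine resting recording of high-frequency ECG, continuous
arterial blood pressure (finger photoplethysmography) and thoracic
respiration. Seven markers, each quantifying a facet of cardiovascular
autonomic control, are computed from the recording and dichotomized at
established cutoffs; the Polyscore is simply the number of abnormal
markers, an integer from 0 to 7. Scores of 0–2 define a low-risk class,
3–4 intermediate, and 5–7 high risk.

| marker | quantity | units | abnormal when |
|---|---|---|---|
| TS | heart rate turbulence slope | ms/RR | $\le 2.5$ |
| DC | deceleration capacity | ms | $\le 2.5$ |
| BRS | baroreflex sensitivity | ms/mmHg | $\le 1.58$ |
| RESP | resting respiration rate (final 10 min) | breaths/min | $\ge 18.6$ |
| ETA | expiration-triggered sinus arrhythmia | ms | $\le 0.19$ |
| PESP | post-ectopic systolic potentiation ratio | — | $\ge 1.03$ |
| ECTOPY | SVE / VE counts per 30 min | counts | $> 7$ or $> 29$ |

Boundary semantics are exactly as printed above ($\le$, $\ge$, strict
$>$), and all cutoffs live in `default_thresholds()` as data, so a user
can swap in alternative dichotomies without touching code. The RESP, ETA
and ECTOPY sides are the explicitly published conventions; for the
remaining markers the "low value = risk" side (and "PESP present = risk")
follows the cited marker literature and is configurable.

## From waveforms to beats

Beat detection is a Pan–Tompkins-style chain: band-pass 5–30 Hz
(second-order Butterworth, zero-phase), squared derivative, 150 ms
moving-window integration, adaptive threshold at 35% of a robust
per-recording energy reference (median of ten per-segment maxima), 200 ms
refractory period, and refinement of each event to the local maximum of
the band-passed ECG. Detection runs on the X lead and falls back to the
vector magnitude $\sqrt{x^2+y^2+z^2}$ when the detected rate leaves
30–150 beats/min.

QRS width — needed to separate ventricular from supraventricular ectopy —
is estimated by a truncated second moment: within ±150 ms of the R peak,
samples above 20% of the peak amplitude contribute to an
amplitude-weighted second moment of time, which is converted to a
Gaussian-equivalent $\sigma$ (with the analytic correction for the 20%
truncation) and reported as $6\sigma$. The truncation makes the estimate
indifferent to low-level baseline noise; the Gaussian calibration matches
the shapes the synthetic renderer produces and is a reasonable surrogate
for real QRS complexes at the accuracy the 120 ms wide/narrow decision
needs.

Classification rules (`classify_beats()`): a beat is premature when its
coupling interval is below 80% of the local median sinus RR (median over
the surrounding ±5 intervals). Premature + (wide QRS > 120 ms **or**
compensatory pause, i.e. coupling + pause within ±10% of twice the local
median) → `V`; premature + narrow + resetting pause → `S`; RR outside
300–2000 ms → `X`; otherwise `N`. These three numbers (80%, 120 ms, ±10%)
are exposed as configuration; they are conventional electrophysiology
rules, not quantities with a single published value.

Artifact filtering (`filter_artifacts()`) relabels as `X` any beat whose
RR leaves 300–2000 ms, and any *normal-to-normal* interval deviating more
than 25% from the running median of the last five accepted sinus
intervals. The NN restriction matters: coupling intervals and
compensatory pauses of recognized ectopic beats are physiology the
turbulence and potentiation markers depend on, so the jump rule must not
see them. Consequently the pipeline classifies first and filters second,
and the composition is idempotent.

Per-beat systolic pressure is the maximum of the pressure waveform in
the window from each R peak to half of the following RR interval. Values
outside 50–250 mmHg are kept but flagged invalid, preserving beat
alignment (deleting them would silently shift every downstream
beat-aligned computation). Breaths are detected on the respiration
channel decimated to ~8 Hz and band-passed to 0.05–1 Hz: breath onsets
are interpolated upward zero crossings; expiration onsets are the
end-inspiration maxima between consecutive onsets. A breath-interval
coefficient of variation above 0.35 is treated as "no oscillation":
resting breathing is quasi-periodic (CV well below 0.2) while zero
crossings of band-passed noise run a CV near 0.5, so the rule separates
the two regimes with a wide margin.

## Phase-rectified signal averaging

PRSA extracts quasi-periodic structure from a noisy beat series by
averaging windows aligned at anchors chosen by a criterion. With anchors
$i_1,\dots,i_M$ and half-window $L$ (default 20 beats),

$$\bar X(k) = \frac{1}{M}\sum_{m} x_{i_m + k}, \qquad k = -L,\dots,L-1,$$

and the scalar used by DC, BRS and ETA is the *quartet*

$$Q = \tfrac14\left(\bar X(0) + \bar X(1) - \bar X(-1) - \bar X(-2)\right),$$

a central estimate of the signal change across the anchor. Anchor
criteria: `rr_increase` ($x_i > x_{i-1}$, with an eligibility ceiling of
a 5% relative increase so that pauses and artifacts cannot anchor the
average) for DC; `bp_rise` ($s_i > s_{i-1}$ on the systolic series) for
BRS; and expiration-onset events, each mapped to the first beat at or
after the event, for ETA. BRS is the ratio of the RR quartet to the SBP
quartet at the same anchors, in ms/mmHg; this ratio-of-quartets
normalization is fixed here as the package's contract and recorded in the
marker's provenance, since only the units are pinned by the marker
literature. An SBP quartet below 0.05 mmHg is treated as a degenerate
anchor set (no pressure dynamics above measurement resolution) rather
than divided by.

Anchors must carry full windows, at least 5 anchors are required for a
PRSA marker to be evaluable, and anchors are excluded within ±2 beats of
any non-sinus beat — extended to 16 beats *after* a ventricular ectopic,
because the heart rate turbulence transient is a baroreflex response to
the ectopic, not the ongoing vagal modulation DC/BRS/ETA quantify, and
letting it anchor the averages measurably biases BRS downward.

Turbulence slope itself is computed from VPCs directly: eligible VPCs
(coupling < 80%, pause > 120% of the local sinus median, ≥ 5 sinus
intervals before and ≥ 15 after) contribute their 15 post-pause sinus
intervals; the tachograms are averaged across VPCs, and TS is the maximum
least-squares slope over the 11 windows of 5 consecutive intervals (ties
to the earliest window). PESP divides the first post-ectopic sinus
systolic pressure by the mean of post-ectopic sinus beats 2–6 and
averages the ratio across eligible VPCs; "beats 2–6" is this package's
concrete reading of "the following sinus rhythm cycles", and averaging
across VPCs (rather than a single representative one) is likewise a fixed
choice.

**No-VPC policy.** A recording without eligible ventricular ectopy cannot
produce TS or PESP. By default such markers contribute "normal" (0) to
the score — consistent with the turbulence literature's treatment of
VPC-free patients as non-high-risk — with a configuration switch
(`no_vpc_policy = "exclude"`) that instead marks the analysis incomplete,
for users who prefer exclusion.

## The survival layer

Cohort validation uses the standard machinery, wrapped so the contracts
are fixed: Kaplan–Meier with Greenwood variance and log(−log)-transformed
95% pointwise intervals; the log-rank test; Cox proportional hazards with
Efron tie handling (Breslow selectable) and Wald statistics per
covariate; per-stratum hazard ratios as seven univariable indicator fits,
each restricted to subjects in strata $\{0,\varphi\}$; and a log-rank
cutoff optimizer that scans a candidate grid, skips degenerate splits,
and breaks ties toward the smaller abnormal group. Times are carried in
days internally with a 5-year horizon in mind for display. Multivariable
fits are complete-case. Two-sided 5% significance is used throughout.

## What the synthetic generator emulates

`physio_profile()` + `synthesize_recording()` produce a recording in
which every marker has a programmed ground truth:

* **Tachogram** — mean RR 900 ms; RSA as $-A\cos(2\pi f t + \phi_0)$
  evaluated at each interval's end (so RR lengthens through early
  expiration, which is what the ETA anchor measures), default
  $A = 15$ ms at 15 breaths/min; a slow 10 ms drift; white jitter of
  2 ms SD. The jitter default is deliberately the *residual* unmodelled
  variability: respiratory and baroreflex-driven variability — the
  dominant sources in supine rest — are modelled explicitly, and the
  turbulence-slope statistic (a maximum over 11 noisy regression slopes)
  must remain identifiable at the VPC counts a 30-minute recording can
  contain, which bounds the admissible white-noise floor at about
  2–2.5 ms.
* **Ectopy** — VPCs replace a sinus beat with 60% coupling, a pause
  completing $2\times$ the sinus RR, and a 15-beat two-phase turbulence
  pattern (2-beat dip, 8-beat linear rise at the programmed slope, 5-beat
  decay) whose maximum 5-beat regression slope equals the programmed
  slope exactly in the noise-free limit. Inside this window RSA and
  baroreflex modulation are suppressed, modelling the transient's
  physiological precedence; white jitter remains. SVEs are narrow
  premature beats with a resetting pause.
* **Pressure** — per-beat systolic values carry a 5 mmHg Mayer-wave
  oscillation (period 9.3 s — deliberately incommensurate with typical
  respiratory periods, since rationally locked oscillators would let LF
  power alias coherently into the expiration-anchored averages, an
  artifact real, non-phase-locked physiology does not show) plus 1 mmHg
  noise; the ectopic beat's own pulse is attenuated to 75%; the first
  post-ectopic pressure is multiplied by $1 + \text{pesp fraction}$.
* **Baroreflex coupling** — each unprotected sinus RR gains
  $G\,(s_i - \bar s)$ ms, so the bivariate-PRSA quartet ratio equals $G$
  by construction. Because this coupling moves the beats, the RSA term is
  re-phased to the final beat times afterwards; without that re-phasing
  the accumulated per-beat shifts desynchronize the tachogram from the
  rendered respiration oscillator and destroy the ETA ground truth.
* **Rendering** — Gaussian QRS templates (90 ms support for N/S, 140 ms
  for V; X/Y/Z amplitudes 1.2/0.7/0.5 mV), Gaussian systolic pulses
  peaking 150 ms after each R wave over a 75 mmHg baseline, a unit
  sinusoid respiration, all at 250 Hz by default — sufficient for the
  detector and the width-based V/S decision, with R-peak timing accuracy
  of a few ms.

`generate_cohort()` draws stratum membership from the observed stratum
proportions (239, 261, 182, 133, 86, 24, 9, 7 of 941), exponential event
times with per-stratum yearly hazards calibrated to the observed 5-year
per-stratum mortality, administrative censoring at 5 years and a small
independent loss-to-follow-up process; marker flags are drawn uniformly
among the combinations consistent with each stratum.

**What it does not emulate** — and hence what passing tests do not show
about real data: nonstationary breathing and posture changes, real QRS
morphology and its detector failure modes, atrial fibrillation or ectopy
runs (bigeminy, couplets), pressure-calibration drift of the finger cuff,
movement artifact, and any correlation structure between markers within
a patient beyond what the stratum flags impose. Recovery of programmed
parameters on this generator validates the *computational* chain, not
clinical performance.

## Numerical choices and degenerate inputs

* Respiration-rate window is half-open, $[T-600, T)$ s, so a breath onset
  exactly at the boundary is counted once; with the default non-zero
  respiration phase, onsets do not coincide with window edges.
* TS window ties go to the earliest window; dichotomies use the printed
  boundary semantics exactly.
* Flat ECG or respiration yields empty results with warnings, never
  exceptions; markers below their minimum support (5 anchors, 30 breaths,
  1 eligible VPC) report "not evaluable" instead of numbers.
* Cox fits run Newton–Raphson to a $10^{-10}$ tolerance with at most 100
  iterations; empty strata yield `NA` hazard-ratio rows rather than
  errors.
* The cutoff optimizer's default candidate grid is the midpoints of
  consecutive sorted unique values, which makes it invariant under
  strictly monotone transformations of the marker (with the grid
  transformed likewise).

Test problem sizes were chosen to keep the full suite fast while leaving
the statistical checks well-powered: unit tests synthesize 700 s
recordings at 200 Hz, the end-to-end recovery checks use the full
30-minute, 250 Hz conditions (including a 100-recording flag-recovery
sweep), and the survival-layer ladder check uses a 5000-subject cohort
with hazards $h_0\,6^{\varphi/3}$, whose fitted per-point log hazard
ratio slope recovers $\ln(6)/3 \approx 0.597$.

## Known limitations

The V/S discrimination is a two-rule surrogate for morphology analysis
and will misclassify aberrantly conducted supraventricular beats; the
width estimator is calibrated to Gaussian-like complexes; the Portapres
pressure is taken as recorded, with no calibration-step handling; the
no-VPC policy, PESP denominator and BRS normalization are fixed package
contracts where the marker literature leaves latitude — each is
configurable and recorded in the result's provenance so that downstream
users can see exactly which conventions produced a score.
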