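# polyscore

Composite autonomic risk stratification for cardiac patients from a
single 30-minute non-invasive recording.

Survivors of myocardial infarction differ widely in their mortality risk,
and single markers (ejection fraction, individual autonomic indices)
separate risk groups poorly. The Polyscore approach computes **seven**
risk markers from one simultaneous supine resting recording of
high-frequency orthogonal-lead ECG, continuous finger arterial pressure
and thoracic respiration, dichotomizes each at an established cutoff, and
counts the abnormal ones:

| # | marker | abnormal when |
|---|--------|----------------|
| 1 | heart rate turbulence slope (TS) | ≤ 2.5 ms/RR |
| 2 | deceleration capacity (DC) | ≤ 2.5 ms |
| 3 | baroreflex sensitivity (BRS, bivariate PRSA) | ≤ 1.58 ms/mmHg |
| 4 | respiration rate, last 10 min | ≥ 18.6 breaths/min |
| 5 | expiration-triggered sinus arrhythmia (ETA) | ≤ 0.19 ms |
| 6 | post-ectopic systolic potentiation (PESP) | ratio ≥ 1.03 |
| 7 | ectopy frequency | > 7 SVE or > 29 VE per 30 min |

The Polyscore φ ∈ {0,…,7} is the number of abnormal markers; φ ≤ 2 is
low risk, φ ∈ {3,4} intermediate, φ ≥ 5 high risk. DC, BRS and ETA are
all built on phase-rectified signal averaging (PRSA): windows of the RR
series are aligned at anchors (RR prolongations, systolic pressure rises,
or expiration onsets) and averaged, and the quartet
(X(0)+X(1)−X(−1)−X(−2))/4 summarizes the modulation in the target's
units. The package implements the whole chain — waveform I/O (CSV, WFDB
format 16, EDF), automated beat detection/classification/artifact rules,
PRSA, the seven markers, the score — plus the survival-analysis layer
used to validate such a score on a cohort (Kaplan–Meier with log(−log)
95% intervals, log-rank, Cox models with Efron ties, per-stratum hazard
ratios vs stratum 0, log-rank-optimal cutoffs), and a synthetic generator
producing recordings and cohorts with known ground truth.

## Worked example

Synthesize a healthy-physiology 30-minute recording (RSA 15 ms,
baroreflex gain 8 ms/mmHg, 10 ventricular ectopics with turbulence slope
8, no potentiation) and analyze it end to end:

```r
library(polyscore)
syn <- synthesize_recording(physio_profile(seed = 42))
res <- analyze_recording(syn$recording)
print(res)
#> <polyscore_result> synthetic-42
#>          name   value       units threshold  abnormal_side abnormal evaluable n_support
#> TS         TS    8.28       ms/RR       2.5 below_or_equal    FALSE      TRUE        10
#> DC         DC 12.3333          ms       2.5 below_or_equal    FALSE      TRUE       780
#> BRS       BRS 8.08973     ms/mmHg      1.58 below_or_equal    FALSE      TRUE       874
#> RESP     RESP      15 breaths/min      18.6    at_or_above    FALSE      TRUE       150
#> ETA       ETA 10.9521          ms      0.19 below_or_equal    FALSE      TRUE       397
#> PESP     PESP 1.02186       ratio      1.03    at_or_above    FALSE      TRUE        10
#> ECTOPY ECTOPY    0;10 count/30min      7;29          above    FALSE      TRUE        10
#> Polyscore 0 -> low risk
```

Every marker lands near its programmed ground truth (TS 8.28 vs 8, BRS
8.09 vs 8, respiration 15/min exactly, PESP ≈ 1 with no programmed
potentiation, 10 ventricular ectopics recovered), all seven dichotomies
are normal, and the recording scores Polyscore 0.

The survival layer on a synthetic 941-patient cohort whose stratum sizes
and per-stratum hazards are calibrated to a published post-infarction
population:

```r
co  <- generate_cohort(cohort_spec(seed = 42))
shr <- stratum_hazard_ratios(co)
round(shr[c("stratum", "n", "events", "hr", "lower", "upper")], 2)
#>   stratum   n events     hr lower   upper
#> 1       1 270      9   4.22  0.91   19.53
#> 2       2 163      2   1.54  0.22   10.96
#> 3       3 124     11  11.47  2.54   51.74
#> 4       4  97     25  36.74  8.70  155.17
#> 5       5  27     13  79.58 17.91  353.57
#> 6       6   4      3 161.98 25.73 1019.63
#> 7       7   5      4 144.60 25.97  805.13

lr <- logrank_test(co$followup_days, co$event, classify_risk(co$polyscore))
sprintf("chi2 = %.1f (df = %d)", lr$chisq, lr$df)
#> "chi2 = 225.2 (df = 2)"
```

The hazard ratios versus stratum 0 climb near-exponentially across the
Polyscore ladder, and the three risk classes separate sharply in the
log-rank comparison.

A thin command-line interface is installed with the package
(`exec/polyscore`): `polyscore analyze --recording rec.csv --out
report.json`, `polyscore cohort --cohort cohort.csv --out summary.json`,
`polyscore simulate recording|cohort --seed N --out …`, with exit code 2
flagging analyses with non-evaluable markers.

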