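---
title: "Nonparametric circadian statistics for high-frequency accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonparametric circadian statistics for high-frequency accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actirhythm)
```

## The problem

Modern wrist-worn accelerometers record activity continuously for weeks at
sampling periods of a few seconds. The activity signal analysed here is ENMO
(*Euclidean norm minus one*): the per-sample norm of the three acceleration
axes minus 1 g of gravity, floored at zero. From such a series one wants
stable summaries of the rest–activity rhythm: how strongly the daily pattern
repeats, how fragmented activity is within a day, and how the correlation
structure of activity scales across time. `actirhythm` implements four
nonparametric statistics for this purpose, together with a synthetic
generator that makes each of them verifiable against analytic ground truth.

## The statistics

**Interdaily stability (IS).** With $\bar X_s$ the mean over all samples
whose clock hour is $s$ ($s = 1..24$, pooled across days) and $\bar X$ the
overall mean,
$$\mathrm{IS} = \frac{\sum_{s=1}^{24}(\bar X_s - \bar X)^2 / 24}
                    {\sum_{t=1}^{N}(X_t - \bar X)^2 / N}.$$
Both variances are population variances (divide by 24 and by $N$), so
$\mathrm{IS} \in [0, 1]$ by the variance decomposition; a series that is an
exact function of clock hour attains 1. Hour bins are clock hours; partial
first/last days contribute to whichever bins they cover. An empty hour bin
or a constant series is an error, not a silent zero.

**Intradaily variability (IV).** For a subsampling factor $\Delta$, phase
$j$ ($1 \le j \le \Delta$) of the series is
$Y^{[j]}_k = X_{(k-1)\Delta + j}$, $k = 1..M$, $M = \lfloor N/\Delta
\rfloor$, and
$$\mathrm{IV}^{[j]} =
  \frac{\sum_{k=2}^{M}(Y^{[j]}_k - Y^{[j]}_{k-1})^2 / (M-1)}
       {\sum_{k=1}^{M}(Y^{[j]}_k - \bar Y^{[j]})^2 / M},
  \qquad \mathrm{IV} = \frac{1}{\Delta}\sum_{j=1}^{\Delta}\mathrm{IV}^{[j]}.$$
Averaging over all $\Delta$ phases uses every sample regardless of
$\Delta$ (at most $\Delta - 1$ trailing samples are lost to the floor).
For i.i.d. data $E[\mathrm{IV}] \approx 2$ at any $\Delta$; persistent,
smooth series score lower. Phases with zero variance (near-constant
nighttime stretches) are skipped with a warning rather than poisoning the
average. `ivSweep()` evaluates IV across factors; on 5-second data the
recommended subsampling is 5 minutes, with 2–10 minutes acceptable
(`ivRecommendedDelta()`): shorter intervals are dominated by short-lag
autocorrelation, longer ones wash out between-subject contrast.

**DFA scaling exponent.** The profile $Z_t = \sum_{u \le t}(X_u - \bar X)$
is tiled from the head of the series into $\lfloor N/S \rfloor$
non-overlapping segments of length $S$; a least-squares line is removed per
segment; the per-segment RMSD divides by $S$ (population form); and
$F(S)$ is the root mean square of the segment RMSDs. The exponent $\alpha$
is the unweighted OLS slope of $\log_2 F$ on $\log_2 S$ over the grid
$S = \mathrm{round}(2^i)$, $i = 4, 4.25, \ldots, 8$ (16–256 samples;
1.333–21.333 minutes at 5-second sampling; duplicates after rounding are
deduplicated, and the 16-sample minimum respects the usual
more-than-10-samples rule of thumb). $\alpha = H$ for stationary
noise-like series and $H + 1$ for walk-like series: white noise 0.5, 1/f
pink noise 1.0, a random walk 1.5. `dfaDayNight()` estimates separate
daytime and nighttime exponents after the clock partition below.

**Proportion of variance (PoV).** The periodogram
$I(f) = \tfrac1N\left|\sum_t (X_t - \bar X)e^{-2\pi i f t\,dt}\right|^2$ on
the Fourier grid distributes the variance over frequency. PoV sums the
two-sided periodogram mass over the narrow band of periods 23.5–24.5 h
around the circadian fundamental ($1/88200$ to $1/84600$ Hz), and, for
$\mathrm{PoV}^{(H)}$, over the integer harmonic multiples $k = 2..4$ of
those edges, then divides by the total two-sided mass. No smoothing or
tapering is applied: the band itself already averages neighbouring
frequencies. The parametric comparator `cosinorR2()` fits
$X_t = M + a\cos(\omega t) + b\sin(\omega t)$ at the fixed 24-h period by
exact linear least squares and reports $R^2$.

## Numerical and design choices

* **ENMO truncation.** The gravity subtraction leaves small negative
  residuals; these are floored at zero (the standard ENMO definition), which
  matches the hard floor visible in real wrist data. Absolute-valuing was
  the rejected alternative.
* **Missing data.** Recordings are cleaned by dropping whole calendar days
  that contain any gap (inter-sample interval beyond 1.5 dt, a threshold
  robust to timestamp jitter without masking dropouts) or any absent
  expected sample. Dropping whole days — rather than splicing arbitrary
  ranges — preserves every retained sample's time of day, which IS, the
  day/night split and the daily profile all depend on. Timestamps are naive
  local time; no daylight-saving adjustment is made.
* **Day/night split.** Day is [06:00, 23:00) and night [23:00, 06:00) by
  default, half-open on the clock. For DFA the per-day segments of each
  class are concatenated into one long stream: DFA needs series much longer
  than its largest scale, and the splice points at the boundaries are an
  accepted approximation. A per-day mode (`perDay = TRUE`) that estimates
  per block and averages is provided for sensitivity analysis.
* **PoV normalisation.** The band definitions are integrals of a continuous
  spectrum; on the discrete Fourier grid the package uses the ratio of
  two-sided periodogram sums (band over total), which by Parseval is exactly
  the fraction of variance and keeps $\mathrm{PoV} \in [0,1]$ with
  $\mathrm{PoV}^{(F)} \le \mathrm{PoV}^{(H)}$. The nominal $N-1$ sample
  variance denominator differs from the Parseval total by $(N-1)/N$, a
  relative discrepancy of at most $1/N$; the sample variance is reported in
  the result object. Band edges are inclusive; whether ordinates should
  instead be trapezoid-integrated is not determined by the definitions, and
  the ratio-of-sums form was chosen for exact normalisation.
* **Degenerate inputs.** Zero-variance series are errors everywhere
  (IS, IV, periodogram, cosinor, DFA); a DFA scale grid too large for the
  series reports the maximum usable scale; an empty clock partition warns
  and returns an empty stream; metrics that fail inside `computeMetrics()`
  become NA with a warning, never a silent zero.

## The synthetic generator and what a green test establishes

`simulateCircadian()` builds
$X_t = \max(0,\ b + \sum_k A_k \cos(2\pi k t\,dt/86400 + \phi_k) +
\epsilon_t)$ with white or AR(1) noise. The defaults describe a realistic
able-bodied wrist recording at the reference device settings: 7 days at 5-s
sampling, baseline 0.05 g, harmonic amplitudes (0.04, 0.02, 0.01, 0.005) g
with the activity peak at 14:30, noise sd 0.03 g — ENMO mostly between 0 and
0.2 g, high by day and low by night. Rectification at zero (not shifting)
reproduces ENMO's hard floor. `simulateNoise()` provides the calibration
processes: white noise, 1/f pink noise by spectral synthesis (deterministic
$f^{-1/2}$ amplitudes, uniform random phases — the target spectrum is exact,
with no filter warm-up), and a random walk whose increments are the white
draw from the same seed. All generators are bit-for-bit reproducible given
a seed and restore the caller's RNG state.

`simulateCohort()` generates 40 recordings (26 "weak" / 14 "strong" rhythm,
mirroring a typical impaired/control contrast) with circadian amplitude
graded across 0.005–0.09 g and the AR(1) persistence of the activity noise
graded alongside it (phi 0 to 0.9): in real cohorts strong daily rhythms
co-occur with smoother, more persistent activity, and this coupling is what
produces the field's characteristic correlation pattern (IV negative with
IS, $\alpha$ and $\mathrm{PoV}^{(H)}$; all other pairs positive). Cohort
recordings default to 7 days at dt = 30 s: the paper-grade 5-s period is
unnecessary for cohort-level properties, 30 s keeps the full 40-recording
panel to seconds of compute, and the recommended 5-minute IV subsampling
stays an integer factor ($\Delta = 10$).

The generator emulates the *structure* of wrist ENMO data — nonnegativity,
non-sinusoidal 24-h shape, night troughs, tunable fragmentation — but not
posture artefacts, non-wear episodes, device calibration error, or
behavioural day-to-day variability. A green synthetic test therefore
establishes that the estimators recover known ground truth under the stated
model, not that any clinical threshold transfers to real cohorts.

## Known limitations

* Day/night DFA on concatenated streams detrends across splice boundaries;
  the per-day mode quantifies the effect but shorter blocks estimate noisier
  exponents.
* IS with hourly bins is insensitive to the bin width on high-frequency
  data but never exactly 1 for a smooth (non-hour-constant) rhythm, because
  within-hour variation stays in the denominator.
* PoV requires at least two recorded days, otherwise the 23.5–24.5 h band
  contains no Fourier frequency; edge bands at very short recordings are
  sparse and noisy.
* The Mann–Whitney comparison uses the exact distribution only for small
  untied samples (the usual `wilcox.test` rule); ties fall back to the
  corrected normal approximation. No multiple-testing correction is applied.

## A worked example

```{r example, eval = FALSE}
es <- simulateCircadian(days = 7, seed = 1)      # 7 days at 5-s sampling
isValue(interdailyStability(es))
ivValue(intradailyVariability(es, ivRecommendedDelta(5)))
dfaExponent(es)
pov(es)

co <- simulateCohort(seed = 1)
rows <- computeMetrics(co$series, groups = co$truth$group)
metricCorrelations(rows)
```
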