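# actirhythm

Nonparametric summary statistics of rest–activity rhythms for
high-frequency wrist accelerometry.

Wrist-worn accelerometers record activity for weeks at sampling periods of
a few seconds. The analysed signal is **ENMO** (Euclidean norm minus one):
`max(0, sqrt(x² + y² + z²) − 1)` per sample, in g. From an ENMO series
`{X_t}` of length `N`, `actirhythm` computes four statistics used to
quantify circadian rhythm strength and fragmentation — for example to
contrast individuals with disrupted rest–activity cycles against controls:

* **Interdaily stability**
  `IS = [Σ_s (X̄_s − X̄)² / 24] / [Σ_t (X_t − X̄)² / N]`, with `X̄_s` the
  mean over clock hour `s`; IS ∈ [0, 1], and 1 means a perfectly repeating
  daily pattern.
* **Intradaily variability**, phase-averaged over all `Δ` subsampling
  offsets: for each phase,
  `IV = [Σ_k (Y_k − Y_{k−1})² / (M−1)] / [Σ_k (Y_k − Ȳ)² / M]`;
  IV ≈ 2 for white noise, lower for smooth persistent activity. An
  `ivSweep()` across `Δ` supports choosing the subsampling interval
  (recommended 5 minutes on 5-second data, acceptable 2–10 minutes).
* **DFA scaling exponent** `α`: slope of `log2 F(S)` on `log2 S`, where
  `F(S)` is the root-mean-square fluctuation of the mean-centered
  cumulative profile around per-segment least-squares lines, on the scale
  grid `S = round(2^i)`, `i = 4, 4.25, …, 8`. `α = H` (Hurst exponent) for
  stationary series, `H + 1` for walk-like series: white 0.5, pink 1.0,
  random walk 1.5. Separate daytime/nighttime exponents via
  `dfaDayNight()` (day 06:00–23:00, night 23:00–06:00).
* **Proportion of variance** from the periodogram
  `I(f) = |Σ_t (X_t − X̄) e^{−2πift·dt}|² / N`: the fraction of variance in
  the band of periods 23.5–24.5 h around the circadian fundamental
  (`PoV^(F)`) and summed over its first four harmonic bands (`PoV^(H)`).
  `cosinorR2()` is the parametric comparator (fixed 24-h cosine fit).

Recording I/O (`readActigraphy()`, `computeEnmo()`, `cleanRecording()` —
whole-day gap exclusion), 24-h profiles (`dailyProfile()`), synthetic
ground-truth generators (`simulateCircadian()`, `simulateNoise()`,
`simulateCohort()`), and cohort reporting (`computeMetrics()`,
`summarizeGroups()`, `compareGroups()` Mann–Whitney, `metricCorrelations()`)
round out the toolkit. A thin CLI is installed at
`system.file("exec", "actirhythm", package = "actirhythm")` with
subcommands `simulate`, `compute`, `sweep-iv`, `dfa`, `pov`, `spectrum`,
`report`.

## Worked example

```r
library(actirhythm)

es <- simulateCircadian(days = 7, seed = 1)   # 7 days of ENMO at 5-s sampling
es
#> EnmoSeries: 120960 samples @ 5 s (7.00 days)
#>   start: 2018-01-01 00:00:00
#>   ENMO (g): mean 0.0518, max 0.2297

interdailyStability(es)
#> Interdaily stability IS = 0.5623
#>   overall mean 0.0518 g; hourly means in [0.0267, 0.1246]

intradailyVariability(es, ivRecommendedDelta(5))   # 5-minute subsampling
#> Intradaily variability IV = 0.8610 (delta = 60, M = 2016)

dfaExponent(es)
#> DFA scaling exponent alpha = 0.5150 (R^2 = 0.9988)
#>   scales: 16 to 256 samples over 17 scales; N = 120960

pov(es)
#> Proportion of variance: PoV(F) = 0.4177, PoV(H) = 0.5694 (4 harmonics)
#>   fundamental band: periods 23.5-24.5 h; per-harmonic: 0.4177, 0.1152, 0.0295, 0.0070
```

The simulated recording has a marked but noisy daily rhythm: just over half
the between-hour structure repeats day to day (IS = 0.56), activity is much
smoother than white noise at the 5-minute scale (IV = 0.86, versus ≈ 2 for
noise), the whole-series DFA exponent is near the white-noise value 0.5
(the generator's default noise is uncorrelated), and the circadian
fundamental band alone carries 42% of the variance, rising to 57% with
harmonics — the non-sinusoidal daily shape is why `PoV^(H)` exceeds
`PoV^(F)` and the plain cosine fit (cosinor R² = 0.418 here).

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference calibration from
scratch — it simulates 50 i.i.d. Gaussian series of length 2^17, estimates
the DFA exponent of each on the default scale grid, and reports the mean —
and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
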