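---
title: "Robust analysis of prospective time estimation under dual-task load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust analysis of prospective time estimation under dual-task load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prospectime)
```

## The experiment and the quantities of interest

`prospectime` analyses prospective verbal duration estimation: a participant
knows in advance that an interval must be judged, performs a concurrent
cognitive task while it elapses (fixating a point, reading numbers aloud,
solving simple or hard sums), and reports the elapsed seconds verbally. The
reference design crosses two motor conditions (sitting, treadmill walking)
with four tasks and five nominal intervals (15, 30, 60, 90, 120 s), ten
repetitions per cell, 200 trials per participant per condition, 16
participants. Actual durations are jittered integers within ±10% of the
nominal value, so the 15-s interval really spans 13–17 s and the 120-s
interval 108–132 s. Trials come in blocks of ten containing every interval
exactly twice, with tasks interleaved at random under the ten-per-cell quota.

The primary outcome is the estimation bias $\Delta = e - d$ (estimate minus
true duration; positive = overestimation), and its two derived descriptions:

* how the *mean* bias varies with duration — a two-parameter line
  $\Delta(d) = a + b\,d$, where $a$ is a constant estimation error and $b$
  the per-second drift;
* how the *dispersion* (RMSE) varies with duration and with the mean
  estimate. Under scalar timing the dispersion is proportional to the
  estimate, so the through-origin slope of RMSE against mean estimated time
  is the coefficient of variation (CV).

## Generative models

Two interchangeable simulators produce trial-level estimates with the
statistical structure the analysis assumes.

**Linear internal clock** (`linear_clock_model()`). Each (condition, task)
cell has an additive offset $\alpha$ (s), a multiplicative gain $g$, and a
coefficient of variation $c$:
$$ e = \alpha + g\,d + \varepsilon,\qquad
   \varepsilon \sim \mathcal N\!\big(0,\ [c\,(\alpha + g d)]^2\big), $$
so the bias line has intercept $\alpha$ and slope $g - 1$, and the noise SD
grows linearly with the expected estimate (constant CV — the scalar
property). Default cell parameters reproduce the reference study's fitted
bias lines: attending only to time overestimates by a constant amount
(look: $\alpha = 6.4$, $g - 1 = 0.005$ sitting; $8.9$, $0.01$ walking),
reading is near-veridical, and mental arithmetic underestimates
progressively ($g - 1$ from $-0.2$ to $-0.4$), more while walking. The
default $c = 0.2$ sits at the level of the study's RMSE-vs-duration slopes
(0.14–0.23). With probability `outlier_rate` (default 0.02) a trial's noise
SD is multiplied by `outlier_scale` (default 5): the occasional wild verbal
report that the outlier filter exists to remove. The study filtered
outliers but did not model them; contamination is this package's own
addition so the filter has something to catch. Estimates are floored at
1 s. The noise law is not identified by group-level summaries; the default
is Gaussian on the estimate scale, with a log-normal option (same mean and
CV, right-skewed) since verbal magnitude reports often skew right.

**Pacemaker–accumulator** (`pacemaker_accumulator_model()`). The mechanistic
reading: a pacemaker emits pulses at rate $\lambda$ (default 50 /s),
perturbed per trial by multiplicative noise ($\sigma_{\text{gain}} = 0.2$);
an attentional switch transmits pulses with probability $p$ (lower when the
concurrent task diverts attention); the accumulator count is Poisson; the
readout divides by $p_{\text{ref}}\lambda$. The expected estimate is
$(p/p_{\text{ref}})\,d$ — a pure gain with no additive offset — and once
$\lambda d$ is large the rate noise dominates Poisson counting noise, giving
a constant CV $\approx \sigma_{\text{gain}}$. The calibration gate
$p_{\text{ref}}$ is not observable from behaviour; the default ties it to
the "read" task's gate (0.9), making reading near-veridical, and sets every
other gate proportional to that cell's linear-model gain, so both
generators agree on relative bias slopes.

What the generators deliberately do *not* emulate: participant-level random
effects (all simulated participants share cell parameters), sequential or
block effects on estimates, response quantisation (humans round to 5-s
multiples; the time-ruler protocol was designed to discourage this), and any
mechanistic model of arithmetic difficulty — accuracy and response times are
plain Bernoulli/log-normal draws (`add_math_performance()`) so that the
descriptive performance summaries are testable. Passing tests therefore
show the *chain* is correct and calibrated for data with this structure,
not that real data satisfy the structure.

## The robust chain, step by step

1. **Pseudomedian outlier filter** (`filter_outliers()`). For each
   (condition, task, interval) cell, pooled over participants, the
   Hodges–Lehmann pseudomedian (median of all Walsh averages
   $(x_i + x_j)/2$, $i \le j$) centres an acceptance band of ±3 sample SDs;
   values strictly outside are removed. Deliberate choices where the
   procedure is under-specified: the SD is that of the *raw, unfiltered*
   sample and the filter is single-pass (iterating would silently remove
   extra points); boundary values are kept; cells are the narrowest
   "per distribution" reading; samples of size < 2 pass through. With 3-SD
   bounds and a contaminated raw SD the band is generous — roughly half the
   5-SD contaminants survive — which the downstream uncertainty treatment
   has to respect (see CV standard errors below).

2. **Binning** (`make_bins()`). Each interval's integer jitter window is cut
   into 2-s bins anchored at the window minimum (the last bin of an
   odd-width window holds one value): 3 + 4 + 7 + 10 + 13 = 37 bins per
   (condition, task), hence 35 degrees of freedom for two-parameter fits.
   Binning avoids inflating dispersion with the drift of the mean across a
   ±10% window. Per bin: mean bias, its SE, the RMSE, and the mean
   estimate. Bins with fewer than two trials are dropped and logged. Two
   documented choices:
   * *RMSE about the bin mean* (within-bin dispersion) is the default,
     because the study reads RMSE as estimation *uncertainty* and reports
     sitting-condition RMSE as comparable across tasks despite very
     different biases; RMS about the true duration is available via
     `rmse_about = "truth"`.
   * *SE pooling*: the SD entering $\mathrm{SE} = s/\sqrt{n}$ is pooled
     over the bins of one interval cell (`se_pooling = "cell"`). Under
     scalar noise the SD is constant across a ±10% window to within a few
     percent, and pooling keeps $1/\mathrm{SE}^2$ weights stable where bins
     hold only six to a dozen trials; with per-bin SDs
     (`se_pooling = "bin"`) occasional small-SD bins get enormous weight
     and the fit's claimed precision becomes anticonservative (recovery
     z-scores overdispersed by up to 2.7×).

3. **Weighted line fits** (`fit_line()`, `fit_bias_line()`,
   `fit_rmse_line()`). Measurement-error weighted least squares: weights
   $1/\mathrm{SE}^2$, parameter covariance $(X^\top W X)^{-1}$ *not*
   rescaled by residual variance, and $\chi^2 = \sum ((y - \hat y)/
   \mathrm{SE})^2$ as the goodness-of-fit statistic — the convention of
   physics-style fitting, consistent with the study's reported
   $\chi^2(35)$ values of 34–58. Zero-SE bins get the smallest positive SE
   observed (capped weight). Unweighted fits fall back to residual-based
   SEs; the RMSE-vs-duration fit uses two parameters (slope and intercept,
   matching the reported fits), the RMSE-vs-estimate fit is strictly
   through the origin and returns the CV. Per-bin RMSE standard errors
   default to the delta-method value $s/\sqrt{2(n-1)}$ with the SD scale
   $s$ pooled over the cell like `se_bias`: weighting a bin by its *own*
   tiny-$n$ RMSE is unstable (a bin whose few values happen to coincide
   would get unbounded weight and drag a through-origin fit toward zero).
   A whole-process bootstrap alternative is available.

4. **Bootstrap through the filter** (`bootstrap_variance()`,
   `estimate_cv()`). Uncertainties of variance-type statistics are obtained
   by resampling the *raw* sample, re-running the filter on each resample,
   then evaluating the statistic — so the randomness of the filter bounds
   propagates. Resamples where fewer than two values survive are redrawn
   and counted. This matters for the CV: the through-origin fit SE treats
   the 37 RMSE values as independent, but all bins of a cell share one
   filter bound, so their errors are mildly correlated and the fit SE
   under-covers by ~20% (measured across independent simulated cohorts).
   `estimate_cv(se_method = "bootstrap")` resamples trials within each
   cell, re-filters, re-bins and re-fits (default $B = 200$); its SEs track
   the empirical cohort-to-cohort dispersion. The plain fit SE remains the
   default for continuity with the fit-based chain; prefer the bootstrap SE
   when CVs are compared.

5. **Tests and summaries.** Cell-wise accuracy uses the one-sample Wilcoxon
   signed-rank test on biases (exact, tie-aware distribution up to
   $n = 25$ via the subset-sum recursion over doubled ranks — identical to
   enumerating all $2^n$ sign assignments — then a tie-corrected,
   continuity-corrected normal approximation), Bonferroni-adjusted within
   each motor condition (the 20 cells reported together). Slopes are
   compared with z-tests, $z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}$.
   Percentual effect summaries quantify the motor effect (walking vs
   sitting in the no-load look task, relative to the interval) and the
   cognitive effect (look vs solve while sitting); on the published cell
   means these give a mean motor effect of ~8%, maximal ~17% at 15 s, and
   cognitive effects several times larger (mean ~36%, maximal ~61% for
   hard sums at 15 s). Computed from the published per-cell means these
   differ by a few tenths of a point from the study's trial-level values
   (7.5%/37%/62%) — the cell means are the only reproducible input, and
   both bases are noted here for that reason. Block-trend controls regress
   per-block mean fatigue, tiredness and temperature on block number with
   t-statistics on $n - 2$ df.

## Reproducibility and numerical choices

Every stochastic function takes an integer seed and is deterministic given
it; `run_pipeline()` derives all stage seeds from the single config seed, so
a config fully determines every number in the report, and the report logs
how many trials the filter removed (the reference study never reports
this). Degenerate inputs are handled explicitly: zero-dispersion samples
pass the filter untouched; all-zero differences give Wilcoxon $p = 1$ with
$V = n(n+1)/4$ flagged; perfect regression fits report an infinite-t flag;
noiseless pipelines (all SEs zero) fall back to unweighted fits rather than
dividing by zero. Jitter windows round outward
($\lfloor 0.9T \rfloor$ to $\lceil 1.1T \rceil$, with a floating-point
fuzz), which is what makes the 15-s window 13–17 s and the bin arithmetic
come out at 37 bins.

Problem sizes used by the test suite are the study's own where feasible:
the parameter-recovery calibration runs 50 cohorts of 16 participants × 10
repetitions with $c = 0.2$ and 2% contamination and asks for joint
(intercept, slope) coverage within 2 SE at a pooled rate of at least 90% —
the theoretical ceiling for joint 2-SE coverage of two correlated
parameters is about 91%, which is why the bar is pooled across cells rather
than per cell. Scalar-flatness and null-calibration checks use 4–8 seeded
cohorts each; oracle-equivalence checks (Walsh-average enumeration, $2^n$
sign enumeration, closed-form normal equations) run in seconds.

## Known limitations

* The filter's "3 SD" is interpreted as the raw-sample SD in a single pass;
  an iterated or robust-scale variant would remove more points and is not
  provided.
* Binned fits pool trials across participants; participant-level summaries
  are kept for cell tables, but the fits do not model between-participant
  variance (the generators have none). With real data the bin SEs would
  absorb participant heterogeneity into the pooled within-bin SD, which is
  correct for the fit but discards the repeated-measures structure; the
  mixed-effects analysis that would use it is intentionally out of scope,
  as are repeated-measures ANOVA of the performance summaries and normality
  screening (the pipeline always takes the nonparametric path).
* The pacemaker readout calibration $p_{\text{ref}}$ is conventionally tied
  to the read task; other conventions rescale all gate probabilities
  without changing relative biases.
* CV comparisons with the plain fit SE are anticonservative (see above);
  prefer the bootstrap SE.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 5L)
report <- run_pipeline(cfg, out_dir = "run1")
report$bias_fits
report$cv_fits
report$effects
```
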