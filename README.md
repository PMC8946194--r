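# prospectime

Simulation and robust analysis of **prospective verbal time estimation under
dual-task load** — experiments in which participants judge elapsed intervals
of tens of seconds to minutes while performing a concurrent cognitive task
(fixating, reading aloud, solving simple or hard sums), either sitting or
walking on a treadmill. The package is aimed at time-perception researchers
who want a tested, reproducible implementation of the robust/nonparametric
analysis chain such designs call for, together with generative models for
power analysis and method calibration.

## The model and the chain

For a trial with true duration *d* and verbal estimate *e*, the estimation
bias is Δ = *e* − *d* (positive = overestimation). Two generative models
produce trial data with the structure the analysis assumes:

* a **linear internal clock**, *e* = α + *g·d* + ε with noise SD
  proportional to the expected estimate (constant coefficient of variation —
  the scalar-timing property), plus a small rate of inflated-noise
  contaminant trials;
* a **pacemaker–accumulator** with an attentional gate: pulses at rate λ are
  transmitted with probability *p*, counted (Poisson), and read out against
  a calibration gate, giving E(*e*) = (*p*/*p*<sub>ref</sub>)·*d*; per-trial
  clock-rate noise yields the same scalar property.

The analysis chain, in order:

1. **outlier filtering** per condition × task × interval cell: drop values
   more than 3 raw-sample SDs from the Hodges–Lehmann pseudomedian (the
   median of all Walsh averages);
2. **binning** of biases over 2-s sub-intervals of each ±10% jitter window
   (3 + 4 + 7 + 10 + 13 = 37 bins);
3. **weighted linear fits** of mean bias vs duration (χ² goodness of fit on
   35 df) and of RMSE vs duration;
4. **coefficients of variation**: through-origin fits of RMSE vs mean
   estimated time, with an optional bootstrap-through-the-filter standard
   error;
5. **tests**: exact/tie-aware one-sample Wilcoxon signed-rank tests of
   accuracy per cell with Bonferroni adjustment, z-tests on slopes, and
   percentual motor/cognitive effect summaries;
6. **controls**: regressions of fatigue/tiredness/temperature on block
   number.

## Worked example

```r
library(prospectime)
report <- run_pipeline(pipeline_config(seed = 5L))
print(report)
```

```
prospectime run report (seed 5 , model linear )
  6400 trials; 57 removed by the 3-SD pseudomedian filter
  Bias fits (slope +/- SE per condition/task):
    sitting  look         slope -0.010 +/- 0.014  intercept  6.55 +/- 0.45  chisq(35) = 34.0
    sitting  read         slope -0.087 +/- 0.011  intercept  5.37 +/- 0.40  chisq(35) = 37.9
    sitting  solve_hard   slope -0.302 +/- 0.008  intercept  1.08 +/- 0.26  chisq(35) = 37.3
    sitting  solve_simple slope -0.202 +/- 0.009  intercept  2.90 +/- 0.30  chisq(34) = 58.9
    walking  look         slope -0.003 +/- 0.013  intercept  9.56 +/- 0.46  chisq(35) = 36.3
    walking  read         slope -0.076 +/- 0.011  intercept  5.28 +/- 0.36  chisq(35) = 46.9
    walking  solve_hard   slope -0.395 +/- 0.008  intercept  1.71 +/- 0.24  chisq(35) = 22.4
    walking  solve_simple slope -0.303 +/- 0.009  intercept  3.37 +/- 0.28  chisq(35) = 31.8
```

A 16-participant cohort is simulated (6400 trials), filtered, binned and
fitted. The slopes say how the bias drifts per second of true duration:
near zero for passive looking (a constant ~6.5 s overestimate while
sitting, ~9.6 s while walking), mildly negative for reading, and steeply
negative for mental arithmetic (−0.30 s/s for hard sums sitting, −0.40
walking) — the harder the concurrent task, and the more so when walking,
the stronger the progressive underestimation. χ²(35) values near 35 say
the lines describe the binned data to within the stated uncertainties.

Coefficients of variation (`report$cv_fits`) are flat across tasks at the
generator's configured relative noise:

```
  condition         task    cv   cv_se
1   sitting         look 0.202 0.00538
2   sitting         read 0.190 0.00506
...
8 walking solve_simple 0.196 0.00524
```

Effect sizes relative to the interval, computed from the shipped reference
cell means (`reference_cell_means()`, the published group means of the
16-participant study this design reproduces):

```r
effect_summaries(reference_cell_means())
#> Motor effect (look task): mean 8.1%, max 17.3%
#> Cognitive effect (sitting): mean 35.5%, max 60.7%
```

Walking alone lengthens look-task estimates by ~8% of the interval on
average (17% at 15 s); cognitive load alone shortens them by several times
that amount.

A thin command-line wrapper is available for shell use:

```sh
Rscript scripts/pipeline.R simulate --seed 5 --out run1
Rscript scripts/pipeline.R analyze --in run1/trials.csv --out run2
```

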