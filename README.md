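# proteoturn

Protein turnover kinetics from heavy-leucine metabolic labeling.

## What this package is for

In vivo proteome dynamics studies switch animals onto a diet in which
leucine is replaced by deuterated (²H₃) leucine and sample tissue at a
series of labeling times. Every tryptic peptide then shows up in LC-MS/MS
as an *isotopologue envelope* — peak areas at unit mass spacing — that
mixes three things: the peptide's natural isotope pattern, the rising
enrichment *p(t)* of the free-leucine precursor pool, and the fraction
*f* of protein molecules synthesized since the switch. `proteoturn`
implements the desk side of such a study for researchers quantifying
protein half-lives and how interventions (age, calorie restriction,
mTOR inhibition, ...) change them:

* **Isotope model** — peptide elemental composition, natural-abundance
  envelopes (exact truncated convolution), and the envelope of newly
  synthesized peptide at enrichment *p* (each heavy leucine shifts the
  envelope by +3 nominal offsets; heavy count is Binomial(L, p)).
* **Deconvolution** — per observation, non-negative least squares for
  `y = A[(1−f)·natural + f·labeled(p)]`; per sample, the precursor-pool
  enrichment as the median of joint (f, p) fits over multi-leucine
  peptides (L = 1 peptides are excluded: only f·p is identifiable).
* **Kinetics** — AUC-weighted pooling of unique peptides per protein and
  mouse, then first-order fits: at steady state
  `f(t) = 1 − exp(−k t)`, so `−ln(1−f)` is regressed on time through the
  origin with variance-stabilizing weights; `HL = ln 2 / k`. A
  steady-state check tests that peptide abundances do not drift with
  labeling time.
* **Comparative statistics** — pairwise per-protein half-life ratios
  with a proportion z-test (`z = (p̂ − ½)/√(¼/n)`), Welch tests on rate
  constants with Benjamini–Hochberg q-values, differential abundance on
  summed peptide AUC with median-of-ratios normalization, pathway and
  compartment half-life summaries with one-way ANOVA, Spearman
  comparisons between contrasts, and log₂-ratio matrices for heatmaps.
* **Polysome profiles** — baseline correction, valley segmentation of
  the 40S/60S/80S/polysome peaks, trapezoidal areas and ratios-to-total,
  and linear trend tests across ribosome loading.
* **Synthetic data** — a generator for the full 2-age × 3-diet design
  (4 timepoints × 3 mice per cohort) with known ground truth, used by
  the test suite and reproducibility script.

## Worked example

Simulate a two-cohort study (control vs calorie restriction with a true
1.6× half-life effect, 100 proteins, 5% intensity noise) and run the
whole pipeline:

```r
library(proteoturn)

cfg <- sim_config(n_proteins = 100,
                  hl_multipliers = c(YCL = 1, YCR = 1.6),
                  seed = 42)
sim <- simulate_cohort(cfg)
res <- run_pipeline(sim$observations, reference = "YCL")

head(res$enrichment, 3)
#>       sample         p n_peptides_used dispersion
#> 1 YCL_d03_m1 0.3872010              86 0.01408949
#> 2 YCL_d03_m2 0.3890160              86 0.01456410
#> 3 YCL_d03_m3 0.3939812              86 0.01754062
```

The estimated day-3 pool enrichment (~0.39) recovers the generating
curve `0.6·(1 − e^(−0.35·3)) = 0.390`. Per-protein fits report the rate
constant, half-life and regression diagnostics:

```r
head(res$fits$YCL[c("protein", "k", "HL", "slope_se", "r_squared", "n_points")], 3)
#>   protein          k       HL     slope_se r_squared n_points
#> 1   P0001 0.07507183 9.233119 0.0009256536 0.9983304       12
#> 2   P0002 0.34496450 2.009329 0.0083549152 0.9970756        6
#> 3   P0003 0.16503619 4.199971 0.0036994644 0.9945031       12
```

(`n_points` below 12 means some mice sat above the saturation cutoff
`f > 0.97` and were excluded.) The between-group comparison recovers the
injected effect:

```r
cmp <- res$comparisons[["YCR/YCL"]]
attr(cmp$ratios, "median_ratio")     # 1.596994  (true effect: 1.6)
cmp$ztest$proportion_above_1         # 1
cmp$ztest$z                          # 8.831761
cmp$ztest$p_value                    # 1.030406e-18
sum(cmp$hl_test$q_value < 0.05)      # 78 of 78 shared proteins
```

So every shared protein's half-life ratio lies above 1, the proportion
z-test rejects equality decisively, and all per-protein rate differences
are significant after FDR adjustment — as expected for a uniform 1.6×
effect at this noise level.

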