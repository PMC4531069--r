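---
title: "Methods: precursor-corrected protein turnover from heavy-leucine labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: precursor-corrected protein turnover from heavy-leucine labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoturn)
```

# The measurement problem

In a metabolic labeling experiment, animals are switched to a diet in which
leucine is replaced by deuterated (2H3) leucine. Proteins synthesized after
the switch incorporate heavy leucine; proteins made before it do not. At a
series of sacrifice times (here 3, 7, 12 and 17 days, three mice per
timepoint per cohort), LC-MS/MS yields, for each tryptic peptide, an
*isotopologue envelope*: a vector of chromatographic peak areas at unit mass
spacing. The analysis has to untangle three confounded quantities:

* the **natural isotope envelope** of the peptide (from 13C, 15N, etc.),
* the **precursor-pool enrichment** `p(t)` — the fraction of free leucine
  that is heavy at time `t`, which rises gradually because dietary label
  mixes with unlabeled leucine from protein breakdown, and
* the **fraction new** `f` — the proportion of that peptide's molecules
  synthesized since the diet switch, which is the kinetic signal of
  interest.

Ignoring `p` (assuming complete enrichment) biases every rate constant;
the pipeline therefore estimates `p` per sample and conditions the
per-peptide `f` estimates on it.

# Isotope model

A peptide's elemental composition is the sum of residue compositions plus
one water; compositions and terrestrial isotope abundances for C/H/N/O/S
ship as TSV data (`inst/extdata/`) so tests can substitute degenerate
tables. The natural envelope is the convolution of per-atom isotope
distributions, computed per element by exponentiation-by-squaring of the
truncated convolution; because mass offsets are non-negative, truncating
each intermediate at the working window is exact for the retained entries.
The default window is `3L + 6` offsets for a peptide with `L` leucines,
which captures essentially all envelope mass for tryptic peptides.

Each heavy leucine shifts the envelope by exactly +3 nominal offsets; the
~0.009 Da mass defect between 3x2H and 3x13C is far below unit resolution
and is ignored. A peptide synthesized entirely from a pool at enrichment
`p` carries Binomial(L, p) heavy leucines, so its envelope is the
binomially weighted mixture of 3h-shifted natural envelopes. Each shifted
component is renormalized within the truncation window before mixing so
that the simulator's forward model and the deconvolution's design matrix
are identical objects; without this, truncation-tail mismatch alone would
spoil exact round-trip recovery.

# Deconvolution

An observed intensity vector is modeled as

```
y = A * ( (1 - f) * natural + f * labeled(p) ) + noise
```

The old-protein component is fully unlabeled; any label recycling is
absorbed into `p`. For fixed `p` the problem is linear in
`(A(1-f), A f)` with non-negativity constraints — a two-variable NNLS
solved in closed form, which also guarantees `f` in [0, 1] and flags
observations whose unconstrained optimum fell outside it. When `p` is
free, the residual is profiled over a deterministic 101-point grid on
[0, 1] (vectorized over the grid through the shift matrix) and refined by
golden-section search to 1e-9. Ties across the grid — which occur exactly
when the observation carries no label, e.g. a pre-switch control — are
broken toward the smallest `p`, so unlabeled samples report `p = 0`
rather than an arbitrary grid point.

Identifiability dictates which peptides inform which parameter. For
`L = 1` the envelope depends on `f` and `p` only through the product
`f * p`, so single-leucine peptides are excluded from enrichment
estimation (the suite asserts the confounding directly). The sample-level
enrichment is the median of per-peptide joint `(f, p)` fits over
multi-leucine peptides; one pool per liver at sacrifice is assumed, as a
free amino-acid pool equilibrates much faster than proteins turn over.
By default the 200 highest-signal qualifying peptides are used per
sample: the median over 200 peptides is statistically indistinguishable
from the median over all of them, and the cap keeps repeated-simulation
studies fast. Per-peptide `f` values are then re-fit with `p` fixed at
the sample estimate.

## Precision of the fraction-new estimate

The intensity noise is multiplicative (approximately constant CV per
isotopologue), so the variance of `f-hat` is not constant: it depends on
the envelope overlap between the old and new components (small `p` makes
them nearly collinear) and on `f` itself. Each fit therefore reports a
delta-method *relative* variance of `f-hat` — the sandwich
`(X'X)^-1 X' diag(mu^2) X (X'X)^-1` contracted with the gradient of
`f = b/(a+b)` — which is exact up to the unknown common CV. Only ratios
of these variances are used downstream, so the unknown scale cancels.

# Kinetics

Under steady state (synthesis = degradation, abundance constant — checked
explicitly, see below), label appearance is first order:
`f(t) = 1 - exp(-k t)`, so `-ln(1 - f)` is linear in `t` through the
origin. Per protein and cohort, peptide-level `f` values are pooled per
mouse as the AUC-weighted mean over unique peptides (peptides mapping to
more than one protein are discarded), giving one point per mouse, and the
rate `k` is the zero-intercept regression slope; `HL = ln 2 / k`. A free
intercept is available as a switch.

Two numerical choices matter and were made deliberately:

* **Weighting.** The log transform amplifies noise by `1/(1-f)`; with
  measurement noise roughly constant in `f`-space, the transformed
  residual variance grows as `(1-f)^-2`. Unweighted least squares lets
  the noisiest late-time points dominate the fit and understates the
  slope standard error — in null simulations the per-protein t-statistics
  were over-dispersed (sd up to 1.6) and their p-values badly non-uniform.
  The fit therefore iteratively reweights points by
  `exp(-2 k t) / v_i`, where `v_i` is the pooled relative variance
  propagated from the deconvolution. With weights proportional to the
  true inverse variances this is homoscedastic OLS in transformed
  coordinates, so the usual `n - p` residual degrees of freedom apply.
  `weighting = "none"` restores plain OLS.
* **Saturation cutoff.** Points with `f > f_max = 0.97` are excluded
  (and counted). Near `f = 1` the deconvolution clips at the boundary,
  truncating the error distribution; such points carry essentially no
  rate information but inject strong skew. The practical consequence is
  a resolution floor: with the first sample at day 3, proteins with
  half-lives below ~1.4 days do not yield enough usable points and are
  not fit. Their absence right-censors *marginal* per-cohort half-life
  summaries slightly, while pairwise ratio analyses — the primary
  between-group readout — are unaffected because both cohorts lose the
  same proteins.

The steady-state assumption itself is tested by regressing each
peptide's total AUC on labeling day and testing whether the slope
distribution is centered at zero.

# Between-group statistics

* **Half-life ratios.** Between-protein half-lives span orders of
  magnitude, so the sensitive comparison is within-protein: the ratio
  `HL_A / HL_B` per shared protein. Under no group effect each ratio is
  equally likely to fall on either side of 1; the proportion above 1 is
  tested with the normal approximation
  `z = (p-hat - 0.5) / sqrt(0.25 / n)` (ties at exactly 1 dropped,
  minimum n of 10). The phrase "z-test for proportions" admits more than
  one reading, so a one-sample t-test on the log2 ratios is reported
  alongside as a cross-check.
* **Per-protein rate difference.** Welch-style t on `k_A - k_B` using
  the two regression slope standard errors with Satterthwaite degrees of
  freedom, Benjamini–Hochberg adjusted (`bh_fdr` delegates to
  `stats::p.adjust`). The specific per-protein test behind published
  q-values of this kind is rarely stated; this choice is recorded in the
  output metadata and validated by the null-calibration tests.
* **Differential abundance.** Protein abundance per mouse is the summed
  unique-peptide AUC (labeled plus unlabeled area). Sample depth is
  normalized with median-of-ratios size factors computed jointly over
  both cohorts. A subtlety motivated a two-pass scheme: when a minority
  of proteins changes in one direction, even the median of ratios shifts
  by a small amount, and because the per-protein standard errors under
  this noise model are tiny, that shift alone generates false positives.
  The second pass recomputes size factors on proteins the first pass
  found stable (q > 0.5), then retests. With both cohorts at steady
  state, mice from all labeling days are usable (12 per cohort).
* **Pathway summaries.** Per pathway and group: median, mean, quartiles
  and 5th/95th percentiles of HL, plus a one-way ANOVA of HL across
  groups within the pathway. Pathway membership is a user-supplied
  mapping table; no enrichment knowledge base is reproduced.
* **Cross-comparison correlation.** Spearman rank correlation (average
  ranks, two-sided t approximation) between log-ratio vectors paired by
  protein, for questions like "does intervention X move old livers
  toward young ones".

# Polysome profiles

Absorbance traces (A254 vs gradient position) are baseline-corrected by
subtracting the line through the flanking minima and clipping at zero —
invariant to constant offsets and linear drifts. Peaks are local maxima
above a prominence threshold (default 2% of the trace maximum, plateau
tops collapsed to a single peak); segment boundaries sit at the deepest
valley between consecutive peaks. The first three peaks are labeled
40S/60S/80S, the next ones 2/3/4 ribosomes, and everything beyond the
sixth pools into a single ">=5" segment running to the end of the trace
(the gradient bottom), since the heavy fractions are not resolved
peak-by-peak. Areas are trapezoidal; ratios are taken to the summed area
over all segments. Treatment effects are expressed per segment as
percent of the control-cohort mean and tested for a linear trend across
the integer ribosome-loading index; an exactly collinear input is
reported with a degenerate-fit flag rather than a fabricated p-value.

# Synthetic data generator

The generator emulates the study design end to end with known ground
truth: six cohorts (young/old x control/CR/rapamycin), four timepoints
(3/7/12/17 d), three mice each, ~300 proteins (the study's 950 available
via config), 2–4 tryptic peptides per protein with residues drawn from
average vertebrate amino-acid frequencies (so leucine counts are
realistic: mostly 0–3 per peptide). Half-lives are log-normal with
median 3.1 d and log-sd 0.8 — spanning roughly two orders of magnitude,
as observed for liver proteomes. Default group effects multiply
half-lives by 1.6 (CR, young), 1.15 (rapamycin), 0.9 (age), with the old
intervention effects composed accordingly; abundance multipliers default
to 1. Enrichment follows a saturating exponential
`p(t) = p_max (1 - exp(-rate t))` with `p_max = 0.6`, `rate = 0.35`/d —
a gradual rise to a realistic dietary plateau; the functional form is a
simulator choice exposed in the config, since only the fact that
enrichment "varies over time and condition" is observable. Noise is
independent multiplicative log-normal per isotopologue intensity
(unit mean, default CV 5%), the simplest error model consistent with
positive AUC data.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: between-mouse biological variation in
abundance or turnover, correlated (e.g. retention-time or batch) noise,
missing peptides, interference from co-eluting species, missed
cleavages, or post-translational modifications. Recovery tolerances in
the acceptance suite (e.g. <10% median half-life error at CV 5%;
injected 1.6x ratio recovered within [1.5, 1.7]) are statements about
the algorithm under this noise model, not about instrument performance.

# Problem sizes and determinism

The test suite and the acceptance script run the full design at 300
proteins (about 21,600 peptide observations per two-cohort study), with
the 20-replicate null-calibration study at the same scale; these sizes
were chosen so that a complete run is a desk-scale computation while the
per-protein test still sees the design's real 12-mice-per-cohort
granularity. All randomness flows through explicit seeds: the simulator
seeds its own RNG from the config, grid searches are deterministic, and
re-running a pipeline on the same table reproduces every output
byte-for-byte.

# Interfaces

All inputs and outputs are plain TSV/CSV (isotopologue vectors travel as
a semicolon-delimited column) plus a JSON run manifest, written and
re-read by the package's own functions — diff-able and CI-friendly. The
package's users drive it from R, so the pipeline surface is the exported
functions (`simulate_cohort`, `run_pipeline`, readers/writers) rather
than shell subcommands; `scripts/acceptance.R` is the runnable
end-to-end entry point.

# Known limitations

* Half-lives below ~1.4 d are unresolvable under the 3–17 d design (see
  the saturation cutoff above); half-lives much beyond ~70 d rest on
  small `f` values and carry wide intervals.
* One enrichment per sample: a tissue with heterogeneous precursor pools
  (or strong recycling gradients) would violate the single-`p` model.
* The per-protein rate test assumes the pooled per-mouse points are
  independent; peptide-sharing across proteins is handled by exclusion,
  not by a hierarchical model.
* Envelope fitting assumes unmodified sequences and elements C/H/N/O/S
  only; no fine isotope structure.
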