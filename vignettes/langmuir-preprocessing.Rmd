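---
title: "Physicochemical preprocessing of oligonucleotide arrays: model, conventions and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical preprocessing of oligonucleotide arrays: model, conventions and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langmuirchip)
```

## The model

Most GeneChip preprocessing pipelines treat the measured fluorescence of
a probe as a purely statistical quantity. `langmuirchip` instead treats
it as the readout of an equilibrium surface-hybridization experiment.
Three physical ingredients define the preprocessing:

1. **Nearest-neighbor free energies.** The affinity of a 25-mer DNA
   probe for its complementary RNA target is approximated by the
   nearest-neighbor model: the duplex free energy is an initiation term
   plus the sum of stacking contributions of the 24 overlapping
   dinucleotides of the probe strand read 5'→3',
   \[ \Delta G(s) = \Delta G_{\mathrm{init}} + \sum_{i=1}^{L-1}
      \Delta G_{\mathrm{stack}}(s_i s_{i+1}). \]
   The package ships the RNA/DNA hybrid stacking parameters of Sugimoto
   and co-workers (solution hybridization, ΔG at 37 °C), re-keyed to the
   DNA probe strand; the file format is plain text and the table is an
   explicit argument of every function, so users can substitute their
   own calibration.

2. **Binding constant.** A free energy becomes an equilibrium constant
   through the Boltzmann factor \(K = e^{-(\Delta G - \Delta G_{\mathrm{ref}})/RT}\)
   with \(T = 318.15\) K (45 °C, the standard GeneChip hybridization
   temperature; the preprocessing paper family does not fix \(T\), so it
   is configurable) and \(R = 0.0019872\) kcal/(mol·K).

3. **Langmuir isotherm.** At equilibrium the fraction of surface probes
   in duplex with a target at concentration \(c\) follows
   \[ I = I_0 + A\,\frac{cK}{1 + cK}, \]
   with saturation amplitude \(A\) (default \(10^4\) intensity units)
   and constant optical background \(I_0\) (default 0 — background
   correction is deliberately not part of this preprocessing; the
   resulting over-estimation of weak concentrations is the reason the
   variance-stabilized t-tests exist downstream). The preprocessing step
   is the exact algebraic inversion
   \(\hat c = (I - I_0) / (K (A - (I - I_0)))\), applied probe by probe.

Because the inversion divides out the sequence-specific affinity, probe
estimates of the same transcript's concentration are — in the ideal
model — identically distributed, which is exactly what summarizers and
multivariate analyses downstream would like to assume about their
input.

### The scale convention for K

Raw solution-phase free energies of random 25-mers are around −32
kcal/mol, which would put \(e^{-\Delta G/RT}\) near \(e^{50}\): on that
scale every pM-level target saturates the isotherm. On a chip surface
the effective binding is far weaker than in solution (surface packing,
electrostatics, labeling, washes), and any practical isotherm fit
absorbs that difference into the scale of \(K\). The package makes the
absorption explicit and singular: a single reference free energy
`dg_reference` (default −37.7 kcal/mol in the pipeline configuration)
is subtracted once, chosen so that a typical random 25-mer gets
\(K \approx 10^{-4}\,\mathrm{pM}^{-1}\), i.e. the doubling ladder of the
spike-in design (0.25–1024 pM) spans the informative range of the
isotherm below saturation. With `dg_reference = 0` (the
`thermo_config()` default) the textbook \(K = e^{-\Delta G/RT}\) is
recovered exactly. Sequence-to-sequence *differences* in affinity — the
quantity that matters for the inversion — are untouched by the offset.

### Censoring and rescaling

Intensities at or above \(I_0 + A\) sit at the pole of the inverted
isotherm; they are censored (missing, flagged) rather than
extrapolated, and censored values are never imputed downstream.
Intensities at or below \(I_0\) map to concentration 0 with a
below-background flag.

Array-to-array differences are assumed to stem mainly from the amount
of hybridized material, so the only normalization is one multiplicative
factor per array ("slope one between arrays"). `rescale_arrays()`
computes a per-probe pseudo-reference (median across arrays) and scales
each array by the median ratio to that reference. A single sweep leaves
the stated goal — median ratio exactly 1 for every array — slightly
unmet because the reference moves with the scaling, so the sweep is
iterated to its fixed point (tolerance \(10^{-13}\), typically 2–3
sweeps); the procedure is then idempotent to machine precision and
preserves within-array ranks exactly.

## Summarizers

Five probe-set summarizers are provided, mirroring the summarization
steps of the classic preprocessing pipelines so the concentration-based
preprocessing can be compared against them on equal terms:

| method | description | default scale |
|---|---|---|
| `median` | per-array median of finite probe values | linear |
| `average_difference` | trimmed mean: drop min and max, then average values within ±3 SD of the trimmed mean | linear |
| `tukey_biweight` | one-step bisquare-weighted location around the median, MAD-scaled (`c = 5`, `eps = 1e-4`) | linear |
| `mbei` | Li–Wong multiplicative model \(y_{pj} = \phi_p \theta_j\) by alternating least squares, \(\sum\phi^2 = P\) | linear |
| `medianpolish` | Tukey median polish; summary = overall + column effect | log2 |

Median polish defaults to the log2 scale (it performs best there and
that is the convention of the polish-based pipelines it mirrors); the
other methods default to the linear concentration scale. Both paths are
available for every method via `use_log`. The `transposed` polish
variant — rows and columns swapped, proposed to avoid polish-induced
inter-array correlation with few replicates — is exposed as a
configuration flag and verified against the identity "transposed polish
of the transpose = straight polish".

The polish backend is `stats::medpolish()`, wrapped so the convergence
tolerance is absolute on the change of \(\sum|r|\) (the base function's
`eps` is relative) and so single-probe probesets decompose trivially.
The average-difference outlier rule is the closest published
description of the earliest GeneChip summarizer and is documented as an
approximation. MBEI is implemented without the original's probe-outlier
rejection schedule (not specified in the sources this package
follows); the alternating least squares with the \(\sum\phi^2 = P\)
constraint is the documented core.

## Differential tests

Three two-group tests operate on the summarized expression matrix,
sharing one NA rule: a probeset is filtered from a comparison when
either group has fewer than two finite values (in particular when a
group is entirely missing).

* **Student t** — pooled variance, \(df = n_A + n_B - 2\), two-sided.
* **Window t** — probesets are ranked by overall mean expression; the
  pooled variance is replaced by the mean pooled variance over the
  \(2h+1\) rank-neighbors (truncated at the ends, ties broken by
  probeset id), default \(h = 50\). The df is kept at
  \(n_A + n_B - 2\), a conservative choice since pooling across
  probesets does not make the window's variances independent.
* **Regularized t** — the pooled variance is shrunk toward that same
  window-estimated background variance with \(\nu_0\) pseudo-degrees
  of freedom (default 10), \(df = \nu_0 + n_A + n_B - 2\).

The exact parameterizations of the historical implementations of the
latter two are not published alongside their descriptions; the defaults
here are declared, interpretable knobs (both reduce exactly to the
Student t at \(\nu_0 = 0\) / \(h = 0\), which the tests assert to
\(10^{-12}\)). With triplicates, the per-probeset variance estimate has
4 df and its noise dominates the ranking of the plain t; pooling along
the expression ranking is what restores detection power, and the
spike-in benchmark below shows exactly that.

## Benchmarks

**Correlation study.** For a mixture series of two tissues, the
comparison of the two pure samples defines a reference list of
p-values; every other pairwise mixture comparison is correlated against
it on the log10 p-value scale (floor \(10^{-300}\) before the log, so
order is preserved without \(-\infty\)). Pearson is the reporting
default; Kendall and Spearman are selectable. Cross-platform versions
go through a best-match mapping table from which only one-to-one rows
are used, discarding transcripts covered by a single platform.

**Spike-in evaluation.** The synthetic Latin Square mirrors the classic
benchmark design: 14 groups of 3 probesets spiked on the doubling
ladder 0, 0.25, 0.5, …, 1024 pM, group \(g\) receiving
\(\mathrm{ladder}[(g + k) \bmod 14]\) in condition \(k\) (the cyclic
square — the design class fixes only that each concentration visits
each condition once, and the cyclic permutation is the canonical,
testable choice), 3 replicate arrays per condition. All
\(\binom{14}{2} = 91\) pairwise comparisons are tested, the 91 p-value
lists concatenated into one, the matching truth lists (`TRUE` iff the
two design concentrations differ, including 0-vs-present) concatenated
alongside, and the threshold swept through every distinct p-value
(called positive means \(p \le\) threshold, ties together) to produce
sensitivity \(TP/(TP+FN)\), FDR \(FP/(FP+TP)\) (0 when nothing is
called) and 1−specificity \(FP/(TN+FP)\). A cross-hybridization
exclusion list can be injected before the curves are formed.

## The synthetic-data generator

The generator runs the physical model forward so every stage is
testable without external downloads: random 25-mers (uniform ACGT)
grouped into probesets; design concentrations from the Latin Square or
the mixture table (brain fraction 0, 5, 10, 25, 50×3, 75, 90, 95,
100%); intensities \(I = \mathrm{isotherm}(c + c_{\mathrm{ns}})\cdot
e^{\varepsilon}\) with lognormal multiplicative noise (default sd 0.1,
≈10% CV — a typical replicate CV for well-measured arrays), optional
additive noise (default 0), clipped at 0.

Two generator choices deserve justification:

* `nonspecific_pM` (default 0.05 pM) adds a small nonspecific-binding
  floor to every true concentration, so absent targets (0 pM spikes)
  still produce signal. Real chips always do (optical background,
  cross-hybridization); without the floor a 0 pM spike would yield
  intensity exactly 0 and entire probesets would be NA-filtered, a
  failure mode the real datasets never exhibit.
* Background (unspiked) probesets draw one lognormal baseline per
  probeset (median 10 pM, sdlog 1 — mid-ladder, spanning roughly two
  decades) held constant across conditions, so their fold change is
  exactly 1 in the truth.

What the generator does **not** emulate: spatial scanner artifacts,
sequence-driven cross-hybridization between the synthetic probes,
probe-position effects along the transcript, and the saturation/optical
nonlinearity of real scanners beyond the isotherm itself. Passing the
synthetic benchmarks therefore demonstrates the internal consistency
and statistical calibration of the machinery — inversion, rescaling,
summarization, testing, evaluation — not field performance on real
chips, where free-energy miscalibration and background dominate the
error budget.

## Numerical choices and degenerate inputs

* Inversion is exact algebra; the roundtrip
  intensity→concentration→intensity is tested to relative \(10^{-10}\)
  over \(c \in [10^{-3}, 10^3]\) pM and six decades of \(K\).
* Boltzmann exponents above 700 are clamped (flagged), never silent
  `Inf`.
* Zero pooled variance: equal means give \(t = 0, p = 1\); unequal
  means give \(p = 0\) flagged degenerate. p-values are floored at
  \(10^{-300}\) only inside the correlation engine.
* MBEI on an all-zero matrix returns a zero fit with a warning flag;
  rank-1 inputs recover \(\theta\) (up to the norm constraint) with
  zero residual within 3 sweeps.
* All generators, the pipeline and the writers are deterministic under
  their seeds; rewriting an artifact is byte-identical.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script runs use synthetic experiments
sized so a desk machine reproduces them in minutes: the full default
Latin Square (42 spiked + 1000 background probesets, 11 probes each,
42 arrays, 91 comparisons) for the recovery benchmark; 10,000
probesets × 5 probes for the null-calibration run; 2,000 probesets for
the mixture correlation study. These sizes are the package's declared
study conditions, chosen once to keep Monte-Carlo error well inside
the asserted bands.

## Worked example

```{r example, eval = FALSE}
nn <- load_nn_params(system.file("extdata",
                                 "sugimoto1995_rnadna_dg37.tsv",
                                 package = "langmuirchip"))
res <- run_pipeline(pipeline_config(seed = 1))
sensitivity_at(res$evaluation$curve, 0.05)
plot_eval_curve(res$evaluation$curve, type = "fdr")
```

## Known limitations

* The free-energy table is a solution-hybridization calibration; no
  salt/temperature correction, mismatch duplexes, position-dependent
  stack weighting or secondary-structure penalties are applied (the
  unweighted stack sum is the documented extension point).
* The extended-isotherm correction for target–target hybridization in
  solution is not implemented; the hyperbolic isotherm is the default
  and only form, with `saturation_A` global rather than per-array.
* Per-concentration error bars are out of scope.
* Multiple-testing correction is deliberately absent: the benchmarks
  rank raw p-values into curves.
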