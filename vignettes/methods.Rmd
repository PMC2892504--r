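---
title: "Time-delay linear regression networks: model, selection procedure, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-delay linear regression networks: model, selection procedure, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaynet)
```

## The model

`delaynet` reconstructs gene regulatory networks from short time-course
expression data under a time-delay linear model. On a uniform time grid
with spacing $h$ (minutes), a target gene $g$ is modelled as

$$ g(t) \;=\; b_0 \;+\; \sum_{i=1}^{n} a_i \, \mathit{tf}_i(t - d_i h) \;+\; \varepsilon(t), $$

where each candidate regulator $\mathit{tf}_i$ acts with its own integer
delay $d_i$ (grid steps; reported in minutes as $d_i h$) and signed
coefficient $a_i$: positive coefficients are read as activation, negative
as repression. The delay captures the lag between a change in the
regulator's transcript level and the response of the target's transcript
— translation, activation, and promoter engagement compressed into one
phenomenological number.

The model's assumptions are deliberately strong: regulation is linear and
additive in the (baseline-relative, log-scale) expression values, delays
are constant over the time course and quantized to the grid, residuals
are homoscedastic and uncorrelated, and a regulator's transcript level is
an adequate proxy for its activity. Post-translationally controlled
regulators, saturating or cooperative kinetics, and condition-dependent
rewiring all violate these assumptions; the payoff for accepting them is
a model whose two parameters per edge are directly interpretable and
cheap enough to fit genome-wide.

## Preprocessing

Raw matrices are transformed to baseline-relative log~2~ ratios: optional
log~2~, then subtraction of each gene's first-time-point value, so every
series starts at zero and values are expression *changes*. Replicate time
courses sampled at different physiological times are merged on their
common lifeline (union of time points; observations closer than
10^-6^ min are averaged). Because delays are defined in grid steps, the
observed series are then expanded onto a uniform grid by a per-gene cubic
interpolating spline; the default output is 100 grid columns spanning the
observed range.

Two spline decisions are deliberate. First, the spline *interpolates*
(passes through every observation) rather than smooths: with the short,
low-noise series this method targets, an interpolating spline makes the
pipeline exactly invertible on noiseless input — the property the
recovery tests rely on — while a penalized fit would shrink real
amplitude. Second, the boundary condition is *natural* (second derivative
zero at the ends, linear extrapolation), which reproduces affine trends
exactly and behaves conservatively at the boundaries; the `fmm`
alternative is exposed as an argument. Fewer than four observed points
cannot support a cubic spline; a linear fallback must be requested
explicitly (`allow_linear = TRUE`).

## Model selection

Fitting is ordinary least squares of the delay-aligned target on the
delay-aligned regulators plus an intercept. All fits for one target use a
fixed window starting at `max_delay_steps`, so every candidate delay and
regulator set is evaluated on the same $n$ observations and their
information criteria are directly comparable; a per-delay shrinking
window would make AICs across delays incommensurable. The criteria are
the Gaussian profile AIC with additive constants dropped,

$$ \mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2 k_p, $$

with $k_p$ counting regulators + intercept + residual variance (any
affine-equivalent AIC variant selects identically at fixed $n$), and the
adjusted coefficient of determination

$$ \bar R^2 = 1 - (1 - R^2)\,\frac{k_s - 1}{k_s - n_r - 1}, $$

with $k_s$ the sample size and $n_r$ the number of regulators.

Selection proceeds in two steps per target:

1. **Screening and ranking.** Each candidate is fitted singly at every
   delay $0 \dots$ `max_delay_steps`; the best (smallest-AIC) fit
   represents the candidate. Candidates whose best fit misses the
   single-regulator cutoff (default $\bar R^2 \ge 0.8$) are treated as
   irrelevant to this target; survivors are ranked by AIC (stable sort on
   ties, so input order breaks them deterministically).
2. **Forward selection of regulators and delays.** The selected set is
   seeded with the top-ranked regulator at its best single-regulator
   delay. Remaining candidates are tested in rank order: all delays of
   the candidate are traversed while the delays of the already-selected
   set stay frozen, and the candidate joins at its best delay only if the
   joint AIC strictly decreases. Acceptance is strict improvement with no
   tolerance — the $+2$-per-parameter penalty already guards against
   ties. A variable once added is never removed, and a candidate whose
   addition would alias an existing column (same regulator at the same
   delay, a constant column) is discarded with a log entry.

The model is reported only if its final $\bar R^2$ reaches the
multiple-regression cutoff (default 0.9) and, after iterative pruning and
refitting, every coefficient magnitude lies within
[`min_coef`, `max_coef`] = [0.25, 4]. The magnitude floor removes
regulators with negligible effect that survived on AIC alone; the ceiling
guards against wild coefficients from near-collinear designs.

Three aspects of this procedure were genuinely open and are resolved as
package design choices, each with the alternative exposed as a
configuration flag:

* **Intercept.** An intercept is always included. Baseline subtraction
  makes series start at zero but does not centre the fitting window, and
  standard linear-model routines include one by default;
  intercept-free fitting is not offered.
* **Single pass vs. prefix restarts.** The default is one forward pass
  seeded with the top-ranked regulator. An alternative reading of
  "testing all top regulator sets" — restarting the pass from every
  ranking prefix $\{tf_1 \dots tf_i\}$ and keeping the lowest-AIC result
  — is available as `restart_prefixes = TRUE`; it multiplies cost by the
  ranking length and, on every fixture in the test suite, returns the
  same model.
* **When to enforce coefficient bounds.** By default bounds are enforced
  after selection, by iteratively removing offenders and refitting
  (`bounds_during_selection = TRUE` instead rejects candidates during the
  pass). Post-hoc enforcement lets a weak regulator participate in the
  AIC competition before being pruned, which is the more conservative
  reading of the bounds as a reporting filter.

### Numerical choices

* Saturated fits (RSS $= 0$, common on noiseless fixtures) have the RSS
  floored at $n \times 10^{-12}$ so the AIC stays finite; the perfect
  model still wins every comparison, and adding a parameter to a perfect
  model costs exactly $+2$.
* Delay ties break toward the smaller delay (the simpler temporal
  explanation); ranking ties preserve candidate input order.
* Rank-deficient designs drop the aliased columns (via the pivoted QR
  inside `lm.fit`) with a warning rather than failing.
* $\bar R^2$ is undefined when $k_s \le n_r + 1$; it is returned as `NA`
  and fails every cutoff comparison.
* A constant target (zero total sum of squares) is assigned $R^2 = 0$.
* Selection contains no randomness: identical inputs and parameters give
  bit-identical model lists.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `single_adj_r2` | 0.8 | — | screening cutoff for a candidate's best single-regulator fit |
| `multiple_adj_r2` | 0.9 | — | acceptance cutoff for the final model |
| `max_delay_steps` | `floor(0.1 · n_grid)` | grid steps | largest delay traversed; also the fitting-window offset |
| `min_coef`, `max_coef` | 0.25, 4 | expression ratio per ratio | admissible coefficient magnitudes |
| `n_out` | 100 | columns | interpolation grid size |

The defaults are the method's published operating point. The delay cap of
one tenth of the grid keeps the fitting window at 90% of the series and
bounds the lag search to a biologically plausible fraction of the
experiment; `max_delay_steps = 0` switches the method into a delay-free
forward-selection regression, the natural baseline for quantifying what
the delays buy.

## The synthetic benchmark

Because curated time courses cannot be shipped with the package, every
layer is exercised against a seeded generator
(`make_benchmark()`) whose defaults define the standard benchmark used in
the tests: 10 regulators and 20 targets on a 100-point grid (spacing
2 min), one to three regulators per target, coefficient magnitudes in
[0.3, 2] with random signs, delays of 0–5 grid steps, intercepts in
[−0.5, 0.5], and Gaussian observation noise of sd 0.1 on a signal range
of roughly [−3, 3] — keeping single-regulator fits near the 0.8–1.0
adjusted-R² regime in which the screening step is meaningful.

Regulator curves emulate a synchronised, cell-cycle-like experiment: a
shared two-cycle oscillation (amplitude 1.3–1.6, in phase across genes)
carries the strong mutual co-expression of such data, while two to three
gene-specific harmonics (amplitude 0.5–0.8, periods between 1/14 and 1/4
of the span) plus a low-amplitude smooth spline component give every
regulator an individual temporal signature. The balance between the two
is what makes the benchmark informative: the shared oscillation lets each
true regulator of a multi-regulator target pass the marginal screen, and
the individual signature pins the regulator's delay.

Targets are drawn inside the method's operating regime by rejection
sampling on two *data* properties, checked on the noiseless series:
every true regulator, fitted singly, (a) reaches the screening cutoff
and (b) attains its best fit at its generating delay. Without (a), a
secondary regulator of a multi-regulator target would be screened out by
step 1 regardless of implementation correctness — with mutually
uncorrelated regulators two of them cannot both explain 80% of one
target — and without (b) the greedy pass would freeze a misleading
delay. Draws failing the constraint are redrawn (deterministically, on
the same seeded stream), relaxing the regulator count only after 20
failures; a target's delays are drawn without replacement whenever the
delay range allows, since coincident delays are the one configuration in
which they are not separately identifiable. These constraints describe
the data-generating regime — strongly co-expressed genes with marginally
visible lags — not the fitted pipeline, so recovery tests remain a real
check of the implementation.

What passing the benchmark does and does not show: exact noiseless
recovery plus high precision/recall under noise demonstrates that the
screening, selection, delay estimation and bounds machinery is correct
*within the model class the data were generated from*. Real expression
data violate that class — activity–transcript mismatch for
post-translationally controlled factors, nonlinear and combinatorial
regulation, unsynchronised cells smearing delays, array noise that is
neither Gaussian nor homoscedastic — so benchmark performance is an
upper bound, not a forecast, of performance on biological data.

## Evaluation against reference networks

Predicted edges are scored against one or more reference edge sets, each
flagged directed (curated regulator→target collections) or undirected
(association databases; either orientation matches). Per edge and
reference the flag is 1 (pair present), 0 (both genes in the reference's
universe, pair absent), or NA (a gene outside the universe). References
combine by OR: an edge with a 1 anywhere is true, an edge with a 0 or 1
anywhere is scorable, accuracy = true/scorable, and an all-NA edge set
has *undefined* (not zero) accuracy. The universe defaults to all
identifiers appearing in the reference, since an edge list alone cannot
distinguish "known absent" from "never studied"; an explicit universe
can be supplied. Probe-level identifiers of the form
`NAME_ORF_probe` can be collapsed to ORF level, deduplicating parallel
probes by the higher adjusted R² and dropping self-loops the collapse
creates.

## Problem sizes and runtime

The test suite and the acceptance script are sized for interactive use:
the standard benchmark (10 regulators × 20 targets × 100 grid points,
delay cap 10) fits in a few seconds; the greedy-versus-exhaustive
comparison enumerates all regulator subsets × delay tuples on 200
instances of ≤3 candidates × ≤3 delay steps on 36–48-point grids in
under half a minute. The full suite runs in well under a minute on one
CPU. Larger problems scale as
(candidates × delays) per screening pass and (survivors × delays) per
selection round, per target; targets are independent and could be
processed in parallel, though the package deliberately keeps a
single-threaded, deterministic code path.

## Known limitations

* Delays are bounded by `max_delay_steps` and quantized to the grid;
  regulation slower than the cap, or lags between grid points, are
  approximated by the nearest admissible delay.
* Forward selection is greedy: a variable once added is never removed,
  and frozen delays are not revisited, so strongly correlated candidate
  pools can yield locally rather than globally optimal models (the
  exhaustive-search tests quantify this on small instances).
* The reported yeast-scale behaviour of the original method (specific
  probe-level coefficients and network sizes) can be reproduced with
  `tests/testthat/test-acceptance.R` only when the processed cell-cycle
  matrices are supplied locally (`options(delaynet.yeast_dir = ...)`);
  they are not redistributable with the package, and reference-database
  consistency percentages additionally depend on database snapshots.
* One probe, one gene: the package performs no probe summarisation
  beyond the optional ORF-level collapse of edges.
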