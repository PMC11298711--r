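---
title: "Threshold-free network-based statistics for structural connectomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free network-based statistics for structural connectomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfnbs)
```

## The problem

Structural connectivity matrices (SCMs) summarize a subject's white-matter
wiring as a symmetric node-by-node matrix over a gray-matter parcellation,
with edge weights such as the cross-sectional area (CSA) of the fiber bundle
connecting two parcels. Comparing SCMs between a patient group and controls
poses three linked problems:

1. **Scanner batches.** Cohorts acquired across a scanner software upgrade
   carry additive (bias) and multiplicative (variance) batch effects on edge
   weights that can masquerade as, or mask, group differences.
2. **Mass-univariate inference on edges.** With thousands of edges, per-edge
   tests need family-wise error (FWE) control, but a fixed cluster-forming
   threshold (classical network-based statistics) makes results sensitive to
   an arbitrary choice.
3. **Reporting.** Edge-level results need aggregation into interpretable
   units — here, the 15 unordered pairs of five lobe classes (frontal,
   occipital, parietal, temporal, subcortical).

`tfnbs` implements the full chain — harmonization, edge-wise GLM,
threshold-free enhancement over graph components, permutation inference and
lobe-pair summaries — plus a synthetic-cohort generator so every stage is
testable with known ground truth and no MRI data.

## Edge-weight model and the synthetic generator

Edge weights are modeled as log-normal: empirically, log-transformed SCM edge
weights have approximately normal, aligned distributions, and all modeling
here happens on the log scale (weights are exponentiated only for display
and file output). The generator draws, for present edge $e$ and subject $i$,

$$\log w_{ei} = \mu_e
  - s\,\sigma_e\,\mathbf{1}[i \in B]\,\mathbf{1}[e \in \text{planted}]
  + \beta_{age}\,\mathrm{age}_i + \beta_{sex}\,\mathrm{sex}_i
  + \gamma_{b(i)} + \delta_{b(i)}\,\varepsilon_{ei},
  \qquad \varepsilon_{ei} \sim N(0, \sigma_e^2)$$

with a *shared support mask*: an edge is either present in every subject or
absent in all. This mirrors the practical situation after prevalence
filtering (zero-weight edges are treated as structurally absent) and keeps
the edge-wise GLM well-posed without imputation.

Defaults emulate a two-group epilepsy connectome study design: 50 controls
and 92 patients, 162 nodes (the cortico-subcortical Destrieux-style layout,
81 nodes per hemisphere), two scanner batches, ages uniform on 18–60 years,
and a *connected* planted subnetwork on which the patient group's mean log
weight is decreased — decrease being the dominant directionality such
studies report. Values the emulated design does not pin down were fixed once
at what we consider realistic for SIFT2-weighted Destrieux connectomes and
are not tuned: edge density 0.30, baseline log-weights $\mu_e \sim N(1,
0.5^2)$, per-edge noise SD $\sigma_e \sim U(0.3, 0.6)$, batch shift 0.5 and
noise scale 1.2 for the second batch, planted effect size 0.8 SD. The
`destrieux162` parcellation is a synthetic stand-in lookup with
representative per-lobe counts (26 frontal, 16 parietal, 18 temporal, 14
occipital, 7 subcortical per hemisphere), not the actual atlas table.

What the generator deliberately does **not** emulate: spatial correlation
between neighboring edges, distance- or lobe-dependent edge density,
heavy-tailed weight outliers, subject-specific support, and any
image-space artifacts. Passing tests therefore demonstrate correctness of
the statistical machinery under the stated model, not robustness to every
property of real tractography data.

## Harmonization

Batch effects are removed with a location/scale empirical-Bayes model
(ComBat family), fitted and applied as two separate steps so the fitted
model — batch effects, hyperpriors, preserved coefficients — is inspectable.
Per edge $e$,

$$y_{ei} = \alpha_e + X_i^\top \beta_e + \gamma_{eb} + \delta_{eb}\,\epsilon_{ei},$$

where $X$ holds the covariates whose effects must be *preserved* (group,
age, sex), and batch effects are constrained so that, weighted by batch
size, they sum to zero. Residuals are standardized by the pooled residual SD;
naive per-batch location ($\hat\gamma$) and scale ($\hat\delta^2$) estimates
on the standardized data are then shrunk toward priors shared across edges —
normal for $\gamma$, inverse-gamma for $\delta^2$, hyperparameters by method
of moments — by iterating the conditional posterior means to convergence
(absolute change below `tol = 1e-4` on both, at most `max_iter = 100`
iterations; conventional for EB iterations of this kind). `max_iter = 0`
returns the unshrunk estimates. The harmonized value is
$(z_{ei} - \gamma^*_{eb})/\delta^*_{eb} \cdot \hat\sigma_e + \alpha_e +
X_i^\top\hat\beta_e$.

Numerical choices worth knowing:

* Within-batch naive variances use the MLE denominator $n_b$, matching the
  pooled variance's denominator $n$. This makes the single-batch case an
  exact identity map (and $\gamma^* = 0$, $\delta^{*2} = 1$ exactly), which
  is also why the pipeline can leave harmonization on for single-batch data.
* Degenerate hyperpriors (zero across-edge variance of the naive estimates,
  as happens with a single batch) disable shrinkage for that parameter
  rather than dividing by zero.
* Only the parametric EB path is implemented; batch means scanner-software
  epoch, a single factor (in the emulated design the slice-direction change
  was collinear with the software upgrade).

The test suite cross-checks the harmonized values against the independent
`sva::ComBat` implementation (correlation > 0.9999 on a two-batch
simulation; small differences trace to the variance-denominator convention).

## Edge-wise GLM

For a two-level contrast with nuisance covariates, each edge gets an
ordinary least-squares fit of its (log, harmonized) value on
`[intercept | group indicator | age (centered) | sex]`, and

$$t_e = \frac{c^\top \hat\beta_e}
 {\sqrt{\hat\sigma_e^2\, c^\top (X^\top X)^{-1} c}},$$

assembled into a symmetric statistic graph. Age is centered at the sample
mean (stabilizes the intercept; irrelevant to the contrast). Subgroup
contrasts — seizure-history positive vs negative, impairment cluster vs
controls — are the same machinery with a different grouping column; subjects
outside the contrasted levels are dropped with a message. Degenerate edges
(zero residual variance) are capped at `t_cap = 1e6` so enhancement stays
finite. Both directionalities are analyzed as two one-sided runs (on $t$ and
$-t$) with $\alpha$ applied per direction, matching how such results are
conventionally reported; this is configurable.

"Adjusted" values for box-plot reporting subtract only the centered nuisance
fit from the full model, so the group-mean difference of adjusted values
equals the GLM contrast exactly.

## Threshold-free enhancement and permutation inference

The statistic graph is enhanced without choosing a cluster-forming
threshold. For an evenly spaced ladder $h_k = k\,h_{max}/K$,

$$\mathrm{score}_e \;=\; \sum_{k:\,t_e > h_k}
   \mathrm{extent}_e(h_k)^{E}\; h_k^{H}\; \Delta h,$$

where $\mathrm{extent}_e(h)$ is the number of edges in the suprathreshold
component containing $e$ — components defined by connectivity through shared
nodes in the graph, not a spatial lattice. This is the "cluster size times
cluster height, summed across thresholds" construction; defaults $E = 0.5$,
$H = 2.25$ and $K = 100$ are the conventional enhancement exponents, exposed
as parameters since reported analyses rarely print them. The implementation
is an incremental union-find sweep in C++ (edges are inserted as the ladder
descends), verified against a naive R threshold-loop oracle to $10^{-10}$
and against the analytic integral $\int_0^t h^H\,dh$ for an isolated edge.

Inference uses permutations (default `P = 5000`, matching the emulated
design; simulations in the tests use smaller P):

* **Freedman–Lane** (default): residuals of the reduced nuisance-only model
  are permuted, the nuisance fit re-added, and the full-model statistics
  recomputed — the standard scheme when nuisance covariates are present.
* **simple_label**: whole-subject (Manly-style) permutation, covariates
  traveling with the label; with no covariates this is the textbook
  two-sample permutation test, and for a pure group design with fewer
  distinct assignments than P the engine enumerates all of them exhaustively
  (with a warning).

Corrected p-values compare each edge's observed score with the permutation
distribution of the *maximum* score over all edges (FWE control);
uncorrected p-values use each edge's own null. Both use the add-one
estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(P+1)$, which bounds p
away from zero and counts ties conservatively; consequently
$p_{corr} \ge p_{unc}$ holds elementwise by construction.

The top of the threshold ladder under permutation was a genuinely open
design choice, and we settled it empirically. Fixing $h_{max}$ from the
*observed* graph for all permutations (a common convention, `h_max_policy =
"observed"`) makes the enhanced score a functional that depends on the
observed data: null maxima get truncated at the observed ladder top while
the observed maximum never is. In our global-null simulations this
measurably inflates the family-wise error at nominal .05 to roughly
0.09–0.13. The default is therefore `h_max_policy = "permutation"`: every
graph — observed or permuted — is integrated up to its own maximum, so the
score is the same functional of each graph, exchangeability is exact, and
the measured FWE returns to the nominal rate. The fixed-observed variant is
retained as an option for comparability with analyses that used it.

A second calibration property worth knowing: per-edge uncorrected p-values
are *valid but not uniform* under the null. A one-sided enhanced score is
zero whenever $t \le 0$ in the tested direction, so about half the null
mass lands exactly at $p = 1$. Tail rates are near-nominal
($P(p \le .05) \approx .05$), which is the property the test suite asserts;
a strict Kolmogorov–Smirnov uniformity check rejects by construction for
this class of estimator.

## Reporting

Significant edges ($p \le \alpha$, corrected or uncorrected) are summarized
per unordered lobe pair. Percentages are normalized by the total number of
significant edges in the (direction, correction) stratum — the "percentage
of significant connections" reading — so they sum to 100 whenever anything
is significant; normalizing instead by the number of available edges per
lobe pair is exposed as an option (`denominator = "possible"`). Top
connections are ranked by corrected p ascending, ties broken by $|t|$
descending and then lexicographic edge id.

## Problem sizes used by the test suite

The suite exercises the full machinery at sizes chosen to make the
statistical checks informative while keeping the default run quick:
TFCE-oracle equivalence on 100+ random graphs of up to 8 nodes; exhaustive
permutation enumeration at $n = 3+3$; null calibration on 200 simulated
cohorts of 20 nodes and 30+30 subjects at $P = 200$; planted-subnetwork
recovery (10-edge connected component, effect 1 SD) on 40+40 subjects at
$P = 500$ over 20 seeds; harmonization recovery on 100+100 subjects with
batch shift 1.0 and scale 1.5. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

## Known limitations

* Inference is edge-level only; no fixed-threshold (classical NBS)
  component-level inference, and no global graph-theoretic measures.
* Exchangeability is whole-subject; no block or site-aware permutation
  structure beyond the two schemes above.
* The harmonization model is single-factor location/scale; no hierarchical
  multi-site, GAM, or longitudinal variants, and no non-parametric prior
  path.
* The generator's independence of edges given the support mask means power
  estimates from simulations should be read as machinery checks, not as
  predictions for real tractography data.
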