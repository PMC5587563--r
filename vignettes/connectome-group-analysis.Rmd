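---
title: "Group analysis of weighted structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of weighted structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopy)
```

# The problem

Diffusion tractography yields, per subject, a matrix of streamline
counts between pairs of brain regions. Comparing two groups of such
weighted networks raises three methodological problems this package
addresses in one coherent pipeline:

1. **Construction.** Raw counts depend on region size. Counts are
   normalised by the product of seed and target region volumes,
   symmetrised, and interpreted as weighted adjacency matrices. The
   reference parcellation has 72 regions: 33 cortical
   (Desikan–Killiany) plus thalamus, lentiform and caudate nucleus per
   hemisphere.
2. **Thresholding.** There is no canonical cut-off separating true from
   spurious connections, so every analysis is carried out across a grid
   of edge densities $\kappa$. At each $\kappa$ a binary mask retains
   the strongest $(100\kappa)\%$ of connections *of the pooled
   group-median summary matrix*, and the same mask is applied to every
   subject of both groups, so that thresholding itself cannot create a
   group difference. Original weights are kept; nothing is binarised.
3. **Inference across thresholds.** Testing at every density inflates
   the family-wise error. The multi-threshold cluster permutation
   (MTCP) procedure calibrates the *maximum* group statistic across the
   whole grid by permutation and summarises effects by the
   supercritical area-under-the-curve, which rewards both strength and
   persistence of an effect.

# Graph measures

Edge lengths are reciprocal weights, $l_e = 1/w_e$: stronger
connections are shorter. On a network with $n$ nodes,

* **global efficiency**
  $\varepsilon = \frac{1}{n(n-1)}\sum_{s \neq t} d(s,t)^{-1}$, the mean
  inverse shortest-path distance over ordered pairs (integration);
  disconnected pairs contribute 0;
* **weighted clustering**
  $C_v = \frac{1}{k_v(k_v-1)} \sum_{x,y}
  (w_{vx} w_{vy} w_{xy})^{1/3}$, averaged over nodes (segregation).
  Weights are first divided by the global maximum so every
  geometric-mean term lies in $[0,1]$. Two denominators are available
  for $k_v$: the node **degree** (the convention of the standard brain
  connectivity toolboxes, guaranteeing $C_v \le 1$; the pipeline
  default) and the node **strength** $\sum_x w_{vx}$ (the formula as
  often printed). The choice is exposed rather than silently resolved
  because the two conventions genuinely coexist in the literature;
  `weighted_clustering(..., denominator =)` selects one.
* **modularity** $Q$ of the best partition found by seeded multilevel
  (Louvain) optimisation, best of 10 restarts by default. $Q$ is
  invariant to a global weight rescaling.
* **nodal measures**: strength (row sum), local clustering ($C_v$),
  and local efficiency — the global efficiency of the subgraph induced
  by a node *together with* its neighbours. Including the node itself
  follows the definition used for this pipeline; the neighbour-only
  convention is available via `include_self = FALSE`. Nodes with fewer
  than two neighbours get 0.

Efficiency and clustering increase with overall connection strength,
which confounds topology in group comparisons. They are therefore
normalised by their mean over 150 randomised reference networks that
preserve size, the exact degree sequence and the weight multiset:
Maslov–Sneppen double-edge swaps (10 attempted swaps per edge)
randomise the topology, then the original weights are re-assigned by
rank-matching node strength — the largest remaining weight goes to the
edge whose endpoints have the largest remaining strength deficit — so
per-node strengths are approximately preserved (the paper-style
constraint names the invariants, not an algorithm; this is our
algorithmic choice and its preservation contract is asserted by tests).
Modularity is scale-invariant and never normalised.

# Statistical machinery

**Strength comparison.** Per subject and region-set (left, right,
interhemispheric), quartiles (type-7 linear interpolation; the
convention choice is ours) of the nonzero weight distribution form a
9-fold family of statistics. Family-wise inference uses the
max-statistic permutation test: for each relabeling of group
membership (identity included, so $p \ge 1/n_{\mathrm{perm}}$), the
maximal $|t|$ over the family is recorded; adjusted p-values are
proportions of relabelings whose maximum reaches the observed $|t|$.
Group-averaged edge-weight distributions (edge-wise mean within group)
are compared by two-sample Kolmogorov–Smirnov tests, and median
strengths by a 2 × k mixed ANOVA (between: group; within: region-set)
with partial $\eta^2$ and Hedges' g
($J = 1 - 3/(4(n_1+n_2-2)-1)$ bias correction) effect sizes.

**MTCP.** For a per-subject measure curve over the density grid
(global grid 0.05–0.95 by 0.05; nodal grid 0.10–0.90 by 0.02), a
pooled two-sample t is computed per density with sign convention
*first group minus second* (controls first: positive t = deficit in
patients). One set of relabelings is evaluated at every density;
$t_{\mathrm{crit}}$ is the 95th percentile (type-7) of the
per-relabeling maximal $|t|$. When the observed maximum exceeds
$t_{\mathrm{crit}}$, the supercritical cluster is the maximal
contiguous run around the peak with $|t| > t_{\mathrm{crit}}$, and the
effect size $A$ is the area of the piecewise-linear $|t|$ curve above
$t_{\mathrm{crit}}$ over that run, with the run boundaries extended to
the interpolated crossings of $t_{\mathrm{crit}}$. The extension
matters only at cluster edges; it guarantees the invariant $A > 0$
exactly when the peak is supercritical (a literal trapezoid over a
single-point run would be 0). $A_{\mathrm{crit}}$ is the mean
supercritical area of the relabelings; because it is ambiguous whether
relabelings with no supercritical excursion should count, both
estimates are reported (`A_crit` excludes zeros, `A_crit_all` includes
them). The family-wise p is the proportion of relabelings whose
maximal $|t|$ reaches the observed maximum. The nodal screen runs this
machinery per region with a shared relabeling set and per-region
critical values, reporting group means at the peak density, Hedges' g,
and the two ratios $t_{\max}/t_{\mathrm{crit}}$ and
$A/A_{\mathrm{crit}}$ that flag significance and persistence.

Degenerate densities (missing values from fragmented graphs, or zero
variance) are dropped with a warning before testing.

**Clinical association.** Network measures are correlated with a
severity score by Pearson and Spearman coefficients, with and without
age as a covariate (partial correlation via residualising both
variables on age; t-test on $n-3$ degrees of freedom). A linear and a
two-parameter exponential model $y = a e^{bx}$ are compared by the
small-sample Akaike criterion
$\mathrm{AICc} = n \ln(\mathrm{RSS}/n) + 2k + 2k(k+1)/(n-k-1)$ with
$k$ counting the residual variance alongside the coefficients;
absolute AICc values are convention-dependent and only differences are
meaningful, which the relative likelihood
$\exp(\Delta \mathrm{AICc}/2)$ makes explicit. The exponential fit is
seeded from a log-linear regression with five jittered restarts, best
RSS kept.

# Numerical conventions

* **Edge-count rounding**: the retained count is
  $\mathrm{round}_{1/2\uparrow}(\kappa\, n(n-1)/2)$, half away from
  zero — the unique convention consistent with the four reference
  counts 128/2428 (72 nodes) and 32/599 (36 nodes); note
  $0.05 \cdot 630 = 31.5 \to 32$ and $0.95 \cdot 630 = 598.5 \to 599$,
  where round-half-to-even would give 598. A round-to-6-decimals guard
  protects ties from floating-point representation
  ($0.95 \cdot 630 = 598.4999\ldots$ in doubles).
* **Tie-breaking** at the retention boundary: descending weight, then
  ascending row and column index — masks are reproducible and nested
  across $\kappa$. All off-diagonal pairs are ranked, structural zeros
  last, so the nominal density is reached even for sparse summaries
  (zero-weight "edges" are inert in every measure).
* **Symmetrisation** of directed counts: arithmetic mean of the two
  volume-normalised directed entries.
* **Seeding**: every stochastic step (rewiring, Louvain restarts,
  relabelings, simulation) takes a seed; child seeds derive from a
  master seed through a counter, and the caller's RNG state is always
  restored. Fixed seed implies bit-identical output.

# The synthetic cohort generator

`simulate_cohort()` generates the conditions the analysis assumes: a
symmetric lognormal population template (intra-hemispheric blocks with
log-mean $\log 0.3$, log-SD 0.8; interhemispheric mean divided by 3,
reflecting the weaker callosal connectivity that drives the large
region effect in strength comparisons), per-subject elementwise
lognormal noise (log-SD 0.3), ROI volumes lognormal around 5000 mm³
used to reconstruct raw counts so `build_connectome()` round-trips
exactly, group sizes 13 + 13, and ages N(34.5, 9²). A patient-specific
deficit multiplies the intra-right-hemisphere block by $1-\delta$
($\delta = 0$ is the exchangeable null used for type-I calibration;
$\delta = 0.3$ is the default effect condition).

Clinical scores are generated for patients only, on a bounded
positive severity scale (clamped to $[1, 100]$), linked to
right-hemisphere global efficiency through the subject's *deviation
from the patient-group mean efficiency*. Anchoring the link to the
deviation rather than to absolute efficiency is deliberate: the
absolute efficiency scale varies between template draws (and
subject-level noise biases it upward relative to the template), so an
absolute-scale link would saturate the bounded score range for many
cohorts. Defaults: linear link $35 + 400\,d$ with noise SD 8 (score
SD comparable to clinical severity scales); exponential link
$20\,e^{50 d}$ with noise SD 5, the slope set so that the curvature
signal — the quadratic departure $a (b\,\mathrm{sd}_d)^2/2$ from the
best line at the typical deviation spread
$\mathrm{sd}_d \approx 0.02$ — is about twice the score noise, which
is the regime in which a 13-subject cohort can identify the family.
Both links stay inside the model families fitted by
`fit_and_compare()`.

What the generator does **not** emulate: spatial embedding and
distance-dependent connectivity, tractography false positives with
anatomical structure, volume–connectivity coupling, hub organisation
beyond what lognormal weights induce, and site or motion artefacts.
Calibration results on these cohorts therefore validate the
*statistical machinery* (error control, power, recovery), not the
anatomical realism of any particular dataset.

# Problem sizes used in validation

The shipped tests and the acceptance script calibrate at sizes chosen
to make Monte-Carlo error small relative to the bands they check while
keeping runs interactive: oracle equivalence on 50 random graphs with
up to 10 nodes at tolerance $10^{-10}$; null-model calibration with
the full 150-realisation ensemble on 36-node networks; MTCP type-I on
500 null cohorts (200 in the script) and power on 100 (50) cohorts at
$\delta = 0.3$, both with 200 relabelings on the 19-point global grid;
model-selection recovery on 100 (60) exponential-link cohorts.
Release-scale settings (10⁶ relabelings for the strength test, 10³ for
MTCP, 150-realisation ensembles per subject and density) remain the
function defaults.

# Limitations

* The strength-rank weight reassignment preserves per-node strengths
  only approximately (correlation > 0.9 contract); exact
  strength-preserving nulls would require iterative adjustment.
* Louvain optimisation is a heuristic; restarts reduce but do not
  eliminate the risk of a suboptimal partition on adversarial graphs.
* With 200 relabelings the granularity of MTCP p-values is 1/200;
  release runs should use the 10³ default or more.
* The "as printed" clustering denominator (strength) can produce
  values outside $[0,1]$ when scaled strengths fall below 1; it is
  provided for comparability, not recommended as a default.
* Absolute supercritical areas depend on the unit of the density axis;
  only comparisons against $A_{\mathrm{crit}}$ from the same grid are
  meaningful.
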