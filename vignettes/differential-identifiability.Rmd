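---
title: "Differential identifiability of connectome network properties: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential identifiability of connectome network properties: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idiffr)
```

## The problem

A functional connectome (FC) is the matrix of Pearson correlations between
the activity time courses of brain regions, one square symmetric matrix per
subject, condition and run.  When the same subject is scanned twice ("test"
and "retest"), their two connectomes resemble each other more than they
resemble anyone else's: connectomes carry a subject fingerprint.  `idiffr`
quantifies that fingerprint — for the connectome itself and for eight
weighted-graph network properties derived from it — and asks whether a
group-level PCA denoising step strengthens it, and whether the same step
makes the derived properties more sensitive to the task a subject performed.

The central score is differential identifiability.  Stack each subject's
vectorized data as columns (2S columns for S subjects), correlate every test
column with every retest column to get the S × S identifiability matrix, and
define

$$ I_{\mathrm{diff}} = (I_{\mathrm{self}} - I_{\mathrm{others}}) \times 100, $$

where $I_\mathrm{self}$ is the mean diagonal (same subject across runs) and
$I_\mathrm{others}$ the mean off-diagonal.  Higher $I_\mathrm{diff}$ means a
stronger subject fingerprint.

## Synthetic cohorts

Real test–retest cohorts are large and access-restricted, so the package
ships a generator whose output has exactly the algebraic structure the
framework assumes.  Each run's nodal time series is a linear mixture of three
standard-normal latent factor matrices:

* a **subject factor**, drawn once per subject and shared by all of that
  subject's runs — the fingerprint;
* a **condition factor**, drawn once per condition and shared by all subjects
  — the task signature;
* **run noise**, drawn fresh for every run.

The connectome is the Pearson correlation matrix of the mixed series, so
every generated matrix is automatically symmetric, unit-diagonal and bounded
by ±1 — including rank-deficient cases when the series are shorter than the
parcellation, which the generator permits with a warning.  Working through
time series rather than perturbing matrices directly is deliberate: the
random-walk machinery downstream assumes genuine correlation matrices, and a
direct matrix perturbation can easily leave the valid cone.

Defaults mirror a full test–retest study: 100 subjects, a 374-node
parcellation (360 cortical + 14 subcortical regions), two rest sessions plus
seven tasks (each with test and retest, hence 18 matrices per subject), and
1,200 time points per run — the order of a typical resting-state acquisition.
The mixture weights default to `subject_signal = 0.6`,
`condition_signal = 0.2`, `noise_signal = 0.4`: a clearly detectable but not
saturated fingerprint, a weaker task signature, and enough run noise that
denoising has something to remove.  These weights are free parameters of the
simulation, not estimates of any particular dataset; analyses of real data
should treat them only as a sandbox.

What the generator does **not** emulate: hemodynamics, temporal
autocorrelation, motion and physiological artifacts, global-signal effects,
site or session drifts, and the heavy-tailed, spatially structured
correlations of real parcellations.  Passing tests on synthetic cohorts
therefore demonstrates that the algorithms do what they claim on data with
known structure — not that any particular real dataset has a fingerprint of
a given size.

## The eight network properties

All measures operate on the clamped graph: every non-positive correlation is
replaced by machine epsilon (`2.22e-16`).  Clamping zeros as well as
negatives is intentional — the goal of the constant is a complete, connected
graph whose random-walk chain is regular, and a surviving zero edge would
defeat both.  Edge lengths are inverse weights throughout, so strong
correlations are short hops.

1. **Degree strength** $K_i = \sum_j w_{ij}$.
2. **Shortest path length** $\mathrm{SPL}_{ij} = \min_\pi \sum_{(l,m) \in \pi} 1/w_{lm}$,
   computed by Dijkstra's algorithm (igraph).
3. **Search information** $\mathrm{SI}_{ij} = -\log_2 P(\pi_{i \to j})$, the
   bits needed to steer an unbiased walker along the shortest path.  The path
   probability multiplies the *weighted* transition probabilities
   $w_{l,\mathrm{next}}/K_l$ over every node on the path except the target.
   A binary-degree product would ignore the weights entirely and reduce the
   measure to its unweighted special case, which is inconsistent with a
   weighted-graph analysis; the weighted form is used.  If several shortest
   paths tie exactly, their probabilities are summed before the logarithm —
   with continuous correlation weights ties have probability zero, so this is
   a safety rule, and tie detection deliberately uses exact floating-point
   equality rather than a tolerance (deterministic, and correct in the
   measure-zero sense).
4. **Mean first passage time**, in steps, via the Kemeny–Snell fundamental
   matrix $Z = (I - P + \Phi)^{-1}$ with $P = W/K$ row-stochastic and $\Phi$
   the matrix whose every **row** is the stationary distribution $\varphi$
   ($\varphi_i = K_i / \sum_j K_j$ for this reversible chain).  The row
   orientation is the one under which
   $\mathrm{MFPT}_{ij} = (\zeta_{jj} - \zeta_{ij})/\varphi_j$ is exact; the
   tests verify it against per-target linear hitting-time systems and
   Monte-Carlo walks.
5. **Driftness** $W_{ij} \ge 1$: how much slower the random walk is than the
   optimal route.  For the bound to be a theorem the numerator and
   denominator must share units, so the numerator is the walker's expected
   accumulated journey *length* (each traversed edge costs $1/w$), computed
   exactly from the fundamental matrix with per-step cost
   $r_i = \sum_k P_{ik}/w_{ik}$:
   $H_{ij} = (\zeta_{jj} - \zeta_{ij})\,\bar r/\varphi_j + u_i - u_j$ with
   $u = Zr$, $\bar r = \varphi^\top r$ (this reduces to MFPT when every cost
   is 1).  Dividing the step-count MFPT by the weighted SPL instead would mix
   units and can drop below 1 on graphs whose direct edges are weak — the
   bound would then be false, not approximately true.  Every walk's journey
   is at least the shortest path, so $W_{ij} \ge 1$ holds on every input by
   construction.  One consequence of clamping worth knowing: an
   eps-edge is traversed with probability $\sim \varepsilon/K$ at cost
   $1/\varepsilon$, so each clamped pair contributes a finite amount to the
   expected journey; simulations cannot see these rare-huge events, which is
   why the Monte-Carlo cross-check runs on fully positive graphs.
6. **Communicability** $C = e^{D^{-1/2} A D^{-1/2}}$, $D = \mathrm{diag}(K)$:
   a hub-normalized weighted count of all walks (matrix exponential via the
   Matrix package).
7. **Clustering coefficient** (Onnela's weighted form)
   $CC_i = 2 t_i / (k_i (k_i - 1))$ with
   $t_i = \tfrac12 \sum_{j,h} (w_{ij} w_{ih} w_{jh})^{1/3}$ and $k_i$ the
   *binary* degree.  With a weighted degree in the denominator the measure
   would no longer be normalized to $[0, 1]$ for correlation weights; the
   binary convention keeps it a proper coefficient (and after clamping,
   $k_i = n - 1$ for every node).
8. **Betweenness centrality**, weighted shortest-path betweenness (Brandes,
   via igraph), normalized by the $(n-1)(n-2)$ ordered pairs so
   $B_i \in [0, 1]$.

Degree strength, clustering and betweenness are node properties (length-n
vectors); SPL and communicability are symmetric pairwise properties
(vectorized as the upper triangle, $n(n-1)/2$ features); search information,
MFPT and driftness are asymmetric (all $n(n-1)$ ordered pairs are kept —
discarding one triangle would discard information).

## The identifiability framework

For one condition the feature matrix has F rows (features) and 2S columns
(test block then retest block, subjects sorted).  PCA is computed by singular
value decomposition of the column-centered matrix: the mean feature vector —
the group-average connectome or property — is removed before decomposition
and added back after reconstruction.  Centering is a deliberate choice the
framework's description leaves open: the group mean is exactly what all
subjects share, so it belongs in every reconstruction rather than in the
components competing to explain identity.  Component signs are fixed
(largest-magnitude loading positive) so results are deterministic; components
are ranked by explained variance and reconstruction at m keeps the top m.
At `m = 2S` the input is recovered to numerical precision, and the retained
variance $R^2(m)$ is nondecreasing with $R^2(2S) = 1$.

`sweep_components()` scores $I_\mathrm{diff}$ at every m on a grid (default
every integer in `[1, 2S]`; a stride can be set for speed) and reports the
optimum $m^\*$, breaking ties toward the smallest m — the most parsimonious
reconstruction.  Two orders of operations are supported, and they are not
interchangeable:

* **NP(𝕀f{FC})** — reconstruct the connectomes at each m, repair them
  (diagonal restored to 1, entries clipped back into $[-1, 1]$, non-positive
  weights re-clamped: reconstruction is unconstrained least squares and can
  overshoot the correlation bounds, and the random-walk algebra needs valid
  weights), then derive each property per run and score it.  The
  identifiability profile of the reconstructed connectomes themselves (the
  FC baseline) is always computed alongside.
* **𝕀f{NP(FC)}** — derive each property once from the original clamped
  connectomes, then decompose and reconstruct the property's own feature
  matrix.

At full reconstruction both orders coincide (both reduce to properties of
the original connectomes), which the tests assert to `1e-8`.

## Task sensitivity

Task sensitivity of a feature is the one-way random-effects intraclass
correlation ICC(1,1), $(\mathrm{MSB} - \mathrm{MSW}) / (\mathrm{MSB} +
(k-1)\,\mathrm{MSW})$, with conditions as groups and a subject's test and
retest values as the $k = 2$ unordered members of each group, computed per
subject and averaged across subjects per feature.  The one-way form is the
right one because runs within a subject are exchangeable replicates, not
distinguishable raters; negative ICCs (down to $-1/(k-1)$) are retained so
that distribution comparisons between variants are faithful, and a group set
with no variance at all yields a flagged `NA` rather than an error.

Three variants are compared per property: properties of connectomes
reconstructed at the FC baseline optimum (the reconstruction knob sits on
the connectome, so the connectome's own $m^\*$ for that condition is used);
properties reconstructed at their own per-property $m^\*$; and
unreconstructed properties.  Each condition contributes its own optimum.

## Null model

Under "no fingerprint", subject labels on the retest side are exchangeable.
`idiff_permutation_null()` permutes the retest columns of an identifiability
matrix and recomputes $I_\mathrm{diff}$; the observed score of a pure-noise
cohort should sit inside the permutation band.  The acceptance checks use a
conservative familywise band of four null standard deviations around the
null mean, because the profile is tested at every m of a sweep
simultaneously and a per-m 95% band would reject somewhere on the grid by
chance alone; a genuine fingerprint clears this band by orders of magnitude.

## Numerical choices and degenerate inputs

* `eps_clamp` defaults to machine epsilon, matching the convention above;
  any positive value is accepted.
* Connectome files are written with 17 significant digits and parsed with
  `strtod`, so write/read round-trips are bit-exact.
* An all-constant feature matrix has no principal components; reconstruction
  returns the mean and $R^2$ is reported as 1 by convention.
* A zero-variance run column makes Pearson correlation undefined; the
  identifiability matrix raises an error naming the column rather than
  propagating `NA`s.
* Matrices read from disk must be square, symmetric within `1e-8`, with
  off-diagonal entries in $[-1, 1]$; every (subject, condition) must pair a
  test with a retest run.

## Problem sizes

The test suite exercises the full pipeline at sizes a laptop handles in
minutes, chosen as the smallest cohorts in which the phenomena are
unambiguous: oracle comparisons on 50 random graphs with up to 7 nodes
(where exhaustive path enumeration is feasible) plus closed-form families up
to 50 nodes; fingerprint-recovery experiments on 20 subjects × 40 nodes ×
1,200 time points over five seeds, with four conditions for the
task-sensitivity comparison.  At these sizes every qualitative conclusion —
an interior $I_\mathrm{diff}$ peak near $m \approx S$ at roughly 70–80%
retained variance, higher identifiability of the connectome than of derived
properties, and higher task ICC after either reconstruction variant — is
reproduced stably across seeds.

## Limitations

* Identification across conditions (training on rest, identifying in task)
  is out of scope; identifiability is always within-condition.
* Only $I_\mathrm{diff}$ is implemented, not top-1 identification rate.
* The ICC comparison reports distributions; it attaches no significance
  tests to differences between variants.
* Structural connectomes, real fMRI ingestion (NIfTI/CIFTI), and
  preprocessing choices such as global signal regression are outside the
  package; real connectomes must arrive as delimited correlation matrices.
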