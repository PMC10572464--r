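---
title: "Threshold-free cluster enhancement for ROI-to-ROI connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free cluster enhancement for ROI-to-ROI connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `conntfce`: the
connectivity model, the TFCE permutation test and its numerical choices,
the fixed-threshold NBS comparator, the downstream cluster-of-interest
analyses, and the synthetic BOLD generator that stands in for restricted
clinical imaging data. It is the package's design record: every choice
that was genuinely open is stated here with its rationale.

## The problem

Resting-state fMRI studies of Alzheimer's disease (AD) and mild cognitive
impairment (MCI) compare ROI-to-ROI functional connectivity between
diagnostic groups. Each subject contributes a matrix of Fisher-z
transformed Pearson correlations between regional BOLD time series;
group differences live on the ~500 edges of a 32-ROI, 8-network
parcellation. Mass-univariate edge tests need multiple-comparison
control, and biologically plausible effects are *clustered*: a disrupted
pathway touches several adjacent edges. Cluster-extent methods such as
the network-based statistic (NBS) require an arbitrary edge-defining
threshold; threshold-free cluster enhancement (TFCE) integrates evidence
over all thresholds instead, which is the motivation for this package.

## Connectivity model

For subject $s$ with ROI series $R_i(t)$ (columns mean-centred before
anything else — the estimator assumes zero-mean series, so centring is
made explicit rather than assumed of the input):

$$r(i,j) = \frac{\sum_t R_i(t) R_j(t)}
 {\left(\sum_t R_i^2(t)\,\sum_t R_j^2(t)\right)^{1/2}},
 \qquad Z(i,j) = \tanh^{-1} r(i,j).$$

The diagonal of $Z$ is stored as 0 and never enters statistics. Edges
are the strict upper triangle, mirrored for storage.

Degenerate $|r| = 1$ (possible for duplicated synthetic signals) is
clipped to $1 - 10^{-7}$ with a warning naming the pair, rather than an
error: synthetic pipelines can legitimately hit the bound and should
keep running with an audit trail.

**Scrubbing.** Before correlation, timepoints are censored (removed, not
interpolated) when the global signal deviates more than 5 standard
deviations from its mean or framewise displacement exceeds 0.9 mm; a
timepoint flagged by both rules is removed once. Removal was chosen over
interpolation or regressor-based handling because it is the simplest
defensible reading of outlier-scan rejection; interpolation would be an
unstated elaboration. Fewer than 10 surviving timepoints is a
degenerate-input error. Band-pass filtering and nuisance regression are
deliberately not implemented: they belong to upstream imaging
toolchains, and this package starts from extracted ROI series.

## Edgewise statistics

Group contrasts use the classical pooled-variance two-sample $t$ per
edge (positive $t$ = first group larger), df $n_a + n_b - 2$; a Welch
variant is available behind a flag but the pooled form matches the
standard GLM contrast. Three-group comparisons use the one-way
fixed-effects $F$, df $(k-1, n-k)$. Covariates (age, sex) are not
modelled — nothing in the analysis this package implements specifies a
covariate design, and inventing one would change the estimand. Edges
with zero pooled variance get $t = 0$ with a warning (they arise only in
degenerate synthetic data).

## TFCE

The enhanced score of edge $(i,j)$ with statistic height $h(i,j)$ is

$$\mathrm{TFCE}(i,j) = \int_{h_0}^{h(i,j)} e(h)^E\, h^H\, dh,$$

where $e(h)$ is the extent of the suprathreshold connected component
containing the edge at level $h$. Defaults $E = 0.5$, $H = 2$, $h_0 = 0$
are the canonical published TFCE defaults; the integral's parameters are
not prescribed elsewhere, so they are exposed in `tfce_params()`.

**Discretization.** The integral is evaluated by the midpoint rule over
`n_steps = 100` equal height levels from $h_0$ to the tail maximum.
Midpoint was chosen over a right-endpoint Riemann sum because its
$O(n^{-2})$ error keeps a single isolated edge of height $v$ within a
fraction of a percent of the closed form $v^{H+1}/(H+1)$ at 100 steps,
and makes scores stable under step-doubling (tested at the map level:
individual near-zero edges may jump between discrete component
memberships, so stability is asserted on the Frobenius norm).

**Neighbourhoods.** Two component-forming rules are provided:

* `matrix_image_4` (default): the ROI-sorted $N \times N$ matrix is
  treated as a 2-D image and suprathreshold entries are neighbours when
  horizontally or vertically adjacent, both symmetric halves processed
  as one image. This is the rule under which the hierarchical ROI
  sorting step has a purpose: average-linkage clustering on
  $1 - |\bar z|$ makes strongly connected ROI groups contiguous, so
  coherent subnetworks form compact image regions.
* `edge_graph`: suprathreshold edges are neighbours iff they share an
  ROI. This is sorting-invariant and graph-theoretically more
  principled; it is provided for comparison and used by NBS.

Both are implemented in compiled code with an independent pure-R
flood-fill oracle in the test suite; the two implementations agree to
relative error below $10^{-10}$ on random maps.

**Two-sided handling.** Positive and negative tails are enhanced
separately and negative-tail scores carry negative sign, so disrupted
(group A < group B) and enhanced connectivity are both reported, each
with its own clusters.

## Permutation inference

The null distribution is built by complete re-randomization of group
labels among the contrast's subjects, with the identity permutation
excluded and the stream seeded (every stochastic stage derives its seed
from the master seed via a documented FNV-1a splitting rule, so
end-to-end runs are byte-reproducible). Labels are permuted only within
the two contrast groups, not across the full three-group cohort: the
exchangeability assumption needed for validity holds within the
contrast, and nothing specifies a three-group scheme. Each permutation
records its maximum TFCE score (peak) and maximum cluster mass. With $B$
permutations, p-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, which is never zero
and has floor $1/(B+1)$.

* `peak_p_fwe`: a cluster's peak TFCE against the null peaks — the
  maximum-statistic construction that controls family-wise error.
* `p_uncorrected`: the cluster's mass against the null maximum masses —
  the cluster-level quantity conventionally reported in small-sample
  connectivity studies (both are always computed; display defaults to
  showing both).

**Cluster formation.** TFCE deliberately avoids a cluster-forming
threshold for *inference*, but reporting discrete clusters still
requires one. The rule here (`cluster_rule = "null_q95"`) is: clusters
are connected components of edges whose $|\mathrm{TFCE}|$ exceeds the
95th percentile of the pooled null edgewise $|\mathrm{TFCE}|$
distribution. This is deterministic given the data and seed, adapts to
the map's own null scale, and is documented; the alternative
(`"nonzero"`, components of all nonzero-TFCE edges) is behind a flag.
Mirror-image components of the symmetric matrix are de-duplicated by
their edge set.

**Cluster mass** is the sum of $|t|$ over the cluster's edges (a
stat-mass, the conventional "mass/intensity" summary); summing TFCE
scores instead is available via `mass_type = "tfce"`.

## NBS comparator

NBS thresholds $|t|$ at a fixed value (default 3), forms components of
suprathreshold edges sharing an ROI, and compares each component's size
to the permutation null of maximum component sizes. It is included as
the fixed-threshold baseline TFCE is designed to replace; on strong
compact effects the two methods select essentially the same top edges
(tested), while TFCE needs no threshold choice.

## Clusters of interest

Significant clusters are carried into downstream analysis as the mean
Fisher-z over their edges per subject: one-way ANOVA across the three
diagnostic groups plus pairwise pooled t-tests (reported unadjusted,
matching the common presentation of per-pair tests, with a Bonferroni
column alongside), and within-group Pearson correlation of cluster mean
z with the global Clinical Dementia Rating. The reporting rule — flag a
correlation only when $p < 0.05$ **and** $|R| > 0.35$ (i.e.
$R^2 > 0.1225$) — is implemented as a pure function of $(R, p)$ and
results that fail it are flagged rather than suppressed, so the rule's
behaviour is itself auditable. (Published applications of such rules
have reported sub-threshold values like $R = -0.08$ as significant,
which the rule as stated cannot produce; the package enforces the rule
literally.)

## Synthetic cohort generator

Restricted clinical imaging data cannot ship with a package, so every
stage is exercised by a generator whose defaults encode the study
conditions the analysis is meant for:

* Cohort HC = 31, MCI = 31, AD = 33 — the three-group regime of the
  motivating cohort.
* $T = 200$ timepoints at TR = 3 s. No acquisition length is prescribed
  by the analysis itself; these are stated assumptions, configurable in
  `simulation_scenario()`.
* One latent unit-variance Gaussian signal per network; ROI $i$ in
  network $k$ is $\lambda L_k + \sqrt{1-\lambda^2}\,\varepsilon_i$ with
  loading $\lambda = 0.6$, so same-network ROIs have population
  correlation $\lambda^2 = 0.36$ and the connectivity matrix has the
  8-network block structure. This is the simplest generative model that
  produces block-structured connectivity.
* AR(1) temporal autocorrelation (coefficient 0.3) on all innovations:
  BOLD series are autocorrelated, and this stresses the correlation
  estimator realistically without modelling hemodynamics.
* A planted effect: a 10-edge contiguous cluster (the six within
  default-mode edges plus four default-mode-to-sensorimotor/salience
  edges) whose population Fisher-z is reduced by $\delta_z = 0.4$ in the
  AD group only.
* CDR and an MMSE-like score are linear in the subject's empirical mean
  planted-edge z plus Gaussian noise (CDR slope negative: less
  connectivity, more severe rating), clipped to their clinical ranges;
  rounding CDR to the half-point scale is an optional "realistic" mode,
  off by default because continuous scores make correlation-recovery
  tests clean. Default intercept/slope/noise were set so group-level
  CDR means and spreads land in the clinically familiar range
  (HC near 0, AD near 1, sd 0.15–0.3); a consequence worth knowing is
  that *within-group* CDR-connectivity correlations are weak (the
  within-group signal is only sampling variation of mean z), which
  mirrors the weak within-group correlations typical of real cohorts.

**Implementation of the planted effect.** Conceptually the effect
attenuates the shared signal for exactly the planted ROI pairs. An ROI
has a single time series, so literal per-pair noise substitution cannot
leave other edges untouched when planted edges share ROIs (attenuating
an ROI's shared component changes its correlation with every network
sibling). The generator therefore constructs the *target population
correlation matrix* directly — block structure, with each planted edge
set to $\tanh(\tanh^{-1} r_0 - \delta_z)$ — and colours i.i.d. AR(1)
innovations with its symmetric matrix square root. This achieves the
contract exactly: planted population z reduced by $\delta_z$, all other
edges' populations unchanged. The construction requires the target
matrix to remain positive definite; the default configuration has
minimum eigenvalue ≈ 0.18, and a configuration that breaks positive
definiteness (e.g. very large $\delta_z$ on many edges) is a
configuration error, reported as such.

**What the generator does not emulate:** hemodynamic response shapes,
physiological noise spectra, scanner drift, spatial smoothness,
volumetric images, atrophy-driven signal loss, or site effects. Passing
tests therefore demonstrate the *statistical* machinery — estimator
consistency, FWE calibration under exchangeability, power against
clustered effects of known geometry — not robustness to the full
messiness of scanner data.

## Problem sizes used in the test suite

The suite's statistical checks run at sizes chosen to make their
Monte-Carlo error small relative to the asserted tolerances while
keeping a full run in the minutes range: FWE calibration uses 100 null
datasets (20 subjects/group, $T = 200$) at 500 permutations; power uses
50 replicates of the default planted scenario (30/group) at 500
permutations; oracle equivalence uses 200 random 8-ROI maps; the
acceptance script runs the full default cohort (95 subjects) at 1000
permutations. Counts of hits are compared against exact binomial
acceptance regions, not point estimates.

## Known limitations

* Exchangeability of subjects under the null is assumed by the
  permutation scheme; confound-driven group differences (motion, age)
  would violate it, and no covariate scheme is provided.
* The `matrix_image_4` neighbourhood makes cluster topology depend on
  the hierarchical ROI ordering; the ordering is deterministic, but
  different orderings can split or merge image-space clusters. The
  `edge_graph` neighbourhood avoids this at the cost of diverging from
  the matrix-image convention.
* The cluster-forming rule for *reporting* (null 95th percentile) is a
  documented convention, not part of TFCE theory; sensitivity to it is
  limited to how edges are grouped, never to the edgewise scores or the
  peak-level FWE inference.
* Pairwise COI t-tests are reported unadjusted by default; treat them as
  descriptive follow-ups to the ANOVA.
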