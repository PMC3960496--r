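---
title: "Methods: wavelet functional connectomes, small-world topology and the network-based statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet functional connectomes, small-world topology and the network-based statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcnet)
```

# Overview

`fcnet` implements a complete task-fMRI functional-connectome analysis
for two-group ROI-level studies: head-motion quality control, nuisance
regression, wavelet-based connectivity matrices, cost-thresholded binary
graph topology (efficiencies, hubs, degree-distribution fits) against
matched null models, subnetwork detection with the permutation-based
network-based statistic (NBS), and covariate-adjusted group inference
with false-discovery-rate control.  Because ROI time-series for clinical
cohorts are rarely shareable, the package ships a synthetic cohort
generator with known ground truth, and every stage is validated against
that generator or against independent brute-force oracles.

The intended input is a per-subject matrix of ROI signals (nodes ×
frames) extracted upstream from preprocessed images, together with the
six rigid-body realignment parameters per frame and a cohort manifest
(group, age, sex, IQ, symptom T-scores).  Image-space processing —
slice timing, smoothing, registration, ROI extraction — is out of
scope; the packaged 68-ROI node table documents the node definitions
the default analysis assumes.

# Head-motion quality control

Motion traces follow the MCFLIRT `.par` column order: three rotations
in radians, then three translations in mm.  Three frame-wise summaries
are computed:

* **FD** (frame-wise displacement): per frame, the sum of absolute
  differentials of the six parameters, rotations converted to mm as arc
  length on a 50 mm sphere, i.e.
  $FD_t = \sum |\Delta d| + 50 \sum |\Delta \theta|$.
* **Diff**: the per-parameter absolute differentials themselves.
* **Mean Motion**: the mean frame-to-frame translational displacement.
  The phrase "mean of the absolute values of the displacements along
  x-, y- and z-axes" is ambiguous between the per-frame Euclidean norm
  and a per-axis average; the convention usually cited for this metric
  (Van Dijk) is the norm, which is the default here.  The per-axis
  variant is available via `mean_motion(method = "per_axis")` without
  endorsement.

A subject is excluded when any converted parameter exceeds 1.0 mm or
Mean Motion exceeds 0.25 mm — the same two rules are applied by
`run_pipeline()`, which logs and drops excluded subjects.  The 50 mm
sphere is also used for the 1.0 mm rule on rotations, since the rule is
stated in mm for all six parameters.  `motion_connectivity_check()`
tests subject-level connectivity against Mean Motion with Pearson and
Spearman correlations (the rank correlation standing in for an
unspecified "non-linear" check).

# Wavelet connectivity

Each node's signal is decomposed with the maximum-overlap discrete
wavelet transform (MODWT).  The MODWT is undecimated: each scale keeps
one coefficient per frame, so detail series from different scales stay
aligned and can be averaged pointwise.  Scale $k$ of a series sampled
every $TR$ seconds carries the octave $[2^{-k-1}/TR,\, 2^{-k}/TR]$ Hz;
at $TR = 2$ s, scales 2–4 jointly cover 0.0156–0.125 Hz, the band that
carries most block-design task information.  (Note the dyadic formula
assigns scale 2 to the *highest* of the three octaves; listings that
pair the bands with scales in ascending frequency order disagree with
the formula about labels, but the union of bands is identical and the
averaged coefficients do not depend on the labeling.)

Implementation choices, all configurable:

* **Filter**: Daubechies least-asymmetric length-8 (LA(8)), the usual
  choice in wavelet fMRI connectivity; Haar is available.
* **Boundary**: periodic (circular), which preserves series length
  exactly, makes the transform equivariant under circular shifts, and
  keeps the per-scale series aligned for averaging.  Boundary-affected
  coefficients are retained.  A reflection variant is provided.
* **Band averaging**: the pointwise arithmetic mean of the aligned
  scale-2, 3 and 4 detail series.

Connectivity between two nodes is the absolute Pearson correlation of
their averaged coefficient series; the 68-node default yields
$68 \times 67 / 2 = 2278$ distinct pairs.  Absolute values discard the
sign of coupling by design (the downstream graph analysis treats
correlated and anticorrelated pairs alike).  Zero-variance series are
flagged and their pairs left undefined rather than silently zeroed.
Nuisance regression (`regress_confounds()`) removes per-frame
confounds — typically the six motion parameters plus white-matter, CSF
and global signals — by least squares before the transform; the 1/80 Hz
high-pass of raw images is treated as upstream preprocessing.

# Binary graphs and small-world topology

The connectivity matrix is binarized at a network **cost**: the target
fraction of the $N(N-1)/2$ possible edges.  `threshold_at_cost()` keeps
the $K = \mathrm{round}(\text{cost} \cdot N(N-1)/2)$ strongest pairs,
rounding half away from zero (no rounding rule is canonical for
fractional edge counts; half-away is deterministic and symmetric),
with ties broken by lexicographic node order so that edge sets are
nested along increasing costs.

Metrics use the Latora–Marchiori conventions: disconnected pairs
contribute $1/l_{ij} = 0$, and neighbor subgraphs with fewer than two
nodes have local efficiency 0.

* $E_{glob} = \frac{1}{N(N-1)} \sum_{i \neq j} 1/l_{ij}$,
* $E_{loc}$ = mean over nodes of the global efficiency of each node's
  neighbor-induced subgraph,
* $E_{nodal}(i) = \frac{1}{N-1}\sum_{j \neq i} 1/l_{ij}$,
* degree, and betweenness centrality normalized by the
  $(N-1)(N-2)/2$ pairs of other nodes (endpoints excluded).

Shortest paths are computed by simultaneous breadth-first search
expressed as boolean matrix products (fast in R for networks of this
size); betweenness uses the igraph Brandes implementation.  The test
suite checks every metric against independent brute-force oracles
(adjacency-power path counting) on all labeled graphs with up to 5
nodes and on random graphs with up to 12, to $10^{-10}$.

A graph is **small-world** at a given cost when
$E_{glob}(G_{reg}) < E_{glob}(G) < E_{glob}(G_{rand})$ and
$E_{loc}(G_{rand}) < E_{loc}(G) < E_{loc}(G_{reg})$, with matched
nulls: the random null preserves the exact degree sequence via double
edge swaps (10 per edge by default, seeded), and the regular null is a
deterministic ring lattice with identical node and edge counts.  Random
null efficiencies are ensemble means; the ensemble size defaults to 20
per cost, a compromise between the stability of the mean and runtime.  The small-world **regime** is the
longest contiguous run of passing costs.  The default global cost grid
is 0.1–0.5 in steps of 0.01; group comparisons can also be run from
0.05 (both grids are configuration keys, since published descriptions
vary between the two).

Degree distributions are fitted with an exponentially truncated power
law $P(k) \propto k^{\alpha-1} e^{-k/k_c}$ by maximum likelihood over
the discrete support $k \in [1, N-1]$ (a least-squares fit to the
complementary CDF is provided for comparison, since no single fitting
method is canonical for this family).  Non-convergence and degenerate inputs are
flagged in the result rather than raised.

# Hubs

For each node, degree and betweenness are averaged over the hub cost
grid (default 0.05–0.3 by 0.01, the small-world regime typically
reported for such networks), standardized across nodes
($n-1$ denominator), and tested one-sided against the standard normal:
a node is a hub when $p = 1 - \Phi(z) < 0.05$.  By construction about
5% of exchangeable nodes are flagged; the hub label is relative to the
network's own distribution, not an absolute property.  Hub profiles are
computed on group-mean connectivity matrices by default (one network
per group); a per-subject mode is available through the same functions
since the aggregation level is a genuine design choice.  Degree- and
BC-defined hub sets are reported separately along with their union and
intersection.

# Network-based statistic

`nbs_permutation()` implements the six-step NBS: per-edge
pooled-variance two-sample $t$ tests on the $|r|$ values (df
$n_a + n_b - 2$; the pooled variant is the NBS-toolbox convention),
thresholding at $t > 3.5$ by default, connected-component extraction,
and a permutation null for the *largest component extent* obtained by
randomly reassigning subjects to groups (sizes preserved, no
exchangeability blocks).  The FWE-corrected p of an observed component
of extent $k$ is the plain proportion of permutations whose largest
component reaches $k$; the $(b+1)/(m+1)$ variant is available as an
option.  Component extent is the edge count (node count optional).
Both contrast directions are extracted and tested separately, each
against the null of its own direction.  For small cohorts an
`exhaustive = TRUE` mode enumerates every relabeling, making the
p-values exact.  Covariates are not included in the edge model by
default (the edge-level model is a plain two-sample contrast; adjusted
models apply to the topology metrics below).

# Group inference

Topology metrics are compared between groups with an analysis of
covariance — the partial F for the group term in
`metric ~ group + age + IQ + sex`, sex as a fixed-effect indicator.
Constant covariates are dropped so the model degrades gracefully to the
two-sample comparison.  FDR correction is Benjamini–Hochberg step-up at
$\alpha = 0.05$, with the correction family kept within each analysis:
across nodes for nodal tests, across costs for efficiency-curve tests,
and across nodes within each score for the clinical regressions.
Nodal-efficiency/T-score relations are per-node simple linear
regressions run in the patient group, reporting slope, model F and p.
Degrees of freedom are always reported as computed from the model
actually fitted.

# The synthetic cohort

`generate_cohort()` emulates the target study design: two groups of 22
subjects, 68 nodes, 150 frames at TR = 2 s.  Each subject's signals
follow a stationary AR(1) process whose innovations are multivariate
normal with a target correlation matrix, so the population
cross-correlation equals the target exactly and sample correlations
converge to it with frame count.  The default target is a modular
correlation structure (4 modules, within-module $r = 0.3$, between
$0.1$) — a coarse stand-in for cortical community structure chosen so
that the planted manipulation below keeps the matrix positive
definite with a comfortable margin.  The patient group differs only on
a **planted** connected subnetwork (default: a 7-edge tree) whose
correlations are multiplied by $1 - \text{effect}$; the group
difference is exactly zero elsewhere, which is the ground truth the NBS
tests recover.  Planted effect sizes are free simulation parameters —
edge-level effect sizes for real cohorts of this kind are not
available to calibrate against.  Covariates are drawn per group to resemble a two-group child
cohort (patients with symptom T-scores near 75 vs 45); symptom scores
are independent of the planted effect unless the user couples them.

What the generator does *not* emulate: hemodynamic response shapes,
the block-design activation structure (an optional boxcar mean term
exists but is off by default — connectivity, not activation, is the
analysis target), spatially structured noise, scanner drift, or
motion-connectivity coupling.  Passing tests therefore demonstrate the
statistical machinery is correct and calibrated, not that any specific
empirical finding generalizes.

Motion traces are simulated as smoothed random-walk drift plus sparse
spikes, in the same 6-column dialect the readers expect.

# Numerical and design notes

* All generators and permutation procedures are pure functions of their
  seeds; `run_pipeline()` derives per-stage seeds from one master seed
  and restores the caller's RNG state.
* Ties in cost thresholding break lexicographically; `K` rounds half
  away from zero.
* Zero-variance edges in the NBS, zero-dispersion hub metrics,
  zero-variance clinical scores and degenerate degree distributions are
  flagged in results instead of raising errors; rank-deficient confound
  or covariate designs raise errors naming the offending columns.
* Problem sizes in the validation suite were chosen to make each check
  statistically meaningful at desk scale: exhaustive graph enumeration
  to 5 nodes plus 500 random graphs to 12 nodes for the metric oracles;
  500 no-effect cohorts (200 permutations each) for NBS family-wise
  error; 50 planted-effect cohorts (1000 permutations) for NBS power;
  5000 samples for power-law recovery; 500–1000 replicates for the 5%
  calibration checks.
* The NBS family-wise error calibration and power checks run the full
  generator → wavelet connectivity → NBS path at the study scale
  (22 vs 22, 68 nodes), not a shortcut on synthetic edge values.

# Known limitations

* Binarized graphs only; no weighted-graph metrics.
* No frame censoring: quality control excludes subjects, not frames.
* The regular null is a deterministic lattice, so its "ensemble" is a
  single graph; small irregularities at odd edge counts are absorbed by
  assigning leftover edges to next-nearest neighbors.
* The truncated power-law likelihood treats degrees as i.i.d. draws,
  ignoring the dependence between node degrees within one graph.
* Group-level hub detection on mean connectivity matrices has no
  subject-level variance; treat hub tables as descriptive.
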