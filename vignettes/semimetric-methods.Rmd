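---
title: "Semi-metric analysis of weighted functional connectomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-metric analysis of weighted functional connectomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semimetric)
```

## The model

Functional connectivity analyses usually keep only the strongest
correlations, discarding the weak edges that can nonetheless carry
information along indirect routes. This package analyses the *whole*
positive-weight connectome and asks, for every pair of regions, whether
the direct connection or some indirect path is the stronger route.

A subject's connectome is a proximity graph: nodes are parcellation
regions, edge weights $w_{ij} \in [0, 1]$ are non-negative Pearson
correlations of wavelet coefficients of the regional BOLD signals.
Proximities map to distances through the isomorphism

$$d_{ij} = \frac{1}{w_{ij}} - 1,$$

so full proximity ($w = 1$) is zero distance and an absent edge
($w = 0$) is infinite distance. Negative correlations are excluded
before this map: in-phase and anti-phase synchrony are different
phenomena, and a signed weight has no consistent place in a shortest-path
calculus, so anti-correlated pairs are treated as infinitely distant.

The *metric closure* replaces every $d_{ij}$ with the shortest-path
distance $D_{ij}$ over the whole graph (`metric_closure()`, all-pairs
shortest paths via Johnson's algorithm as implemented in igraph). Each
present edge is then labelled:

* **metric** — $D_{ij} = d_{ij}$: the direct edge is already the best
  route;
* **semi-metric** — $D_{ij} < d_{ij}$: some indirect path beats the
  direct edge, a violation of the triangle inequality.

The *distortion* $s_{ij} = d_{ij} / D_{ij} \ge 1$ measures how strongly
the closure contracts an edge. The *semi-metric percentage* (SMP) of any
edge set is the fraction of its present edges labelled semi-metric;
absent edges count in neither numerator nor denominator, and a set with
no present edge has an undefined SMP (`NA`), never zero.

`brute_force_closure()` implements the same contract by the cubic
Floyd–Warshall recurrence. It exists so that the production path can be
checked against an independently coded oracle on randomized instances;
the two must agree to $10^{-9}$ in distance and exactly in labels.

### Numerical choices

* **Tie rule.** Floating-point shortest paths rarely reproduce a sum
  exactly, so an edge is semi-metric iff
  $D_{ij} < d_{ij}\,(1 - 10^{-9})$ (relative comparison); anything
  closer is metric. Distortion is set to exactly 1 for metric edges, and
  a metric edge's closed distance is snapped to its direct distance —
  the shortest-path recomputation can differ from the direct edge by a
  final-bit rounding artefact, and snapping makes the closure an exact
  fixed point of itself.
* **Absent edges.** Infinity is represented by `Inf`, never by a large
  finite stand-in, so no spurious path can leak through an excluded
  edge. On disk the token `inf` round-trips losslessly.
* **Zero-cost edges.** $w = 1$ gives $d = 0$; such edges are legal on
  paths and nodes are not merged, keeping the map total on $[0, 1]$. An
  edge bridged by a zero-cost path has infinite distortion.
* **Self-pairs.** The diagonal never enters any computation, count or
  SMP.

## Connectivity from BOLD time series

Regional time series are decomposed with a maximal-overlap discrete
wavelet transform (Daubechies 4-tap filter, periodic boundary), which
keeps one coefficient per time point at every scale and conserves energy
exactly. Scale $j$ nominally covers $(f_N/2^j,\; f_N/2^{j-1})$ with
$f_N = 1/(2\,\mathrm{TR})$; at TR $= 2.43$ s scale 2 spans roughly
0.051–0.103 Hz, the band conventionally analysed in resting-state
studies. The analysis scale defaults to 2 and is configurable.
Correlations are computed on all retained coefficients; no
boundary-coefficient exclusion is applied, a documented simplification —
with periodic filtering every coefficient is defined, at the price of
some wrap-around mixing at the series ends. Daubechies-4/MODWT is the
established choice in the wavelet-correlation literature; the band
labels are reported from TR rather than taken as fixed constants,
because nominal printed bands in the literature often disagree with the
acquisition's actual Nyquist frequency.

## The region hierarchy and gated testing

Regions carry a hemisphere (`left`, `right`, `cerebellum`) and a lobe.
The tested edge sets are nested: the whole brain; each cerebral
hemisphere; the cerebellum; the between-hemisphere pairs; and, inside
each hemisphere, the within-lobe sets plus the within-hemisphere
between-lobe set. Within a hemisphere these child sets partition the
hemisphere's pairs exactly. Cerebellar regions form their own top-level
set and are excluded from the cerebral hemispheres;
cerebellum-to-cerebrum pairs count toward the whole brain only. This
mirrors a reporting layout in which the cerebellum appears as its own
row; an alternative would fold cerebellar pairs into left/right sets,
which would break the hemisphere partitions.

Group differences in SMP are compared with Welch's unequal-variance
two-tailed $t$-test throughout — group sizes of order ten give no basis
for assuming equal variances, and a single uniform test keeps rows
comparable. The nested tests are not independent, so testing is *gated*:
the whole brain is always tested, and a child set is tested only when
its parent's $p$ falls below the gate level $\alpha$ (default 0.05).
The parent map is: hemispheres, cerebellum and between-hemispheres gate
on the whole brain; lobe and between-lobe sets gate on their hemisphere.
Gated-off sets are reported with group means but no $p$-value. No
further multiplicity correction is applied by default, matching the
gating-only philosophy; `p_adjust = "BH"` optionally applies
Benjamini–Hochberg across the tested rows.

Edges are classified once, globally, on the whole-brain closure, and
subgraph SMPs count those global labels inside each subset. The
alternative — re-running the closure inside each subgraph — would let a
path leave and re-enter the subgraph inconsistently and would make
subset SMPs incomparable with the whole-brain value, so it is not used.

Two further group summaries complement the table:

* **Asymmetry.** Per subject, $(r - l)/(r + l)$ of the right- and
  left-hemisphere SMPs, compared between groups with a two-sided
  Mann–Whitney test.
* **Distance ranking.** Each region set is placed on a geometric axis by
  the mean Euclidean distance between its regions' centroids, giving the
  spatial profile of the group difference from short- to long-range
  subgraphs.

## Backbones and difference maps

The *consensus backbone* of a group keeps the node pairs that are
semi-metric in strictly more than a threshold fraction (default
$> 90\%$) of the group's subjects. The comparison is strict because the
threshold is a floor for "shared across the group": at $n = 12$,
consensus must reach $12/12$; at $n = 11$, $11/11$... a group whose
semi-metric topology varies more between subjects clears the bar less
often and shows a sparser backbone, independently of its mean SMP.

The *node difference map* embeds each subject's closed distances back
into proximity space ($w = 1/(D + 1)$), averages the embedded networks
elementwise within each group, takes the elementwise absolute difference
of the group means, and scores each node by its row mean. Semi-metric
edges are the ones strongly moved by the closure, so high-scoring nodes
are those whose indirect connectivity differs most between groups. This
aggregation is a declared stand-in for multilayer embedding methods
whose full details are outside this package's scope; it honours the
qualitative recipe — closure, embedding, group subtraction, absolute
value, node averaging — with the simplest defensible operations
(elementwise means), and it is symmetric in group order.

## The synthetic study generator

No resting-state dataset ships with the package; the generator produces
studies with the structure the analyses expect and with known ground
truth, so every pipeline stage is testable offline.

A `group_spec()` describes one group:

| parameter | default (control / case) | meaning |
|---|---|---|
| `n_subjects` | 12 / 11 | group sizes |
| `mu_r`, `sigma_r` | 0.316 ± 0.036 / 0.291 ± 0.034 | background correlation level and spread |
| `n_triads` | 10 / 40 | planted indirect-path triads |
| `w_strong`, `w_weak` | 0.4, 0.2 | triad leg / chord proximities |
| `jitter` | 0.1 / 0.5 | per-subject triad relocation probability |
| `n_timepoints`, `tr_seconds` | 256, 2.43 | series length and repetition time |

Background weights are drawn i.i.d. from $N(\mu_R, \sigma_R)$ (signed
values kept as the "raw correlations", truncated at zero for the
proximity graph). A planted triad sets two strong legs $w_s$ through a
hub and a weak chord $w_w$; whenever
$2(1/w_s - 1) < 1/w_w - 1$ the chord is *provably* semi-metric — the
two-hop path is an upper bound on the shortest path, and additional
background paths can only shorten it. Ground truth is re-verified on the
final weights after all planting, so overlapping triads cannot silently
revoke a guarantee. The case group differs in three ways, mirroring the
phenomena under study: a slightly lower, narrower background
distribution; more planted triads (more indirect paths, hence higher
SMP); and higher jitter (a more heterogeneous semi-metric topology,
hence a sparser consensus backbone).

Two generator design points deserve emphasis:

* **Triad strengths sit near the background.** With legs at $w_s = 0.4$
  against a background near 0.3, a triad's collateral effect on
  *other* edges is negligible (about 0.2% of edges incident to a triad
  node flip label). Much stronger legs (say $w_s = 0.8$, distance 0.25
  against a background distance near 2.2) act as highways that make
  roughly a third of all incident edges semi-metric; the planted
  structure then dominates the graph, the case backbone becomes denser
  rather than sparser, and shared within-group structure invalidates the
  subject-level independence the group tests rely on. The near-background
  choice keeps the planted signal local and the groups' subjects
  exchangeable under identical specifications.
* **One triad pool per study.** Canonical triad locations are drawn once
  and shared by both groups; a group with $k$ triads uses the first $k$
  pool entries, and each subject relocates each triad with probability
  `jitter`. Under identical group specifications the two groups are
  therefore exactly exchangeable, which is what gives the gated scheme
  its nominal type-I error in the null simulations.

Time-series mode samples each subject's series from a zero-mean
multivariate normal whose correlation matrix is the subject's target
structure after a nearest-positive-semidefinite repair (eigenvalues
clipped at a small floor, rescaled to unit diagonal — a modelling
convenience, not a statistical estimator). The series are temporally
white, so wavelet coefficients at every scale inherit the target
cross-correlation and the scale-2 empirical correlations converge to the
targets as the series lengthens. With 256 time points the sampling error
of a single correlation is roughly $\pm 0.12$, so analytic planted
guarantees hold only approximately in this mode; exact-ground-truth work
uses matrix mode.

What the generator does **not** emulate: hemodynamic filtering, temporal
autocorrelation, scanner drift, motion and physiological noise, spatial
dependence of correlations on anatomical distance, and negative-tail
correlation structure (at the default parameters negative background
correlations are essentially absent, so the negative-count comparison is
usually degenerate on synthetic data and is reported as such). Passing
tests therefore certify the algorithmic pipeline and its statistical
behaviour under the stated model — not robustness to fMRI artefacts.

## Problem sizes used by the test suite

The randomized suites run at sizes chosen to exercise the mathematics
while keeping a full run comfortable on one CPU: oracle equivalence on
about a hundred 20–30-node graphs across edge densities 0.2–0.9;
round-trip and idempotence checks on a hundred 20-node graphs;
planted-edge recovery on fifty full 116-node studies; the
direction-of-effect simulation on 200 study replicates; and the
null-calibration simulation on 400 replicates, from which the empirical
whole-brain rejection rate is required to sit inside the 95% binomial
band around the nominal 5%.

## Known limitations

* SMP compares *counts* of semi-metric edges; it is blind to how strong
  a violation is (distortion is reported per edge but not aggregated).
* The gated scheme controls test multiplicity only through the
  parent-child gates; sets that share many edges (a hemisphere and its
  lobes) remain dependent.
* The bundled 116-region parcellation fixture is synthetic: hemispheres,
  lobe proportions and centroid boxes are atlas-like, but labels and
  coordinates are not those of any published atlas. Users with a real
  parcellation substitute their own table
  (`read_parcellation()`).
* `brute_force_closure()` is quadratic in memory and cubic in time and
  is capped at 200 nodes; it is an oracle, not a production path.
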