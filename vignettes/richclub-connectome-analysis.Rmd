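---
title: "Rich-club analysis of FA-weighted structural connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club analysis of FA-weighted structural connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richclubnet)
```

## The analysis model

`richclubnet` implements the standard group-comparison workflow for
structural brain networks built from diffusion tractography. A subject's
network has the 90 regions of the AAL cortical/subcortical parcellation
as nodes, and an edge between regions *i* and *j* whenever at least one
retained streamline connects them. The edge weight is the FA-based
interregional connection (FABIRC): the average FA of the connecting
streamlines. FA lies in [0, 1] and is a proxy for white-matter
integrity, so a strong edge is a well-myelinated, coherent tract.

Three analysis layers sit on top of the per-subject matrices:

1. **Topology metrics.** Nodal: binary degree centrality (with strength
   reported alongside), betweenness centrality, nodal shortest path
   length, nodal clustering coefficient, nodal efficiency. Global: mean
   clustering `cp`, characteristic path length `lp`, global efficiency,
   mean strength, and the small-world indices `gamma = cp / <cp_null>`,
   `lambda = lp / <lp_null>`, `sigma = gamma / lambda` against
   degree-preserving random networks.
2. **Rich club.** The club at degree level *k* is the set of nodes with
   binary degree > *k*. We report both the density coefficient
   `phi(k) = 2 E_club / (n_club (n_club - 1))` and the mean club edge
   weight `phi_w(k)`, because "rich-club coefficient" is used for both
   in the applied literature, and their normalized ratio against
   rewired nulls. Hubs are identified either as nodes whose averaged
   degree exceeds the profile mean by one standard deviation, or as the
   top 13 nodes by degree averaged over all subjects of a comparison
   pair — the operational rule used in clinical connectome studies of
   this design. Edges are then rich-club (hub–hub), feeder (one hub) or
   local (no hub), and between-group tests on hub–hub edge weights
   yield "abnormal" (significantly increased/decreased) connections.
3. **Group statistics.** Every nodal metric and hub–hub edge weight is
   compared between groups with a pooled-variance two-sample t-test
   after residualizing on age and sex; Bonferroni correction is applied
   within each 90-node metric family. Clinical correlates use partial
   Pearson correlations controlling the same covariates. The ANI
   (asymptomatic neurocognitive impairment) pattern rule labels a
   six-domain T-score profile impaired when at least two domains fall
   at or below the adjusted mean minus one SD.

## Key conventions and why

**Distance transform.** Shortest-path computations use edge length
`1/w`. For FA weights in (0, 1] this is the standard convention in
GRETNA-style structural analyses: strong tracts are short. `-log w` and
hop-count alternatives are available through the `transform` argument of
`shortest_distances()`.

**Disconnected pairs.** Unreachable pairs contribute 0 to efficiency
(their inverse distance) and are excluded from path-length means. This
matches common toolbox behaviour and keeps `lp` finite on the
occasionally disconnected rewired nulls.

**Weighted clustering.** The Onnela form: the geometric mean of the
three triangle weights, normalized by the network maximum, summed over
neighbour pairs and divided by `k (k - 1)`. The binary variant is
selectable since published regional analyses often do not state which
variant their toolbox used.

**Betweenness.** Brandes' algorithm (via igraph) with `1/w` lengths;
tied shortest paths share credit fractionally. The test suite checks
both betweenness and distances against an independent brute-force
enumerator on 50 random graphs with up to 8 nodes.

**Null models.** Maslov–Sneppen double-edge swaps that preserve the
binary degree sequence exactly; each rewired edge carries its weight to
its new endpoints. Defaults: 100 null networks and 10 successful swaps
per edge, seeded. Graphs admitting no valid swap (e.g. a triangle) are
returned unchanged with the achieved swap count attached. The swap walk
runs in compiled code and draws from R's RNG, so a seed fully
determines the null ensemble.

**Hub rule details.** Degrees are averaged across all subjects of the
supplied cohort (both groups of a comparison pooled); the 1-SD rule
uses the population SD over the 90 averaged degrees; top-k ties break
toward the smaller region index. Sample-vs-population SD is a real
ambiguity in the published rule — the choice does not alter any worked
example in the tests, and both hub rules are exposed.

**Covariate adjustment.** Residualization is fitted on both groups
pooled, never per group, so the group contrast itself is not absorbed
by the adjustment. An exactly collinear design raises an error naming
the offending column. Residuals at floating-point noise level (a metric
constant across all subjects) are flagged degenerate (`t = 0, p = 1`)
rather than tested on rounding noise.

**Multiple comparisons.** The Bonferroni family is the 90 nodes within
one metric (m = 90), not nodes × metrics: each metric's table is read
as its own family, the convention in the tables this pipeline mirrors.
Correlation screens are reported at raw p < 0.05.

**ANI boundary.** "At least one SD below the adjusted mean" is read
inclusively (T ≤ mean − SD counts as impaired); the boundary case is
tested explicitly. The preserved-daily-living requirement is an input
flag, since daily-functioning instruments are outside this package.

**Sparsity thresholding** is optional and off by default: the analyses
run on the raw weighted matrices, with an opt-in grid (0.10–0.34, step
0.01) and trapezoidal AUC aggregation, because published threshold
grids for this design are rarely stated and the raw-matrix analysis is
the reproducible core.

## The synthetic cohort generator

`generate_cohort()` produces the cohort structure this analysis design
expects: 48 patients — the first 24 forming the cognitively impaired
(ANI) subgroup and the second 24 the unimpaired (NONHAND) subgroup —
and 48 controls, 90 nodes each.

- **Topology.** One binary topology and one base-weight draw are shared
  by *all* subjects: pair connection probability is
  `base_density + hub_degree_boost × (number of planted-hub endpoints)`
  (defaults 0.15 and 0.30), which plants a 13-node core whose mean
  degree sits more than 3 population SDs above the periphery. The
  default hub set is the 13 AAL regions classically reported as
  rich-club members in subcortical/occipital cortex (bilateral putamen,
  precuneus, calcarine cortex, caudate, superior/middle occipital gyri,
  cuneus, left thalamus).
- **Weights.** Group-level edge FA ~ Normal(0.5, 0.1) truncated to
  [0.2, 0.8] — the range typical of deterministic-tractography FA means —
  plus per-subject Normal(0, 0.04) noise, clamped to keep edges present
  so the binary architecture is stable across subjects.
- **Effects.** Group differences enter *only* through planted edge or
  node effects (`effect_edges`, `effect_nodes`; deltas bounded at ±0.2
  so FA stays in [0, 1], checked before sampling). A cohort without
  effects is therefore an exact null for every group comparison — this
  is what makes the false-positive calibration tests meaningful.
- **Covariates and scores.** Ages ~ Normal(32.3, 5.7) patients /
  Normal(34.5, 6.5) controls truncated to 18–55; sex counts fixed at
  46M/2F (one F per patient subgroup) and 44M/4F rather than Bernoulli
  draws, matching the heavily skewed cohorts of this literature while
  keeping the sex covariate estimable in every 24-subject subgroup.
  Six-domain T-scores are drawn per subgroup with means/SDs in the
  ranges reported for impaired vs unimpaired patients (e.g. fine motor
  40.4 ± 11.6 vs 46.9 ± 7.6); controls carry no scores, as batteries
  are often not administered to controls in this design.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: spatial embedding and distance-dependent
connection probability; inter-subject topological variability (real
subjects differ in binary topology; here only weights vary);
heteroscedastic, non-Gaussian FA noise; correlated measurement error
between neighbouring edges; and any true coupling between cognition and
connectivity (T-scores are independent of the matrices unless an effect
is planted). Results on synthetic cohorts validate the *machinery* —
recovery of planted structure and statistical calibration — not claims
about patients.

## Streamline emulation

Voxel-level tracking is out of scope; the network-construction module
consumes streamline *summaries* (region pair, per-step FA samples,
minimum FA, maximum turning angle) and enforces the tracker's inclusion
rules as record-level predicates: minimum FA ≥ 0.2, maximum turning
angle < 45°, both endpoints assigned, endpoints distinct. Whether a real
tracker terminates segment-wise or filters whole streamlines is not
observable at this level; the record predicate approximates either.
"Average FA of the contained streamlines" is implemented as the mean of
per-streamline mean FA (each streamline counts once, robust to length
imbalance), with a pooled-samples variant behind the `averaging`
argument.

## Numerical choices

- Matrix validation symmetrizes by averaging with the transpose;
  asymmetry above 1e-6 warns (tract counting can be one-sided; hard
  rejection would discard usable data). Negative or NaN entries are
  errors.
- Sparsity thresholding keeps exactly `round(s · N(N−1)/2)` strongest
  edges; ties at the cutoff break toward the lexicographically smaller
  node pair, making thresholded edge sets nested across the grid.
- Zero pooled variance in a t-test returns the degenerate convention
  t = 0, p = 1 with a flag, never an exception mid-table.
- Rich-club values at club sizes below 2 are flagged undefined (`NA` +
  `defined = FALSE`), never silently zero.
- All randomness flows from one root seed through named substreams
  (small-world nulls, rich-club nulls, simulation), so stages are
  individually reproducible and a pipeline rerun is byte-identical.

## Validation problem sizes

The shipped test-suite and acceptance script validate at these sizes,
chosen to give stable Monte-Carlo estimates at interactive runtimes:
oracle equivalence on 50 random graphs of 5–8 nodes; rich-club
calibration on 20 ER graphs G(40, 0.25) and 50 planted-core graphs with
20 nulls each; hub recovery on 100 (tests) / 50 (script) full-size
cohorts; type-I error over 10,000 (tests) / 5,000 (script) simulations
at n = 24 vs 24; power for a d = 1.5 nodal deficit over 200 seeds; and
FABIRC recovery at 200 streamlines per region pair.

## Known limitations

- The AAL→RSN assignment is a bundled, editable reconstruction
  (`inst/extdata/aal90_rsn_synthetic.tsv`): canonical anatomical
  groupings with an `alt_rsn` column for ambiguous regions. Summaries
  use the primary label only, for deterministic counting.
- Only plain two-sample inference is provided; permutation-based
  network statistics (e.g. NBS) and community detection are out of
  scope.
- Normative T-score computation is not performed: adjusted means and
  SDs for the ANI rule are inputs.
- The pooled-residualization + pooled-t pathway approximates ANCOVA; at
  n = 24 + 24 its empirical type-I error is within [0.040, 0.060]
  (verified by simulation), but the residual degrees of freedom are not
  exactly those of a joint model. A Welch variant is available.
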