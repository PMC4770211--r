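---
title: "Methods: disorder evolution analysis of the Mediator complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disorder evolution analysis of the Mediator complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medidr)
```

## The problem

The Mediator complex is a large, modular transcriptional coactivator
(Head, Middle, Tail and Kinase modules) found throughout eukaryotes. Its
subunits are rich in intrinsically disordered regions (IDRs): segments
that adopt no stable tertiary structure and that mediate much of the
complex's promiscuous protein-protein interaction repertoire. `medidr`
implements a comparative pipeline for studying how that disorder is
distributed and conserved across kingdoms: from per-residue disorder
scores to IDR segments, region-wise conservation classes, organism
clustering on disorder signatures, PTM enrichment and hotspots, MoRF and
junction-MoRF analysis, and interaction-hub classification.

The package deliberately consumes predictor output (IUPred-style score
tables, MoRF score tracks, PTM site lists, precomputed alignments,
interaction edge lists) rather than recomputing any of it: the
contribution is the downstream comparative analysis, not the predictors.

## Core definitions and parameters

All defaults are the analysis' canonical values and live in
`run_config()`:

* **Disorder call.** A residue is disordered when its predictor score is
  greater than *or equal to* 0.5 (`binarize()`; the boundary is
  inclusive, so a score of exactly 0.5 counts).
* **IDR.** A continuous stretch of at least 30 residues of disorder,
  tolerating ordered gaps of at most 3 residues (`call_idrs()`). Two
  readings of the gap rule are possible ("one gap total" vs "any number
  of gaps, each at most 3 residues"); we implement the latter, since a
  single-gap rule would make long IDRs with two short interruptions
  uncallable, contradicting the long terminal IDRs the analysis is built
  around. The 30-residue minimum counts the full span including
  tolerated gaps ("a continuous stretch of at least 30 amino acids"
  describes the stretch, not the disordered-residue count).
* **Region assignment.** Proteins are split into thirds: N =
  `[1, floor(L/3)]`, middle = `(floor(L/3), floor(2L/3)]`, C = the rest
  (the remainder when `L` is not divisible by 3 accrues to C — a
  deterministic documented convention). An IDR belongs to the region
  holding more than half of its span; for long IDRs where none does, the
  termini take precedence over the middle, ties to N. With the floor
  convention, region assignment is exactly mirror-symmetric only when
  `L` is divisible by 3; the property tests use such lengths.
* **Conservation classes.** A region of a subunit is *highly conserved*
  in a kingdom when at least 70% of that kingdom's organisms (with the
  subunit) have an IDR there, *moderately conserved* at 50-70%.
  *Restricted* IDRs — conserved only within an organism group — are
  operationalized in `restricted_idrs()` as kingdom-wide presence below
  50% but at least 70% within a user-supplied subset, turning a
  by-inspection notion into a testable rule.
* **Clustering.** Organisms are points in subunit space: the coordinate
  of organism X on subunit i is the mean per-residue disorder of that
  subunit (`average_disorder()`). Distance is the Euclidean
  root-sum-of-squares over corresponding subunits. Subunits absent in
  either organism (Med1 in plants, Med26 in fungi) are skipped under the
  default `shared_only` policy — the least-assumption reading of
  "corresponding subunits"; `shared_rescaled` additionally multiplies by
  `sqrt(n_total/n_shared)` for users who prefer missingness not to
  shrink distances. Trees are built by standard Saitou-Nei neighbor
  joining written for this package (`nj_tree()`), with deterministic
  lowest-index tie-breaking and negative limb lengths clamped to zero
  with the deficit moved to the sister branch so path lengths survive.
  On additive matrices the generating topology and branch lengths are
  recovered exactly (this is a tested invariant).
* **Group extraction.** Published dendrogram groupings are visual, so
  `cut_groups()` offers two explicit rules: remove the `k-1` longest
  internal edges, or remove every internal edge longer than `tau` times
  the median internal edge length. On the default synthetic study the
  between-group edges are 14-112x the median while within-group edges
  stay below about 5x, so the default `tau = 8` sits in the middle of a
  wide gap; any `tau` in roughly `[6, 12]` yields the same partition.
* **Kingdom statistics.** Per-subunit kingdom differences are assessed
  with a two-sided Mann-Whitney U test at alpha 0.05 (two-sided because
  the summary table is symmetric in direction; no multiple-testing
  correction, since raw probabilities are reported). `mann_whitney_u()`
  enumerates all label assignments exactly when `min(n) <= 8` and the
  pooled sample is tie-free, and otherwise uses the tie-corrected normal
  approximation with a 0.5 continuity correction. The approximation is
  within 0.02 of the exact p for `min(n) >= 5` (verified exhaustively
  over all achievable U); for the very smallest samples the worst-case
  gap grows to 0.088 at n = 2 vs 2, which is why `auto` prefers exact
  there.
* **Rank-order strings.** `rank_order_string()` prints per-subunit
  comparisons like `"P>M>F"`: kingdoms sorted by decreasing mean,
  adjacent pairs joined by `>` when the pairwise p-value is below alpha,
  `=` otherwise. Within a maximal run of `=`-connected kingdoms the
  letters appear in the fixed display order P, M, F — the convention the
  published comparison tables follow (rows like `P = M = F` print P
  first even when the P mean is not the largest). Only the linear form
  is emitted; the full three-bit significance pattern travels alongside
  in `kingdom_comparison()`.
* **PTM hotspots.** A 30-residue window qualifies when its fraction of
  PTM-occupied positions lies in `[0.1, 0.3]`, both bounds inclusive
  ("between 0.1 and 0.3" read inclusively). Windows slide one residue at
  a time (a tiled scan is available via `step`); overlapping qualifying
  windows merge into maximal regions whose density is the best window
  inside; regions are banded low `[0.1, 0.2)` / high `[0.2, 0.3]` with
  the 0.2 boundary going high. Two PTM types at one position count once:
  density is positional occupancy. Windows denser than 0.3 are excluded
  per the literal rule even though biologically surprising;
  `max_density = 1` lifts the cap.
* **MoRFs.** At least 5 consecutive residues with MoRF score >= 0.5, no
  gap tolerance. A MoRF region is *conserved* when its alignment columns
  are MoRF-covered in at least 4 organisms; any columnar overlap counts
  (requiring full-length overlap is stricter than the stated "aligned in
  at least four organisms"), and regions must span at least 5 columns,
  mirroring the MoRF minimum so single-column artifacts cannot qualify.
* **Junction-MoRFs.** The concept — a MoRF at the boundary between an
  IDR and well-defined secondary structure — comes from structural
  inspection; `junction_morfs()` gives it a coordinate rule usable at
  scale: a MoRF is flagged when it overlaps the `+/-10`-residue window
  around an IDR boundary *and* covers at least one residue on each side
  of that boundary (or when domain intervals are supplied, when its
  boundary window intersects a domain boundary window). The window `w`
  is configurable.
* **Hubs.** A protein with at least 10 distinct direct interaction
  partners is a hub; at least 5 subunit partners makes a
  subunit-subunit hub. Self-loops (homodimerization) are reported but
  never counted as partners. Edge lists are deduplicated as unordered
  pairs; upstream filtering to "direct" evidence is the data supplier's
  job.

## The synthetic study

Real inputs for the 146-proteome study are not redistributable, so
`simulation_config()` defines a synthetic study with the same
statistical structure, and every analysis stage is tested against its
planted ground truth.

* **Composition.** 146 organisms: 97 metazoans, 24 plants, 25 fungi.
  Fifteen of them (8 metazoans, 3 plants, 4 fungi) form a cross-kingdom
  *basal* group sharing one low-disorder signature, emulating the
  early-diverging organisms (placozoans, poriferans, microsporidians,
  green algae) that co-cluster regardless of kingdom.
* **Signatures.** The per-kingdom, per-subunit mean disorder values are
  the published per-kingdom means for a 14-subunit panel spanning all
  four modules, including Med1 (absent in plants) and Med26 (absent in
  fungi) so the missing-subunit distance policies are exercised. The
  basal signature is a uniform low-disorder profile (0.12-0.30).
* **Dispersion.** The between-organism standard deviation defaults to
  0.02 per subunit — the low end of the published 0.02-0.18 range. The
  published standard deviations pool basal and derived organisms, which
  the generator models as separate groups, so the residual within-group
  dispersion is taken at the low end; this also realizes the separated
  signatures under which group recovery is a meaningful test
  (between-centroid distances 0.28-0.9 against a within-group spread of
  about 0.10).
* **Score tracks.** Per-residue scores are Beta-distributed (bounded in
  `[0, 1]` like real disorder propensities): mean 0.75 inside planted
  IDR blocks, 0.25 outside, concentration 30. Blocks are planted to
  carry the disordered fraction implied by each profile's target mean
  (C-terminal first, split N+C for large fractions, echoing the
  terminal-IDR bias of real subunits); a small residual shift aligns
  the profile mean with its target. What this does *not* model:
  amino-acid composition of disorder, autocorrelated predictor noise,
  or phylogenetic correlation within groups — so passing tests show the
  pipeline's rules behave correctly, not that real Mediator data would
  cluster this cleanly.
* **PTMs.** Sites are placed per position with inside-IDR odds
  multiplied by 3 (default), scaled to 5 sites per 100 residues —
  consistent with the observed concentration of phosphorylation and
  acetylation in IDRs.
* **Alignments and MoRFs.** Homologs derive from one ancestor by uniform
  substitution (rate 0.2) and residue deletion (rate 0.03); the true
  alignment is kept by construction, so no aligner runs. MoRF blocks are
  planted at homologous columns in a configured organism subset.
* **Networks.** Planted hub subunits are topped up with distinct
  external partners to degree 10-40; non-hubs stay below 10.
  Subunit-subunit edges appear with probability 0.2, giving several
  subunit-subunit hubs at the >= 5 threshold.

Every generator is a pure function of `(config, seed)`; identical seeds
give byte-identical files, which is what makes the end-to-end
determinism check meaningful.

## Numerical choices

* Density and score boundaries are compared inclusively with a `1e-9`
  tolerance so `3/30` qualifies as exactly 0.1 regardless of floating
  point representation.
* Exact Mann-Whitney enumeration refuses pooled samples beyond 5 million
  assignments; `auto` never requests them.
* NJ Q-matrix ties break at the lowest (row, column) index; group
  cutting breaks edge-length ties by tree edge order. Both make reruns
  reproducible, and neither attempts to replicate any particular legacy
  implementation's tie behaviour.
* Degenerate inputs fail loudly: empty tracks, out-of-range scores,
  non-contiguous score tables, proteins shorter than the analysis
  window, distance matrices without labels.

## A worked example

```{r example}
cfg <- simulation_config(seed = 11)
sim <- simulate_profiles(cfg)
mat <- build_disorder_matrix(sim$profiles)
d <- disorder_distance_matrix(mat)
tree <- nj_tree(d)
groups <- cut_groups(tree, "length_threshold", tau = 8)
lengths(groups)
```

The four groups recover the planted structure: the 89 derived metazoans,
the 21 derived plants, the 21 derived fungi, and the 15-organism
cross-kingdom basal group.

```{r example2}
p <- sim$profiles[["metazoa_main_001|Med19"]]
idr_segments(p)
```

Med19's planted disorder shows up as N- plus C-terminal IDRs, matching
its high mean disorder in the panel signature.

## Problem sizes used in the tests

The test suite and the acceptance script exercise: the full 146-organism
study for clustering and end-to-end determinism; 10,000 random tracks
(length <= 200) for the IDR caller against an independent enumeration
oracle; 200 random additive matrices (<= 12 leaves) for NJ; 2,000 null
replicates (n = 20 per group) for Mann-Whitney type-I calibration and
500 replicates for power at a 0.15 mean gap (sd 0.07, n = 25); 2,000
random site tracks for the hotspot scan and 1,000 for the MoRF caller.

## Known limitations

* The pipeline never computes disorder, MoRF, or PTM predictions from
  sequence; garbage score tracks yield garbage segments.
* `shared_only` distances are not guaranteed metric under heavy
  missingness (with full presence the triangle inequality is tested).
* The junction-MoRF rule is a coordinate surrogate for a structural
  concept; it cannot see secondary structure that is absent from the
  supplied domain intervals.
* Conservation percentages treat organisms as independent; no
  phylogenetic correction is attempted, matching the original analysis.
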