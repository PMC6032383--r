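---
title: "Ensemble docking analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble docking analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdock)
```

## The problem

Rigid-receptor docking against a single crystal structure is biased toward
ligands that fit that one conformation. For conformationally plastic targets
— the motivating case is a nuclear hormone receptor whose ligand-binding
domain adopts distinct agonist-bound and antagonist-bound states, with no
experimental antagonist-bound structure available — this bias is severe:
antagonists score poorly against agonist-state structures and frequently
cannot be docked at all. Ensemble docking mitigates this by docking each
ligand into a set of receptor conformations (crystal structures and/or
snapshots from molecular dynamics) and taking the best score across the
members as the ligand's final score.

`ensdock` implements the analysis side of that workflow: the score
containers, the enrichment statistic, the ensemble-member selection, the
trajectory clustering that produces candidate conformations, and a synthetic
generator so the whole pipeline is testable without a commercial docking
engine or MD package.

## The score model

Scores follow the common empirical docking convention: **lower = higher
predicted affinity**. A score matrix is a ligands × conformations grid with
a parallel logical grid of *docking failures* — cells where the engine
returned no pose. A failure is a flag, never a sentinel value: plots of real
screens sometimes encode failure as score 0, which collides with a
legitimate score of 0.0, so internally the score slot of a failed cell is
undefined (`NA`) and every consumer handles it explicitly.

Ensemble aggregation is the minimum over non-failed member cells:

$$ s_i(E) = \min_{m \in E,\ (i,m)\ \text{not failed}} s_{im}, $$

with $s_i(E)$ failed iff ligand $i$ failed on every member of $E$. This
makes aggregation monotone: enlarging the ensemble can only improve (lower)
a ligand's score — one of the property tests.

## The enrichment statistic

Screening performance is the ROC AUC: the probability that a randomly chosen
active is ranked better than a randomly chosen inactive. It is computed by
the Mann–Whitney rank formulation with midrank ties:

$$ \mathrm{AUC} = \frac{1}{n_a n_d} \sum_{a, d}
   \left[ \mathbb{1}(s_a < s_d) + \tfrac{1}{2}\,\mathbb{1}(s_a = s_d) \right]. $$

Two deliberate choices:

* **Failure censoring.** A failed docking ranks strictly worse than every
  finite score, and two failures tie (contribute 1/2). A compound that
  cannot be docked must not be rewarded; at the same time, this stays
  correct when legitimate scores are positive, which a sentinel-0 encoding
  would not.
* **Midranks, not optimistic/pessimistic ties.** Midranks make the
  antisymmetry identity `auc(A,B) + auc(B,A) = 1` hold exactly. The
  implementation computes the AUC as a single fraction
  $(N - U)/N$ rather than $1 - U/N$; with the correctly rounded IEEE
  division this keeps the identity bit-exact, which the suite asserts with
  `expect_identical()`.

Early-enrichment metrics (BEDROC, EF@1%) are intentionally absent: for
toxicology-style screening the full-ranking AUC is the quantity of
interest, and it has well-understood statistics.

## Ensemble selection

`exhaustive_search()` evaluates **all** $\binom{n}{k}$ size-$k$ subsets of
the conformation pool under one of two objectives:

* `auc_vs_decoys` — AUC of the active class against the decoys;
* `summed_auc` — that term plus the AUC of the active class against a
  second ligand class (e.g. antagonists vs agonists), unweighted. The sum is
  left unweighted because no principled weighting presents itself; both
  terms live on the same [0, 1] scale.

Default $k = 5$: the conventional trade-off between covering receptor
flexibility and docking cost; at the default pool of 12 conformations the
search space is $\binom{12}{5} = 792$ candidates and evaluates in about a
second at full screen size (3233 ligands), so exhaustive search — not a
heuristic — is the right tool at this scale.

Objective ties are real, not hypothetical: when enrichment saturates
(AUC exactly 1 for many subsets) the optimum is a large tie class. Ties are
broken by the **lexicographically smallest sorted member-id tuple** — a
deterministic, reportable rule. The full ranked candidate list is retained
so secondary selections (the best ensemble under a different objective)
need no re-search.

## Trajectory clustering and representatives

Candidate conformations come from clustering trajectory frames on
binding-site similarity:

1. **Binding site**: all protein heavy atoms within 5.0 Å of any ligand
   heavy atom. The selection is resolved once, on a reference frame
   (default: frame 1), and frozen — per-frame reselection would change the
   RMSD atom set across pairs and make the distance matrix ill-defined. All
   heavy atoms are used, not backbone only.
2. **Distance**: pairwise heavy-atom RMSD over the site atoms, after an
   optimal least-squares superposition on those same atoms (MD frames are
   conventionally aligned; the superposition is switchable).
3. **Clustering**: affinity propagation on the similarity
   $s(i,j) = -d(i,j)^2$, with self-similarity (preference) defaulting to the
   median off-diagonal similarity, damping 0.9, at most 1000 iterations,
   convergence declared after 50 iterations of a stable exemplar set.
   Non-convergence is a hard error carrying the partial message state.
   After convergence each cluster's exemplar is refined to the member
   maximising summed within-cluster similarity (the same refinement the
   reference implementations apply). Affinity propagation is used because
   it returns *exemplars* — actual frames — directly; "centroid of a
   cluster" is therefore taken to mean the exemplar, avoiding any
   mean-structure construction. Note that a larger preference yields *more*
   exemplars; the property suite asserts this monotone direction.
4. **Representatives**: exemplars of the 3 most populated clusters,
   population-descending, ties to the lower cluster index.

Crystal-structure pools are clustered separately by
`cluster_structures_by_site()`: superposed binding-site RMSD, average-linkage
hierarchical clustering cut at 5 clusters, medoid (minimum summed
intra-cluster distance) per cluster. This is a declared stand-in for
published binding-site-similarity protocols, not a reproduction of any
specific one; with all-identical inputs the zero distance matrix resolves,
by documented convention, to the earliest structures.

## Pocket volume

`pocket_volume()` estimates the enclosed cavity volume by a grid/flood-fill
construction: cell-centred grid points spanning the site bounding box
(padded by probe + one spacing) are *free* if farther than
$r_\mathrm{vdW} + r_\mathrm{probe}$ from every protein atom
(element radii C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, default 1.7 Å; probe
1.4 Å); free points 6-connected to the box boundary are solvent; the rest
are cavity, each contributing $\mathrm{spacing}^3$.

The grid is **cell-centred** (points at `box_min + (k + 1/2)·spacing`)
rather than corner-anchored. With a corner-anchored grid, points fall
exactly on the probe-contact surface whenever atom coordinates are
commensurate with the spacing, and the strict "farther than" rule then
systematically loses or gains half a cell per face — a ±25% bias on a 6 Å
cube. Cell-centred sampling is the unbiased volume estimator; on the
analytic fixtures (cube side 6 Å = 216 Å³, sphere radius 4 Å ≈ 268 Å³) the
0.5 Å grid is within 2.5%, and halving the spacing moves the estimate by
well under 10%.

## The synthetic generator

The generator stands in for the docking engine and the MD engine, so every
stage has a ground truth. Its defaults are the study conditions of the
motivating screen:

| parameter | default | meaning |
|---|---|---|
| ligands | 118 / 115 / 3000 | agonists / antagonists / decoys (~1:30 actives:decoys per active set) |
| pool | 6 + 6 | agonist-like + antagonist-like conformations (4 trajectories × 3 representatives) |
| means | ago −11 everywhere; ant −6 / −11; decoy −4 | class × conformation-type score means |
| sd | 1 | common score spread |
| failures | antagonist on agonist-like: 0.3 | Bernoulli per cell, independent |

Scores are class-conditional Gaussians (real per-class score distributions
are unimodal to a first approximation); failures are independent Bernoulli
per cell. This is the simplest model reproducing the qualitative phenomena
of the real screen: promiscuous agonists, conformation-selective
antagonists, and class-dependent failure counts concentrated on
antagonist/agonist-like cells.

What the generator does **not** emulate: correlated scores across similar
conformations, heavy-tailed score errors, chemically meaningful ligands, or
physically meaningful trajectories. Passing tests on synthetic screens
therefore demonstrate the correctness of the *analysis machinery*, not
docking accuracy on real systems.

One consequence of the default separations deserves honesty: with decoys at
−4 and actives at −11 (7 standard deviations after min-aggregation), the
active-vs-decoy AUC saturates at exactly 1.0 for essentially every subset
containing at least one favourable conformation. The selection landscape is
then a massive exact tie and the deterministic tie-break — not the
objective — decides the winner, so the selected ensemble is *not* enriched
in the planted favourable conformations even though its enrichment is
perfect. The cross-ensemble *ordering* (the agonist-selected ensemble
screens antagonists worse than the antagonist-selected one) is robust to
this saturation and is the property the pipeline tests lean on. A screen
with overlapping distributions (e.g. decoys at −9) would instead make
membership recovery informative; the defaults were fixed once, as stated
above, and not tuned afterwards.

The toy frame generator plants conformational clusters as per-atom random
displacement *fields* of the binding-site atoms (cluster 1 is the
undisplaced reference). Rigid per-cluster translations would be removed by
the superposition step; a random field is non-rigid, so the planted
separation survives alignment.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`score_gen_config()`
and `gen_toy_frames()` take one; nothing reads hidden global state). The
test suite runs the full-scale screen (3233 ligands × 12 conformations,
792-subset exhaustive search, 10 seeds) in well under a minute; the
clustering and volume fixtures use 30 frames × 40 atoms and ~1000-atom
shells respectively. `scripts/acceptance.R` recomputes the bundled
cross-docking example, the synthetic benchmark, the clustering recovery and
the analytic cavity volumes from scratch in a few seconds.

## Known limitations

* Docking, ligand preparation, induced-fit refinement and MD themselves are
  out of scope; scores and frames are opaque inputs.
* The ROC AUC failure-censoring convention (failures share the worst rank)
  is one defensible choice; excluding failed compounds entirely would give
  different, generally more optimistic numbers. The convention is explicit
  in `roc_auc()` and applied consistently.
* `cluster_structures_by_site()` requires a common (residue number, atom
  name) set across structures — it maps crystal structures of the *same*
  protein, not homologues.
* Pocket volumes depend on the vdW table, probe radius and grid spacing;
  absolute values from different tools are not directly comparable, and the
  printed volumes of real receptor structures are not reproduced here
  (doing so requires those structures and the original tool).
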