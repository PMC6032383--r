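# ensdock

Analysis toolkit for **ensemble docking** virtual screens: given docking
scores of ligand libraries against pools of receptor conformations, it
aggregates scores across ensemble members, measures enrichment, selects the
best-performing ensembles by exhaustive subset search, and provides the
trajectory-clustering machinery that produces candidate receptor
conformations in the first place.

It is written for structure-based virtual-screening and computational
toxicology work on conformationally plastic targets — the motivating case
is a nuclear hormone receptor whose antagonist-bound state has no crystal
structure, so antagonist screening relies on MD-derived conformations and
the question becomes *which* subset of conformations to dock against.

## What it computes

* **Score matrices with failure flags** (`score_matrix`,
  `load_score_matrix`): ligands × conformations, lower score = higher
  predicted affinity; a docking failure is a flag, never a sentinel score.
* **Ensemble aggregation** (`aggregate_scores`): a ligand's final score is
  its best score across the ensemble members; failed only if it failed on
  every member.
* **Enrichment** (`roc_auc`): Mann–Whitney ROC AUC with midrank ties,

  AUC = Pr(random active ranks better than random inactive),

  where failed dockings share the strictly worst rank. Midranks make
  `auc(A,B) + auc(B,A) = 1` exact.
* **Ensemble selection** (`exhaustive_search`): all C(n, k) size-k subsets
  evaluated under `auc_vs_decoys` or the summed two-term objective
  (active-vs-decoy + active-vs-other-class); deterministic lexicographic
  tie-break; full ranked candidate list returned.
* **Trajectory clustering** (`select_binding_site`,
  `pairwise_rmsd_matrix`, `affinity_propagation`, `representatives`):
  binding site = protein heavy atoms within 5 Å of the ligand; superposed
  heavy-atom RMSD; affinity propagation on −d²; exemplars of the three most
  populated clusters as representative structures. Crystal pools are
  clustered with `cluster_structures_by_site` (average-linkage on
  binding-site RMSD, medoids).
* **Pocket volume** (`pocket_volume`): grid/flood-fill cavity volume with
  vdW + 1.4 Å probe exclusion.
* **Synthetic screens** (`score_gen_config`, `gen_score_matrix`,
  `gen_toy_frames`): seeded generators with planted structure standing in
  for the docking/MD engines, so the full pipeline is testable offline.

## Worked example

The package bundles a 5 × 5 cross-docking table (five ligands docked into
five receptor crystal conformations; `N/A` marks failed dockings):

```r
library(ensdock)
ex <- load_crossdock_example()
ex$matrix
#> <score_matrix> 5 ligands x 5 conformations, 8 failed cell(s)

aggregate_scores(ex$matrix, ex$matrix$conformation_ids)
#>  3B66  3G0W  3V49  4HLW  2PNU
#> -12.2 -11.2 -12.2 -11.3 -14.2

run_crossdock_report(ex$matrix, ex$native_map)
#> <crossdock_report> 5 / 5 ligand(s) best on their native structure; 8 failed cell(s)
```

Every ligand's ensemble-aggregated (best-across-members) score is achieved
on its own native structure — the cross-docking consistency check — and 8
of the 25 ligand/structure pairs produced no pose at all, 4 of them for the
bulkiest ligand (2PNU), which only fits its own induced-fit conformation.

A full synthetic screen, end to end:

```r
g <- gen_score_matrix(score_gen_config(seed = 1))
sr <- exhaustive_search(g$matrix, g$labels, k = 5,
                        objective = ensemble_objective("auc_vs_decoys", "antagonist"))
sr$best
#> <ensemble_result> {agolike_01, agolike_02, agolike_03, agolike_04, antlike_01}
#>   objective (auc_vs_decoys, active = antagonist): vs_decoys 1.0000 = 1.0000
```

The `analysis/` directory holds the numbered workflow drivers
(`01_crossdock.R` … `05_pocket_volume.R`); each is a thin narrative script
over the package functions that prints what it found and writes its tables
under `results/`.

## Scope

Docking engines, ligand preparation, induced-fit refinement, metadynamics
and MD simulation are out of scope: scores, labels and coordinate frames
are this package's inputs. See the methods vignette
(`vignettes/ensemble-docking-methods.Rmd`) for the models, parameter
defaults, numerical choices and known limitations.
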