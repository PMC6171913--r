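---
title: "Multi-task Kronecker kernel SVMs for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task Kronecker kernel SVMs for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KronDTI)
```

## The problem and the model

Chemogenomics frames drug-target interaction prediction as completing a
binary protein x molecule interaction matrix: known interactions are
positive labels, and every unlabeled pair is treated as a negative, on the
assumption that true-but-unrecorded interactions are rare. KronDTI solves
this as a classification problem over (protein, molecule) *pairs* with a
support vector machine. The pair kernel is the Kronecker product of two
entity kernels,

$$K_{pair}\big((p, m), (p', m')\big) = K_{protein}(p, p') \times
K_{molecule}(m, m'),$$

so the decision function for a query pair is

$$f(p, m) = \operatorname{sign}\Big(\sum_i \alpha_i\, y_i\,
K_{molecule}(m, m_i)\, K_{protein}(p, p_i) + b\Big).$$

This is a multi-task method: training pairs involving *other* proteins
contribute to the prediction for protein $p$, weighted by how similar those
proteins are to $p$. The single-task baselines (`singleTaskFit`) are the
degenerate cases in which one factor is constant: a ligand-based model
learns over proteins for one fixed molecule, a target-based model over
molecules for one fixed protein. When one kernel is identically 1, the
pair-space model provably collapses onto the corresponding single-task
model; the test suite checks this numerically.

The full Kronecker matrix over all pairs is never materialized: training
Gram matrices are assembled entry-wise from the two entity kernel matrices,
which is what makes pair-space SVMs affordable when the training set per
query is kept small (next section).

### Reduced per-query training sets

Fitting one SVM on all $n_p \times n_m$ pairs is intractable and, more
importantly, training pairs far from the query dilute the decision
function. `buildTrainSet()` therefore assembles a small training set per
query pair $(p^*, m^*)$:

* **intra-task positives** — every known interaction sharing $p^*$ or
  $m^*$ (the query pair itself is always excluded);
* **intra-task negatives** — `negPosRatio` times as many pairs $(p, m^*)$
  with $p$ not a known target of $m^*$, sampled without replacement
  (ligand axis by default; `negBothAxes` adds the symmetric pool). The
  default ratio of 10 is the trade-off point between recall and training
  cost observed when this family of methods is calibrated on interaction
  databases: performance rises with more negatives and then degrades;
* **extra-task pairs** (NN-MT / RN-MT) — `nExtraPos` positives sharing
  *neither* entity, either the nearest by pair similarity
  $K_{protein}(p, p^*) \times K_{molecule}(m, m^*)$ (NN-MT, ties broken
  lexicographically) or drawn uniformly (RN-MT), plus `extraNegRatio`
  times as many extra-task non-positives chosen by the same rule. The
  default `extraNegRatio = 1` keeps training sets small; `nExtraPos`
  defaults to 10, and for orphan-heavy experiments a number comparable to
  the typical intra-task positive count of the dataset is the recommended
  choice, since extra-task pairs then have to carry the prediction.

With `nExtraPos = 0` the NN-MT training set is exactly the MT-intra one; a
test asserts set equality.

### Percentile similarity filters

To study how performance degrades as the training data moves away from the
query, `applyThetaFilter()` removes positive training pairs whose
similarity to the query exceeds the $\theta$-th percentile of the
dataset's off-diagonal similarity distribution on either axis (thresholds
are computed once per dataset, diagonal excluded). Three conventions were
fixed after inspecting the degenerate cases:

* thresholds are strict (`<`), so $\theta = 0$ keeps nothing;
* $\theta = 100$ disables the filter entirely, so everything is kept —
  no single non-strict convention produces both limits;
* an axis on which the candidate *equals* the query entity is exempt.
  Intra-task pairs share the query's protein or molecule by definition, so
  their self-similarity on that axis is maximal; applying the threshold
  there would empty every filtered training set. The filter therefore
  constrains the varying axis only.

Negatives are not filtered by default (they are plentiful at all
distances); `thetaFilterNegatives` exposes the alternative.

### WNN de-orphanization

For an orphan entity (no known interactions), `wnnProfile()` imputes an
interaction profile: neighbors with at least one interaction are ranked by
decreasing kernel similarity and their binary profiles are summed with
geometric decay $T^{rank-1}$, clipped to $[0, 1]$. Profile entries at or
above `wnnThreshold` become pseudo-positive training pairs
(origin `wnn+`). Defaults $T = 0.8$ and threshold $0.5$ keep roughly the
top few neighbors influential; both are recorded in every serialized
configuration. The decay applies per similarity rank, so the scale of the
kernel does not matter, only its ordering.

## Kernels

**Molecules** are labeled graphs (atoms as vertices with element labels,
lower case for aromatic atoms; bonds as edges labeled single/double/
triple/aromatic), parsed from SMILES with hydrogens suppressed.

* *Tanimoto path kernel* (`tanimotoKernel`): the Jaccard similarity of the
  sets of labeled simple paths with up to `d` atoms. Paths are
  canonicalized to the lexicographically smaller orientation so each
  undirected path counts once. Simple paths (no vertex revisits) were
  chosen over walks for finiteness and agreement with fingerprint
  practice; a count-based min/max variant is available via
  `counts = TRUE`. The default `d = 8` is the path length at which this
  kernel family performs best on drug-like molecules.
* *Marginalized walk kernel* (`marginalizedKernel`): random walks start
  uniformly, stop with probability `q` per step and move uniformly over
  neighbors; matched walk pairs contribute the product of their
  probabilities over label-identical steps. At a degree-0 vertex the walk
  must stop, so the stop probability there is 1 — this makes the kernel of
  two identical single-atom molecules exactly 1. The fixed point is solved
  by iteration on the matched product graph (tolerance 1e-9, cap 10,000
  iterations; non-convergence is an error reporting the residual).
  `morganIndex` rounds of Morgan-style label refinement (sorted
  neighbor-label multisets, applied as plain strings so labels stay
  comparable across graphs) sharpen atom environments before matching.

**Proteins** are amino-acid sequences (20-letter alphabet plus X, which
scores 0 against everything).

* *Smith-Waterman kernel* (`swScore`): the optimal affine-gap local
  alignment score under BLOSUM62 (configurable), with a gap of length $L$
  costing $o + Le$. The score matrix is not PSD, so `psdRepair()` adds the
  magnitude of the most negative eigenvalue to the diagonal before the
  matrix is used as a kernel.
* *Local alignment kernel* (`laKernel`): sums $e^{\beta \cdot score}$ over
  *all* local alignments via dynamic programming in the log domain (the
  linear-scale value overflows quickly; `log = TRUE` returns the always
  finite log value). The same gap convention as `swScore` is used, so
  $\frac{1}{\beta}\log K_{LA} \downarrow SW$ as $\beta$ grows — a
  monotone convergence the tests verify on fixture pairs.
* *Neighborhood k-mer kernel* (`kmerProfileKernel`): a PSSM-free analogue
  of profile-style k-mer kernels. Each k-mer $x$ occupies every feature
  k-mer $y$ with $\sum_j s(x_j, y_j) \ge \sum_j s(x_j, x_j) - t$; the
  kernel is the inner product of occupancy-count vectors. Larger `t`
  (default 7.5, grid 6-10.5) allows more substitution degradation, i.e.
  larger neighborhoods. The feature space is restricted to k-mers observed
  in the dataset, which leaves the kernel PSD (one fixed feature map per
  matrix) while avoiding the $20^k$ enumeration. This is a deliberate
  variant: true profile kernels use position-specific scoring matrices
  from database searches, which require external sequence databases; the
  substitution-matrix neighborhood is the closest self-contained analogue,
  and the hyperparameter grids are kept for orientation but are not
  numerically comparable to the PSSM-based original.
* *Hierarchy kernel* (`hierarchyKernel`): the number of nodes shared by
  two proteins' root-to-leaf paths in a family hierarchy — the inner
  product of binary ancestor indicators, PSD by construction. Node
  identity is the full path prefix, so same-named nodes under different
  parents stay distinct.

**Post-processing.** Kernel matrices destined for the SVM are centered
(feature-space double centering) and then cosine-normalized, in that order
(both steps are standard; the order matters and centering-first is the
convention adopted here — centering is idempotent and normalization then
fixes the diagonal at 1). PSD repair, where needed, happens before both.

**Which kernel state feeds which component.** The SVM consumes centered,
normalized kernels. Nearest-neighbor selection and the percentile filters,
however, use *normalized but uncentered* kernels (the `KpSel` / `KmSel`
arguments of `runBenchmark`). The reason is structural: after centering,
similarities can be negative, and the pair similarity is a product — two
*negative* factors yield a *positive* product, so a candidate dissimilar
to the query on both axes can outrank genuinely similar candidates. On
clustered data this systematically selects wrong-cluster "neighbors" for
queries outside the dense blocks. Uncentered normalized kernels are
nonnegative for the kernels used here, so the product is monotone in each
axis's actual similarity, which is what neighbor selection needs.

## Cross-validation schemes

`makeFolds()` builds the fold systems used to emulate prediction
scenarios:

* `random` — stratified shuffling, folds balanced in positives/negatives;
* `orphan_ligand` / `orphan_protein` — molecules (proteins) are
  partitioned into K groups; every sample in a test fold has a molecule
  (protein) unseen in training;
* `double_orphan` — the two partitions are crossed into $K^2$ test folds
  (25 for K = 5); the training pool for fold $(i, j)$ excludes every
  sample whose protein group is $i$ *or* molecule group is $j$, so test
  pairs are orphan on both axes;
* `clustered_*` — entity groups come from average-linkage hierarchical
  clustering of the kernel (distance $\sqrt{2 - 2K}$ on the normalized
  kernel) instead of random assignment, so test pairs are *dissimilar* to
  all training pairs, not merely unseen. Clustered random/orphan folds
  pair protein cluster $i$ with molecule cluster $i$ (clusters ordered by
  size), so they cover only samples whose entities fall in matched
  clusters; the clustered double-orphan scheme crosses all cluster pairs
  and partitions the samples.

`looSplits()` provides leave-one-out splits, with `orphanMode` removing
every training sample sharing the test pair's protein or molecule
(double-orphan LOO — the regime where single-task methods are undefined).
`nestedCv()` wraps a (K-1)-fold inner search in a K-fold outer loop for
hyperparameter selection; the SVM cost parameter C would typically be
searched on a log grid $10^{-3}..10^3$ (the package default C = 1 is used
where no search is run).

## Metrics and negative test sets

`rocAuc()` uses the Mann-Whitney formulation with midrank tie handling.
`aupr()` integrates the precision-recall curve stepwise (precision at each
distinct threshold times the recall increment), with tied scores collapsed
into a single PR point; linear PR interpolation is deliberately avoided as
it is known to overstate the area. AUPR is the headline metric: with
unlabeled pairs standing in for negatives, it is the measure that
penalizes false positives among the top-ranked predictions.

`balancedNegativeSets()` draws negative test sets in which every protein
and molecule has the same degree among negatives as among positives —
shuffled stub pairing followed by 2-swap repair of duplicate/positive
collisions (cap 1e5 swaps). For infeasible inputs (e.g. an entity holding
every positive), the best-effort set is returned with a per-entity
deviation report rather than an error. Four sets is the conventional
number drawn.

## The synthetic generator

`generateSyntheticDataset()` plants the structure the method assumes:
clustered similarity on both axes, plus a bipartite interaction rule that
follows the clusters. Per molecule cluster, one ancestor graph (random
connected graph over C/N/O/S, 8-16 heavy atoms) is mutated per member by
`graphEditSteps` label swaps or connectivity-preserving edge edits; per
protein cluster, one ancestor sequence (length 120-200, i.i.d. uniform
amino acids) is mutated per member by substitutions at `mutationRate`
(no indels, so alignment scores stay length-comparable). Matched cluster
pairs interact with probability `pIn`, all others with `pOut`.

The defaults — 4 x 4 clusters of 8 entities, `pIn = 0.9`, `pOut = 0.02`,
`mutationRate = 0.1`, `graphEditSteps = 2`, seed 1 — are the study
conditions used by the end-to-end tests and the acceptance script:
roughly 250 positives among 1024 pairs, kernels that separate clusters on
both axes, and a contamination rate of cross-cluster positives low enough
that the planted signal dominates. `mutationRate = 0.1` leaves
within-cluster sequences ~90% identical (close homologs) while 10-20
random substitutions keep members distinguishable; two graph edits do the
same for molecules.

What the generator does *not* emulate: the heavy-tailed degree
distributions of real interaction databases, chemically valid valences,
indels, and realistic family hierarchies (the generated hierarchy has one
node per cluster). Passing the end-to-end tests therefore demonstrates
that the pipeline recovers planted cluster-consistent signal under
orphan-aware evaluation — not that any particular AUPR will be attained on
curated interaction data.

At this fixture scale the intra-task negative candidate pool (at most 31
proteins per query molecule) cannot always honor the n-/n+ = 10 request;
the sampler then takes the whole pool and warns, which is the expected
behavior under the scaled-down study conditions.

## Problem sizes used by tests and the acceptance script

Kernel oracles run on graphs of up to 6 atoms (paths up to d = 4) and
sequence pairs of up to 5 residues, where exhaustive enumeration is exact.
The end-to-end experiments run on the default 32 x 32 fixture with ~500
balanced evaluation samples: 5-fold random CV, 25-fold clustered
double-orphan CV, and double-orphan LOO for NN-MT vs RN-MT (with
`nExtraPos` set to the dataset's median intra-task positive count, the
recommended rule when intra-task pairs are unavailable at test time).
These sizes keep a full run in minutes on one core while leaving the
planted-signal recovery unambiguous.

## Known limitations

* The SMILES reader covers the organic subset (B, C, N, O, P, S, F, Cl,
  Br, I, aromatic forms, branches, ring closures, explicit bonds, the dot
  disconnector) — no bracket atoms, charges, isotopes or stereochemistry.
  This matches what the graph kernels consume; richer inputs should be
  standardized upstream.
* The neighborhood k-mer kernel is a substitution-matrix variant of
  profile-style kernels, not a reimplementation of the PSSM-based
  original; `t` grids are not transferable between the two.
* `singleTaskFit` is undefined for orphan entities by construction; use
  the pair-space model (optionally with WNN) in orphan regimes.
* Per-query SVM fits are independent and deterministic given the master
  seed (per-query sub-seeds are derived from the seed and the query ids),
  so results do not depend on evaluation order; the package itself runs
  single-threaded.
* Decision scores with magnitude below 1e-8 are reported as ambiguous
  (class 0) rather than silently signed.
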