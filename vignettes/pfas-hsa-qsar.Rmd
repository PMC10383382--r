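---
title: "Modelling PFAS binding to human serum albumin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PFAS binding to human serum albumin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasqsar)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical
conventions, and the open design choices that had to be settled one way or
another.

## The problem

PFAS are persistent synthetic fluorochemicals; their binding to human
serum albumin (HSA) — quantified here as an EC50 in mM, the ligand
concentration at which half the protein is bound — governs how they are
transported and accumulate. The package models that binding from 2D
structure alone, on a curated set of 24 PFAS spanning perfluoroalkyl
carboxylic and sulfonic acids, fluorotelomer acids, ethers and alcohols.
Lower EC50 means stronger binding; compounds at or below 1.45 mM are
labelled high affinity (H). The two fluorotelomer alcohols did not bind at
all and carry no EC50; they are always labelled L, and the regression
models use only the 22 binders.

The bundled table stores *two* observed-class columns, because the
published table's class labels disagree with its own threshold rule for
three compounds (C3 at 1.40 mM printed L; C8 at 1.49 and C11 at 1.48
printed H). `pfas_hsa_data(classes = "printed")` keeps the published
labels (and exactly reproduces the published confusion metrics);
`classes = "threshold"` re-derives labels from EC50 (and gives the
published 11 H / 13 L split). Reproducing each published number requires
using the inputs its authors actually used, so neither column is treated
as "the" truth. The SMILES themselves are not printed in the original
table; the fixture encodes structures written from the printed CAS numbers
and names, in neutral (protonated) acid form — the convention of 2D
descriptor software — and each is verified against its molecular formula
in the test suite.

## Molecular graphs and descriptors

All topological descriptors operate on the hydrogen-depleted graph
(standard 2D-descriptor convention); implicit hydrogen counts, derived
from neutral-atom valences over kekulized bond orders, enter only the
McGowan volume, the surface-area hydrogen caps, and the drug-likeness
properties. Aromatic rings are perceived and their bonds carry order 1.5
where a descriptor consumes bond orders. SMILES parsing and molecule
handling go through OpenBabel (via ChemmineR/ChemmineOB); everything
downstream of the connection table is implemented here and tested against
brute-force oracles (exhaustive path enumeration, min-plus all-pairs
distances, explicit double sums) on hundreds of random graphs.

The seven modelled descriptors:

* **X4A** — average Kier–Hall path connectivity of order 4: the sum over
  simple 5-vertex paths of `1/sqrt(prod(degrees))`, divided by the path
  count; 0 when no such path exists. Along a homologous PFCA series it
  decreases monotonically with chain length.
* **DECC** — mean absolute deviation of vertex eccentricities; 0 for
  perfectly symmetric graphs.
* **Eig12_AEA(bo)** — 12th-largest eigenvalue of the edge adjacency matrix
  whose diagonal holds bond orders. Eigenvalues are ordered descending by
  algebraic value; a molecule with fewer than k bonds returns 0 for the
  k-th eigenvalue, a deterministic padding convention. Only the diagonal is
  bond-order weighted; off-diagonal entries are 0/1 adjacency. The
  eigenvalue sum equals the bond-order trace, which the tests verify per
  molecule.
* **MATS8m / GATS8v** — Moran and Geary autocorrelations at topological
  lag 8. Pairs are counted as *ordered* pairs, with the pair count Δ
  entering as `1/Δ` (Moran) and `1/(2Δ)` (Geary); both return 0 when no
  pair sits at the lag or the weight variance vanishes. Weights (atomic
  mass, Bondi van der Waals volume) are scaled relative to carbon before
  centring; `scaled = FALSE` gives the raw variant.
* **PDI** — McGowan characteristic volume over total surface area. The
  McGowan volume uses the published elemental increments minus 6.56 per
  bond (hydrogens included), divided by 100. The surface area is a
  Labute-style pairwise sphere-capping approximation summed over heavy
  atoms, with one spherical cap subtracted per bonded neighbour — and one
  per implicit hydrogen. (Some reference implementations subtract a single
  hydrogen cap per heavy atom regardless of count; the per-hydrogen
  version is kept here as the chemically consistent choice, which shifts
  absolute SAtot values by a few percent but cancels in trends.)
* **QED** — weighted geometric mean of eight desirability values obtained
  by mapping molecular weight, Wildman–Crippen logP, H-bond acceptor and
  donor counts, topological polar surface area, rotatable bonds, aromatic
  rings and structural alerts through the published asymmetric double
  sigmoidal parameters. Unit weights are the default; the published mean-
  and max-information-gain weight sets are selectable. logP and TPSA come
  from OpenBabel; TPSA is full-Ertl, i.e. sulfur and phosphorus
  contributions included (some engines omit them by default — for sulfonic
  acids this shifts PSA by ~8 Å² and QED by a few hundredths, and the
  OpenBabel sulfonic-sulfur logP type differs from other engines by ~1 log
  unit; the cross-check tests carry correspondingly wider tolerances for
  sulfur compounds). H-bond acceptors are counted as N+O atoms and donors
  as hydrogens on N/O, which matches the reference implementation on the
  chemical families studied here but not on every heterocycle. The 116
  structural-alert patterns are evaluated with OpenBabel SMARTS; the two
  dot-disconnected patterns in the published list are repeats of one
  component and are evaluated as match-count thresholds.

## The classification model

`qsar_lda()` fits a two-class Fisher discriminant: direction
`Sw⁻¹(mean_L − mean_H)` with pooled within-class covariance, oriented so
larger scores mean lower affinity, intercept centring the decision
threshold at 0 (the midpoint of the class-mean scores). Wilks' λ and the
two-group F transform `F = ((1−λ)/λ)·((n−p−1)/p)` are reported alongside;
the generic variance-ratio F is a separate utility. A singular
within-class scatter raises an error suggesting descriptor pruning.

The frozen reference discriminant (`hsa_discriminant_model()`) carries the
published coefficients and intercept. The published work gives no numeric
potency threshold; the frozen model defaults to 0 and can re-centre the
threshold at the class-mean midpoint of any calibration data passed to it.
Scores at exactly the threshold classify as H, mirroring the inclusive
"at or below" convention of the EC50 class rule. The published fit
statistics (λ = 0.26, F(3,12) = 10.45) ride along as metadata: they were
computed on descriptor values from commercial software whose scaling is
not reproducible here, so the package never claims to recompute them —
applying the frozen coefficients to this package's descriptors yields a
structurally identical but numerically different model, which is why the
published per-compound predictions are reproduced from the published table
columns instead.

## The regression model and the small-dataset workflow

`qsar_mlr()` is ordinary least squares (rank-checked); `qsar_pls()` is
NIPALS PLS1 collapsed to an equivalent linear predictor, with autoscaled
descriptors by default (centred-only via `scale = FALSE`; the original
work does not state which convention its 3-latent-variable PLS used, so
both are exposed). At full latent rank PLS equals MLR to 1e-8, which the
tests assert.

The small-dataset workflow (`small_dataset_qsar()`) follows the
undivided-dataset recipe: (i) pretreatment — drop columns with variance
below 1e-4 and, from each pair with |r| > 0.95, the member less correlated
with the response; (ii) genetic-algorithm subset selection; (iii)
exhaustive double cross-validation; (iv) internal validation. The GA
hyperparameters are not stated in the original work; the defaults here are
standard small-pool settings (population 50, 100 generations, one-point
crossover 0.8, per-gene mutation 0.05, elitism 1, seeded), all
configurable. Regression fitness is leave-one-out Q² computed in closed
form from the OLS hat diagonal (PRESS), which the naive refit loop
`q2_loo()` must match exactly — an identity the tests check.
Classification fitness is −λ.

`double_cross_validate()` enumerates every validation subset of the
configured size (3 compounds by default, i.e. all C(n,3) splits; a seeded
subsample above `max_splits`), fits on the remainder and scores the
held-out triple. The selection rule — rank splits by held-out MAE, break
ties by higher Q² — is a package choice, as the original tool does not
document its rule; it is configurable. The consensus prediction of a
compound is the mean of its held-out predictions. Under study-shaped
synthetic conditions (n = 22, pool of 30 equicorrelated descriptors at
ρ = 0.3, 4 active descriptors, noise at 10% of the response SD) the
workflow recovers all four planted descriptors in ≥ 80% of 50 seeded
replicates — 49/50 at the default settings — which the acceptance test
asserts and `scripts/acceptance.R` re-measures.

## Validation metrics

All confusion-matrix metrics are computed from their printed definitions;
percent metrics live on the 0–100 scale, G-means is reported on the
percent scale (`100·sqrt(sens·spec)`), and metrics with zero denominators
are *undefined* (NA), never silently 0. The ROC sweep over unique scores
with trapezoidal area equals the Mann–Whitney statistic with tied scores
counted 1/2; an independent ROC package reproduces it to 1e-10 in the
tests. The AUROC printed for the original training set (0.97) needs the
unprinted per-compound discriminant scores and is therefore not a
reproduction target.

Regression metrics: R² against the training-mean reference, plain MAE, and
MAE95 (recomputed after discarding the ⌈5%⌉ largest absolute errors). The
published model-quality table's "MAE(95%)" value for the PLS model (0.205)
equals the *plain* MAE of the published predictions over all 22 compounds,
so the plain MAE is the reproduction target and both variants are
reported. Roy's rm² metrics min–max scale both vectors by the observed
range, then compare the squared correlation with and without forcing a
zero intercept; `rm²-bar ≤ r²` always, and small negative radicands from
floating point are clamped at zero.

The applicability domain is the standardization approach (the original
work names no algorithm): a query is outside when any descriptor
standardized by the training mean/SD exceeds 3 (configurable), with
per-descriptor diagnostics and zero-variance columns flagged.
Y-randomization refits on seeded response permutations and reports the
null distribution of R² (or λ).

## Read-across

The read-across scorer is generic: the proprietary chemotype fingerprints
used in the original study are not redistributable, so the default
fingerprint is a hashed linear-substructure key (paths up to 4 atoms,
canonical direction, 256 bits) with a pluggable interface — any binary
fingerprint or precomputed similarity works. The ACT score is the
similarity-weighted mean activity of the top-k (default 10) analogues: a
convex combination, invariant to rescaling all similarities, ties broken
by input order. Dose-valued activities are binarized by a user cutoff.
`genra_validate()` leave-one-out predicts each analogue from the rest and
reports the AUROC plus a seeded permutation p-value; a single-class
neighbourhood yields an *undefined* AUC, flagged as such — the original
study's "AUC = 0" for its predictions is exactly this degenerate
situation, and reporting it as undefined rather than 0 is a deliberate
divergence. The study-specific analogue sets and their scores come from an
external database and are not reproduction targets.

## Synthetic data: what it does and does not emulate

The generators produce (a) equicorrelated Gaussian descriptor matrices
with a planted linear response — matching the study's *shape* (≈22
compounds, pools of tens of descriptors, 3–4 active) — and (b) homologous
PFAS-like series (PFCA, PFSA, FTCA, FTSA, FTOH) as programmatic SMILES
with formula checks. They do not emulate the heavy-tailed, blockwise
correlation structure of real descriptor pools, nor any EC50 biophysics;
passing recovery tests therefore demonstrates that the selection machinery
works under the stated statistical conditions, not that four descriptors
suffice for real PFAS data. All generators are seed-deterministic and emit
truth records.

## Problem sizes and numerical choices

The test suite runs the descriptor oracles on 200+ random graphs of up to
~10 vertices, the recovery study at 50 replicates with the default GA and
a 100-split DCV cap, and the permutation-uniformity check at 200
neighbourhoods of 10 analogues with 49 permutations each; these sizes give
stable pass/fail behaviour at conventional tolerances (1e-12 for exact
graph quantities, 1e-8 for PLS/OLS identities, binomial slack for rates).
Degenerate inputs are contracts, not accidents: single atoms (DECC = 0,
connectivity order 0 well-defined), molecules with fewer bonds than the
requested eigenvalue rank (0), lags beyond the diameter (0), zero weight
variance (0), empty datasets (header-only round trip), and all-zero
fingerprints (an error, since similarity is undefined).

## Known limitations

* Descriptor values are not numerically interchangeable with the
  commercial engine used by the original study; the frozen equations are
  contracts, not a re-derivation. Out of scope by design: the remaining
  ~746 descriptors of that engine's pool, 3D descriptors, tautomer
  enumeration, charged species.
* Implicit-hydrogen assignment is valence-based over kekulized orders;
  exotic valence states and charged atoms are outside the supported scope.
* The aromatic-ring count and H-bond donor/acceptor conventions match the
  reference implementation on the families studied here (fluorinated
  acids, ethers, alcohols) but can differ on nitrogen heterocycles.
* Docking is carried as fixture data only (`correlate_docking()` is
  descriptive); no binding-site computation is attempted.
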