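---
title: "Modelling KIR3DL1–HLA class I binding from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling KIR3DL1–HLA class I binding from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirbind)
```

## The model in one paragraph

KIR3DL1 binding strength to an HLA class I allotype is modelled as a
linear function of the allotype's amino-acid sequence on the natural-log
scale. Each aligned α1/α2 sequence is expanded into binary
(position, residue) indicators over a region mask; the indicator matrix
is projected to K = 7 dimensions; and a single linear score
`f(x) = w·x + b` is trained against binary class labels (binder vs
non-binder, or high vs low binder, from clustering of the binding
matrix) and/or against the continuous normalized log binding itself.
Back-projecting `w` through the (linear) projection yields one beta per
(position, residue), so any aligned sequence — including allotypes never
measured — can be scored by summing betas. Log-additivity is the central
assumption: each residue contributes independently to log binding. Its
sharpest observable consequence is that reciprocal point mutations have
exactly opposite predicted effects, which is what the
mutation-reciprocity analysis quantifies against degranulation data.

## Data processing

**Replicate aggregation.** Bead-binding runs are averaged cellwise, then
each KIR row is divided by its own maximal response, giving raw values
in [0, 1]. Averaging before normalization is the default; the opposite
order, and a global (rather than per-KIR) maximum, are exposed as
options because the measurement protocol does not fix them. Untested
pairs stay `NA` and are never imputed.

**Log transform.** Zeros are replaced by 1% of the minimal positive
value of the matrix before taking logs, so all entries are finite. The
minimum is global — the replacement rule speaks of *a* minimal value —
with a per-row variant behind a flag. The log base is natural; any base
is an affine rescale absorbed by the linear models.

**Per-KIR normalization.** Each KIR row of the log matrix is mapped
affinely onto [0, 100]. This is the representation clustered and used as
the continuous training label; it makes KIR allotypes with different
dynamic ranges comparable.

## Binding classes

HLA allotypes are clustered by average linkage (UPGMA) on Euclidean
distances between their vectors of normalized binding over the KIR
panel. Cutting the tree into its top three clusters and ranking clusters
by mean binding yields the high / low / non-binder taxonomy; naming by
binding rank (not cluster size) matches how the classes are interpreted.
Binder-vs-non pools high and low; high-vs-low is defined only on
binders. Agglomeration ties are broken deterministically by R's `hclust`
(height, then merge index), so leaf orders reproduce exactly.

## Classifiers

Both classifiers minimize one convex objective over the shared score:

$$P(w, b) = \lambda \lVert w\rVert^2
  + \sum_i c_i \max(0, 1 - y_i f(x_i))
  + \mu \sum_j (f(x_j) - t_j)^2 .$$

* With `μ = 0` this is the soft-margin SVM in the libsvm
  parameterization (`λ = 1/2`), with box constraint C = 0.01 and
  "balanced" per-class costs `c_i = C·n / (2·n_class(y_i))`. An
  equivalent per-sample-averaged parameterization (`λ = 1/(2nC)` with
  the hinge term averaged) describes the same convex family up to an
  overall scale of the objective; we use the unnormalized form.
* MLVO couples partially observed binary and continuous labels through
  the shared score with a squared-error continuous loss (`μ = 1` by
  default, ε-insensitive loss deliberately omitted: the squared loss
  satisfies the two defining properties — exact reduction to the SVM at
  `μ = 0`, and a monotone link between predicted class and predicted
  affinity — with one fewer tuning constant). The original formulation
  this generalizes is not reproduced in the source study, so the
  objective above *is* this package's concrete definition.

**Optimization.** No SVM library is assumed. The objective is solved by
BFGS on a Huberized hinge with a smoothing continuation
(γ = 10⁻¹ → 10⁻⁶); the smoothing bias in the objective is bounded by
γ/2 per active sample, far below the 10⁻⁶ agreement demanded of the
solver. An independent oracle — accelerated projected gradient on the
SVM *dual* box-QP with exact intercept line search
(`svm_dual_reference()`) — validates the primal solver in the test
suite; the two routes agree to machine precision on small problems.
Polynomial kernels are supported through an explicit feature map for
comparison runs only; they admit no per-feature betas and
`back_project()` refuses them, as it does MCA projections (the
row-profile normalization of correspondence analysis is not linear in
the indicators).

## Dimensionality reduction

PCA is the default (it outperformed MCA in the source study); centering
only, no unit-variance scaling, because indicator columns are already
commensurate. K = 7 reflects the drop in variance contribution beyond
the seventh eigenvector of the real panel; it is a plain parameter.
Component signs follow a fixed convention (largest-magnitude loading
positive) so serialized models reload bit-identically. Following the
study protocol the projection is fit once on all one-hot vectors;
`per_fold_projection = TRUE` refits it inside each training fold for a
strictly leakage-free evaluation — with the tiny feature spaces involved
the two differ negligibly, and both are reported in the fold table's
metadata.

## Cross-validation

Folds are drawn at the allele level (default 5, i.e. 80/20), stratified
by class when possible, and the same fold assignment is reused for every
KIR task, so an allele is never trained on in one task and tested in
another. "Average over five cross-validations" is read as the five folds
of one split; a `repeats` argument covers the repeated-CV reading. AUC
is the rank-based Mann–Whitney statistic with midrank ties.

## Enrichment statistics

The two-sample logo tests, for every (position, residue) pair observed
in either group, whether the residue frequency differs between groups.
The default is the exact *conditional* binomial test: given the pooled
count `c_A + c_B`, `c_A` is binomial with success probability
`n_A/(n_A + n_B)` under the null. This choice — among the variants a
two-sample binomial comparison admits — is exactly valid (so Bonferroni
control at α is guaranteed, which the test suite verifies empirically)
and exactly symmetric under swapping the groups, making the
effect-negation invariant hold to the bit. The opposite-group-frequency
variant is available as `null = "opposite"`. Effects are frequency
differences in [−1, 1]; rendered letter heights are proportional to
|effect|. Unknown (`*`) residues are excluded from counts.

## Population coverage

Frequencies are renormalized to sum 1 per locus before coverage sums
(untyped remainders are reported but not counted against coverage;
`renormalize = FALSE` flips this). The joint KIR×HLA partition and the
full-genotype coverage Π(covₗ)² assume independence / Hardy–Weinberg, as
the source analysis states; linkage disequilibrium between loci is out
of scope. The KIR factor is optional in the genotype calculation, which
is HLA-only by default.

## Prediction bundle

`build_bundle()` trains 2 + n_KIR models (11 on the nine-tetramer
panel): `overall_binder` and `high_vs_low` use the clustering-derived
binary labels with the mean normalized log binding as the continuous
label; per-allotype models keep the *global* three-cluster binder cut as
their binary label (per-allotype thresholds are not specified by the
source; the global cut is the default) and use that allotype's
normalized column as the continuous label. Prediction ignores unknown
(`*`) residues (they contribute zero and are counted) and residues never
seen in training at a position. Percentiles against the reference panel
use the strictly-below fraction with midpoint ties — the source only
says "relative to the full list"; note the midpoint convention places
even the top-scoring reference allele at 100·(n−½)/n rather than exactly
100. Heterozygous KIR3DL1 genotypes are scored as the arithmetic mean of
the per-allotype raw scores. Reference scores and exported beta CSVs are
serialized at full double precision so round-trips are bit-exact.

## The synthetic world

The generator emulates the structure the pipeline relies on, at the
scale of the real panel (97 HLA × 9 KIR, 3 replicate runs):

* a Bw4/Bw6-like **two-state motif** segregating jointly at positions
  77/80/83 (carrier probability 0.6, linkage-break probability 0.05),
  each motif residue contributing +2 on the natural-log binding scale —
  this makes the noiseless log binding bimodal, separating binders from
  non-binders;
* **balanced binary variation** at the A-pocket sites 62/65/66 with
  mean-zero, evenly spaced residue effects in [−1, +1] — grading binders
  into high and low with an identifiable contrast at every site (two
  residues with *equal* effects would be observationally invisible,
  since their indicators are complementary);
* **low-frequency background variants** (total minor frequency 0.15) at
  26 further positions spread over helices and loops, with zero effect;
* Gaussian noise, σ = 0.3, added per replicate on the log scale; per-KIR
  beta vectors are a common base scaled by U(0.8, 1.2).

Class labels are thresholded on the noiseless score: binder/non at 3.0
(inside the motif gap) and high/low at a midpoint between distinct
binder score values nearest their median, so all three classes are
non-empty by construction and determined by sequence alone.

**What this world does not emulate.** Real HLA panels carry pervasive
linkage disequilibrium: lineage structure correlates positions across
the whole domain. We keep positions independent outside the motif trio,
deliberately — under realistic panel-wide LD, per-position attribution
is mathematically non-unique (any position's lineage pattern is a linear
combination of the others'), and the source study itself notes
enrichment extending along the helix "which may be due to linkage
disequilibrium". A green end-to-end test therefore establishes that the
pipeline recovers planted signal *when it is identifiable*; it does not
establish that per-position contribution maps on real, LD-structured
data isolate causal residues. Peptide-repertoire effects, assay
batch/bead artefacts, and realistic haplotype frequencies are likewise
not simulated.

## Numerical choices and degenerate inputs

* Solver tolerance: BFGS `reltol` 10⁻¹²; convexity is checked in tests
  by restart agreement to 10⁻⁶.
* `aggregate_replicates` refuses all-zero KIR rows; `log_transform`
  refuses all-zero matrices; `minmax_per_kir` refuses constant rows;
  `label_three_groups` refuses panels with fewer than three distinct
  binding vectors (no three groups exist at distinct heights).
* K exceeding the matrix rank is clipped with a warning.
* Gap characters in input alignments map to `*` and are treated as
  unknown everywhere (encoding, logos, prediction).
* Fold RNG is isolated (`with_seed`) so package calls never perturb the
  caller's RNG stream.

## Known limitations

Scores are on the normalized log-binding scale, not physical affinity
units. The linear model cannot express residue–residue interactions or
peptide dependence; the source study reports nonlinear baselines
(XGBoost, neural networks) as inferior on this data size, and they are
intentionally out of scope here. MCA back-projection is refused rather
than approximated. The motif lookup at positions 80/83 implements the
classical epitope table (N80/G83 → C1, K80/G83 → C2, I/T80 with R83 →
Bw4); the rare-combination cutoff is a user parameter because no
frequency threshold is canonical.
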