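# kirbind

Sequence-based prediction of KIR3DL1 binding to HLA class I allotypes.

## The problem

KIR3DL1 is a highly polymorphic inhibitory receptor on natural killer
cells that recognizes HLA class I molecules carrying the Bw4 motif
(residues 77–83 of the α1 helix). Clinical studies usually reduce this
interaction to a binary rule — Bw4 present/absent, or isoleucine vs
threonine at position 80 — but bead-binding data show a continuum shaped
by residues well beyond the motif, and by the KIR3DL1 allotype itself.
With >130 KIR3DL1 protein variants and >15,000 HLA class I allotypes,
most receptor–ligand pairs will never be measured directly.

`kirbind` implements the full modelling pipeline for this problem, for
immunogeneticists who have (or simulate) a KIR×HLA binding matrix and
aligned α1/α2 domain sequences:

* **Encoding** — aligned allotype sequences become binary
  (position, residue) indicators ("an HLA starting `RA` has 1 at `R1` and
  `A2`"), restricted to structurally motivated region masks: the full
  domain, the six Bw4 positions `{76,77,80,81,82,83}`, the α-helices
  `57–85 ∪ 141–175`, or the domain minus connecting loops. Invariant
  positions are dropped.
* **Binding data** — replicate bead-binding runs are averaged and
  max-normalized per KIR; zeros are replaced by 1% of the minimal
  positive value before the natural log; each KIR row is min-max scaled
  to [0, 100].
* **Binding classes** — average-linkage (UPGMA) clustering of the
  normalized matrix; the top three HLA clusters, ranked by mean binding,
  are the high / low / non-binder taxonomy, with Mann–Whitney, ANOVA and
  Tukey group statistics.
* **Models** — PCA (or MCA) projection to K = 7 dimensions, then either a
  soft-margin linear SVM (box constraint C = 0.01, balanced class
  weights) or MLVO, which minimizes one convex objective over a shared
  linear score f(x) = w·x + b:

  λ‖w‖² + Σᵢ cᵢ·hinge(yᵢ f(xᵢ)) + μ Σⱼ (f(xⱼ) − tⱼ)²

  coupling binary class labels yᵢ and continuous log-binding labels tⱼ
  (either may be partially observed). Weights are back-projected to
  per-feature betas, so any aligned sequence can be scored by summing
  betas — the basis of the deployable 11-model bundle (overall binder,
  high-vs-low, and one model per KIR3DL1 allotype).
* **Evaluation** — allele-level 5-fold cross-validation (an allele is in
  the same fold for every KIR task), rank-based AUC, two-way ANOVA
  comparisons of masks × loci.
* **Enrichment** — two-sample logo statistics with exact binomial tests
  and Bonferroni control; per-position contribution maps (Σ|β|, min-max
  normalized).
* **Coverage** — allele-frequency population coverage: per-locus sums,
  joint KIR×HLA partition, and full-genotype coverage Π cov² under
  independence.
* **Synthetic data** — a first-class generator planting a log-linear
  binding model (Bw4-like linked motif at 77/80/83, strength contrasts at
  62/65/66, Gaussian log-scale noise) so the whole pipeline is testable
  without external data.

## Worked example

```r
library(kirbind)

# a synthetic study-scale world: 97 HLA allotypes x 9 KIR3DL1 tetramers
panel <- generate_panel(n_alleles = 97, seed = 1)
pm    <- planted_model(panel, seed = 1)
gen   <- generate_binding(panel, pm, n_replicates = 3, seed = 1)

# replicate aggregation -> log -> per-KIR [0,100] normalization
bm   <- aggregate_replicates(gen$runs)
norm <- minmax_per_kir(log_transform(bm))

# three binding classes from the clustering
labels <- label_three_groups(hierarchical_cluster(norm, "hla"), norm)
#> binding_class_labels: high=31 low=35 non=31

# held-out performance of the helices/MLVO configuration
cv <- run_cv_experiment(panel, bm, mask = "helices", method = "mlvo", seed = 1)
summarize_auc(cv)
#>         mask  loci method           task      mean          sd
#> mean helices A/B/C   mlvo overall_binder 0.9974359 0.005733508

# the deployable bundle and a prediction for one sequence
bundle <- build_bundle(panel, bm, mask = "helices")
#> model_bundle: 11 models (mlvo, mask 'helices', K = 7), 63 features
head(predict_binding(bundle, panel$sequence[5]), 4)
#>         model_id score percentile
#> 1 overall_binder  55.4       46.9
#> 2    high_vs_low  55.4       45.9
#> 3    KIR3DL1*001  55.8       46.9
#> 4    KIR3DL1*002  54.5       46.9

# which positions drive the overall binder/non-binder model?
round(sort(position_contributions(bundle$models$overall_binder),
           decreasing = TRUE)[1:6], 2)
#>   83   80   77   66   62   65
#> 1.00 0.91 0.90 0.57 0.52 0.43
```

The mean held-out AUC of ~1 says the planted log-linear signal is fully
recovered; the contribution map puts the planted Bw4-motif positions
(77/80/83) and the A-pocket strength positions (62/65/66) at the top, as
expected. Mutating position 80 away from the motif residue drops every
model's score by a large, exactly antisymmetric amount
(`mutation_delta()` at position 80 gives ≈ −18.7 here on the 0–100
normalized log-binding scale of the scores).

Scores are on the scale of the continuous training label (normalized log
binding, 0–100); `percentile` places the query among the bundle's
reference panel.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "kirbind.R", package = "kirbind"))')
Rscript $CLI simulate --n-hla 97 --n-kir 9 --seed 7 --out fixtures/
Rscript $CLI encode   --fasta fixtures/panel.fasta --mask helices --out enc.tsv
Rscript $CLI cluster  --matrix norm.tsv --axis hla --k 3 --out labels.tsv
Rscript $CLI train    --runs fixtures/runs.tsv --fasta fixtures/panel.fasta --out models.csv
Rscript $CLI predict  --models models.csv --seq <AA-string> --out report.json
```

See `vignettes/kirbind-methods.Rmd` for the model assumptions, parameter
choices, and what the synthetic world does and does not emulate.
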