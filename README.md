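# netseed

PPI-network-guided case-control exome association analysis in R.

Exome scans on modest cohorts are underpowered for the small effect
sizes typical of complex disease. `netseed` implements the targeted
alternative: take a curated set of seed genes with established or
suggested disease involvement, expand it through a background
protein-protein interaction (PPI) network to every direct interactor,
and restrict the association analysis to variants in or within 20 kbp
of the expanded gene set. The package covers the full workflow:

* **Seed network expansion** — seeds plus first PPI neighbours
  (`expand_seed_network()`), category-annotated subnetworks and their
  largest connected component.
* **Variant filtering** — gene-set ± flank windows over BED intervals
  (`filter_variants_to_geneset()`), cross-cohort variant intersection.
* **Single-variant association (SVA)** — per-variant logistic
  regression `status ~ dosage + PC1..PC10 (+ age)`
  (`logistic_sva()`), allele counts/frequencies, genomic inflation
  factor λ = median(χ²)/median(χ²₁), threshold-scan candidate
  selection ("smallest cutoff yielding more than ten variants"),
  Bonferroni correction.
* **Polygenic risk score** — selection by discovery p-value,
  cross-dataset allele-frequency concordance and LD-block pruning;
  per-sample score `Σⱼ dosageᵢⱼ · ln(ORⱼ)`; replication association
  with FDR/Bonferroni-adjusted per-term report (`compute_prs()`,
  `prs_association()`).
* **Prediction models** — class-balanced random forest on variant
  dosages (MDI importances) and logistic classifier on the PRS, with
  confusion-matrix metrics, balanced accuracy and DeLong AUC CIs.
* **Topology null model** — degree-binned label permutation (30
  equal-sized degree bins, swaps within bins without replacement) with
  one-sided add-one Monte Carlo p-values for average path length
  (lower tail) and average clustering coefficient (upper tail)
  (`null_topology_distribution()`).
* **Synthetic data** — scale-free interactomes with planted dense seed
  modules, truth-labelled gene maps, and stratified (Balding-Nichols)
  case-control genotype panels under an additive logistic disease
  model, so every stage is testable without external data
  (`simulate_interactome()`, `simulate_gene_map()`,
  `simulate_cohort()`, `simulate_study_bundle()`).

See `vignettes/network-guided-exome-association.Rmd` for the methods
and design rationale.

## Worked example

Simulate a complete study (interactome + gene map + discovery and
replication cohorts, with two causal variants of OR 2.2 and 1.64
planted in seed-module genes) and run the whole pipeline from one
config:

```r
library(netseed)

bundle <- simulate_study_bundle("demo", rng_seed = 1)
cfg <- list(
  seed = 1,
  inputs = list(
    edges = bundle$paths$edges, seeds = bundle$paths$seeds,
    genes_bed = bundle$paths$genes_bed,
    discovery_vcf = bundle$paths$discovery_vcf,
    discovery_pheno = bundle$paths$discovery_pheno,
    replication_vcf = bundle$paths$replication_vcf,
    replication_pheno = bundle$paths$replication_pheno),
  analysis = list(selection_min_variants = 3),
  network_test = list(n_permutations = 1000))
report <- run_pipeline(cfg)
```

which logs each stage:

```
[expand] n_seeds=20 n_members=108
[filter] variants_in=150 variants_kept=69
[sva_discovery] n_tested=69 lambda=1.07069961902475 threshold=0.005 n_candidates=4
[sva_replication] n_tested=4 bonferroni_cutoff=0.0125 n_significant=2
[prs] n_variants=3 score_mean=-0.044 prs_or=1.9699 prs_p=1.059e-05
[predict] variant_bal_acc=0.597 prs_bal_acc=0.597
[topology] subnet_size=20 p_apl_lower=0.00699300699300699 p_acc_upper=0.00799200799200799
```

Reading the run: 150 simulated variants are reduced to 69 inside the
seed network ± 20 kbp; the discovery scan is well calibrated
(λ ≈ 1.07); the threshold scan settles on p < 0.005 with 4
candidates, 2 of which survive the replication Bonferroni cutoff
(0.05/4); 3 variants pass PRS selection, and the resulting score is
strongly associated with disease in the replication panel:

```r
report$prs$association[, c("term", "or", "ci_low", "ci_high", "p", "fdr", "bonf")]
#>   term   or ci_low ci_high        p      fdr     bonf
#> 1  prs 1.97  1.457    2.66 1.06e-05 3.18e-05 3.18e-05
#> 2  age 1.01  0.996    1.03 1.46e-01 2.20e-01 4.39e-01
#> 3  PC1 0.94  0.781    1.13 5.11e-01 5.11e-01 1.00e+00
```

(an OR of 1.97 per score unit; 40% of cases versus 21% of controls
fall in the upper score quartile). The planted seed module is also
detected by the topology test — shorter paths and higher clustering
than degree-matched chance:

```r
report$topology
#> Label-permutation topology null (N = 1000, 30 degree bins)
#>   observed: APL 1.1789, ACC 0.8074 (LCC 20)
#>   Monte Carlo p: APL lower 0.006993, ACC upper 0.007992
```

Every stage is also callable directly (`logistic_sva()`,
`select_candidate_threshold()`, `select_prs_variants()`,
`null_topology_distribution()`, ...) on your own VCF/TSV/BED inputs;
`run_pipeline(cfg, out_dir = "results/")` additionally writes
per-stage TSV/JSON artifacts and a deterministic run report.

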