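---
title: "Network-guided exome association analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided exome association analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Individual risk variants for complex neurodegenerative disease have
small effects, so an exome-wide scan on a modest case-control cohort is
underpowered. One remedy is biological targeting: start from a curated
set of genes with established or suggested disease involvement
("seed" genes), expand it to every protein with a direct
protein-protein interaction (PPI) to a seed, and restrict the
association scan to variants in or near the expanded gene set. This
package implements that strategy end to end, together with the
topology test used to ask whether the resulting candidate subnetwork
is more tightly organised than chance would produce.

# The genetics arm

## Gene-set construction and variant filtering

`expand_seed_network()` takes the background interactome (an
undirected simple graph over protein/gene identifiers) and returns
the seeds plus all first neighbours. Seeds without any interaction
record are retained as isolated members: dropping them silently would
distort the seed bookkeeping, and some curated disease proteins (for
example, mitochondrially encoded subunits) genuinely lack PPI records.

`filter_variants_to_geneset()` keeps a variant when its position lies
within `[start - flank, end + flank]` of at least one member gene.
The default flank is 20 kbp. Both window ends are **inclusive**: a
variant exactly 20,000 bp from a gene edge is kept. The convention had
to be fixed somewhere for the filter to be testable against generated
truth labels; inclusivity matches how 0-based half-open BED intervals
convert exactly to 1-based inclusive coordinates. The flank is applied
symmetrically on both sides regardless of strand — the window is an
"upstream or downstream" window, not a promoter model. Gene (BED)
boundaries are used rather than transcript boundaries.

## Single-variant association

`logistic_sva()` fits, per variant, maximum-likelihood logistic
regression of case status on allele dosage with the first ten
principal components of the genotype matrix as ancestry covariates
(age is added in the replication setting). The per-allele odds ratio
is `exp` of the dosage coefficient and the p-value is the Wald test on
that coefficient; a likelihood-ratio alternative is available via
`test = "lrt"`. Missing genotypes are handled complete-case per
variant, which is also the denominator convention for the reported
allele frequencies (`allele_stats()`). Monomorphic variants are
skipped with a recorded reason; non-convergence and suspected complete
separation (|beta| > 10 or SE > 50) are flagged rather than dropped.
Firth-type penalization is deliberately **not** applied — flagging
mirrors the behaviour of the standard association toolchain, and
penalization is an extension point rather than a silent default.

Calibration is monitored with the genomic inflation factor
(`genomic_lambda()`): the median of the chi-square-transformed
p-values divided by the median of the chi-square(1) distribution. The
reference median is computed from `qchisq(0.5, 1)` at full precision,
not from the rounded 0.455 constant, so that a vector of p-values all
equal to 0.5 gives exactly 1.

## Candidate selection and multiple testing

`select_candidate_threshold()` scans a descending ladder of p-value
thresholds (default 0.05, 0.005, 0.0005, 0.00005) and returns the
*smallest* threshold that still yields at least `min_variants`
candidates (default 11, "more than ten"): tight enough to keep the
false-positive rate low, loose enough to leave a workable candidate
set. If no threshold qualifies the largest is used with a warning, so
a pipeline run on weak data degrades loudly rather than dying.
Replication results are judged against a Bonferroni cutoff
(`bonferroni_threshold()`, alpha / number of replicated candidates).

## Polygenic risk score

`select_prs_variants()` applies four rules in order: discovery
p-value below the selected cutoff; not on an exclusion list (variants
that failed orthogonal validation); case allele frequency similar
between discovery and replication; one representative per declared
linkage-disequilibrium block. "Similar" is quantified as the relative
difference to the discovery case frequency,
`|f_disc - f_rep| / f_disc <= tolerance`, with default tolerance 0.5.
The tolerance is configurable; the default cleanly separates
candidates whose replication frequency collapses (relative difference
near 1) from those that replicate, and a variant protective in one
dataset and risk-increasing in the other also fails it. LD blocks are
*declared* inputs (the package does not estimate LD; the original
analysis used an external web tool), and the block representative can
be configured or defaults to the smallest discovery p.

`compute_prs()` scores each sample as the dosage-weighted sum of
**natural** log odds ratios from the discovery scan. The choice of
log base is forced by arithmetic: one copy of a variant with OR 2.208
plus two copies of a variant with OR 1.637 gives
`ln(2.208) + 2 ln(1.637) = 1.78`, the attainable score maximum for
those weights, and that is the value the score range must reproduce.
Missing dosages contribute zero and flag the sample — deterministic
and conservative, and scores stay comparable across samples.
`prs_quartile_summary()` cuts at the 75th percentile of the combined
(cases + controls) score distribution, counting samples strictly
above the cut; whether the original cut was combined or control-only
is not stated anywhere we could check, so the combined convention is
implemented and documented. `prs_association()` refits the logistic
model with the PRS, age and PCs, and reports per-term odds ratios,
Wald 95% intervals, and Benjamini-Hochberg plus Bonferroni adjusted
p-values across the reported terms.

## Prediction models

Two classifiers mirror the published evaluation: a random forest on
the selected variant dosages (`fit_variant_model()`) and a univariate
logistic model on the PRS (`fit_prs_model()`). Both are
class-balanced — the forest by stratified down-sampling to the
minority class size per tree, the logistic model by
inverse-class-frequency observation weights. Balancing is essential
to reproduce the published operating regime, in which roughly a
quarter of controls are called cases despite a 1:137 case-control
imbalance; an unbalanced classifier on such data degenerates to
"always control". Feature importance is mean decrease in impurity
(accumulated Gini reduction, normalized to sum to 1). Evaluation
(`confusion_metrics()`, `auc_with_ci()`) reports sensitivity,
specificity, accuracy, balanced accuracy (the arithmetic mean of
sensitivity and specificity), and the Mann-Whitney AUC with a DeLong
95% interval. Defaults: 500 trees, unlimited depth, probability
threshold 0.5 on the balanced probability — the exact published
hyperparameters are unknown, so the printed confusion matrix is the
only exactly reproducible surface, and the package treats it that way.

# The topology arm

## Null model

The question "is the candidate subnetwork unusually compact?" is
answered against a degree-preserving null. `bin_by_degree()` sorts
all background nodes by (degree, identifier) and cuts the ranking
into 30 equal-sized bins (remainder nodes go one-per-bin to the
lowest-degree bins; the identifier tie-break makes binning
deterministic). `permute_labels()` replaces each subnetwork node by a
uniform draw from its own bin, without replacement within a bin, so
every permuted set preserves the per-bin multiset exactly — an
invariant the tests assert literally. Nodes may map to themselves.

`null_topology_distribution()` repeats this (default 10,000 times),
takes the induced subgraph of each relabelled set, and computes the
average path length (APL) and average clustering coefficient (ACC) of
its largest connected component. One-sided Monte Carlo p-values use
the add-one estimator `p = (1 + k) / (1 + N)` with ties counted as
extreme, so p is never 0 and degenerates gracefully to 1 when every
bin is a singleton. Test directions are fixed to APL lower tail and
ACC upper tail — a disease module is hypothesised to be *shorter* and
*more clustered* than degree-matched chance — but both are
configurable through `monte_carlo_p()`.

Metric conventions, fixed because null and observed values must be
computed identically: APL is the mean geodesic distance over
unordered node pairs of the LCC; ACC is the mean local clustering
coefficient over all LCC nodes with degree-below-2 nodes contributing
0 (not excluded). Permuted subgraphs whose LCC has fewer than 3 nodes
carry no path-length information; they are excluded from the APL null
and counted, so the effective sample size is always visible.

## A power caveat at desk scale

The degree-binned null has a circularity failure mode when the
background is small: planting a module raises its members' degrees,
which concentrates them in the top degree bins, and the permutation
then largely swaps module members among themselves, dragging the null
towards the observed value. On a 500-node background with 30 bins
(about 17 nodes per bin) this noticeably blunts the test against
weakly filled modules, so the packaged power checks plant a *dense*
module (within-module edge probability 0.8); the acceptance script
reports the detection rate it actually achieves. On an interactome of
realistic size (tens of thousands of nodes, hundreds per bin) the
subnetwork is a negligible fraction of every bin and the issue
vanishes — but it is worth knowing about whenever this test is
applied to small graphs.

# The synthetic-data module

`simulate_interactome()` grows a preferential-attachment background
(heavy-tailed degrees, like real interactomes) and plants a dense
module whose members double as the seed gene list, making the
topology test's alternative hypothesis realizable.
`simulate_gene_map()` lays out non-overlapping genes and places
variants in gene bodies, flanks, or outside, recording the truth
category so the window filter can be checked exactly, including both
inclusive boundaries. `simulate_cohort()` draws unlinked diploid
genotypes for two subpopulations whose frequencies drift from the
shared MAF by the Balding-Nichols model
(`Beta(p(1-F)/F, (1-p)(1-F)/F)`); disease status follows an additive
log-odds model with the intercept solved numerically (on a reference
pool of 20,000 genotype draws) so the population prevalence matches
the target, and cases are collected by rejection sampling with a
10^7-draw cap that raises a diagnostic error when the prevalence is
unattainable. All three generators are bit-reproducible under a
fixed seed.

One deliberate deviation from a literal reading of the design: the
top-10 PC covariates are computed from the mean-imputed, centred
dosage matrix *only when the panel is at least 25 variants wide*. On
a one- or two-variant panel the leading components are exact linear
combinations of the tested dosages — "adjusting" for them destroys
the association the simulation exists to produce — so narrow panels
carry zero PC columns instead (equivalent to omitting the
covariates). Ancestry PCs computed from a handful of variants are not
ancestry estimates in any meaningful sense.

What the generator does **not** emulate: linkage disequilibrium
(variants are independent; LD blocks enter the analysis as declared
configuration, exactly as in the real pipeline), realistic
site-frequency spectra, case-control matching on age and sex
(cases and controls are drawn from the same population), sequencing
depth or genotyping error. Passing tests therefore demonstrate the
statistical machinery is correct under the stated model, not that the
pipeline is robust to those real-data complications.

# Problem sizes and numerical choices

The packaged checks use desk-scale versions of the study conditions,
chosen once: interactomes of 300-500 nodes with 15-20 node modules;
calibration panels of 500 null variants at 500 cases / 500 controls
(the acceptance script uses 2000 null variants for a steadier
median-based lambda); effect-size recovery at 2000/2000 samples and
OR 2.2 at MAF 0.05; PRS power at 300 cases / 3000 controls with ORs
2.2 and 1.64; topology nulls at 1000 permutations. Full-scale
settings (10,000 permutations, interactomes with tens of thousands of
nodes) run unchanged, only slower.

Other fixed numerical conventions: LCC ties are broken toward the
component containing the lexicographically smallest node identifier;
degree-bin ties by identifier sort; crude odds ratios apply the
Haldane-Anscombe +0.5 correction (flagged) when a cell is zero;
zero-count replication variants are reported with flagged, undefined
odds ratios rather than being silently removed; variant keys
normalize away `chr` prefixes and expand multi-allelic records to
biallelic keys, but allele strand flips are *not* reconciled —
cohorts are assumed to share a reference strand, and mismatches
surface as exclusion counts.

# Known limitations

* The package operates on opaque identifiers; it performs no
  UniProt-to-gene-symbol mapping, no liftover, and no consequence
  annotation.
* Interaction confidence is not filtered; the association test is the
  evidence filter.
* The published subnetwork member counts and topology p-values from
  the original interactome snapshot cannot be recomputed without that
  exact database version; the package reproduces the procedures and
  their printed arithmetic, and validates the stochastic machinery on
  synthetic data at the effect sizes the original study reported.
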