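---
title: "Stage-wise domestication genomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise domestication genomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bogdiv analyses SNP diversity panels that span successive domestication and
breeding stages — the motivating system is the American cranberry
(*Vaccinium macrocarpon*), a crop domesticated within the last two centuries
whose panel divides into wild clones (WLD), first-generation native
selections (NS), first-generation hybrid cultivars (CLT1) and advanced
selections (CLT2). This vignette is the package's own account of the
statistics it implements, the choices behind them, and what its synthetic
validation does and does not establish.

## Marker filtering

Genotypes enter as biallelic SNP dosages (0/1/2 alternate-allele copies,
`NA` for missing calls). `filter_markers()` removes markers with more than
30% missing calls and panel-wide minor allele frequency below 0.05 — the
standard GBS thresholds. Missingness is filtered first and MAF is computed
on non-missing calls only; the order affects how removals are attributed in
the `FilterReport`, not which markers survive. Duplicate (chromosome,
position) records are collapsed to the first occurrence at VCF read time,
since a marker set "uniquely assigned to a genomic position" admits more
than one uniqueness rule and first-wins is reproducible. Missing data are
an explicit `NA`, never a sentinel dosage; downstream statistics use
pairwise-complete observations, and only PCA, Ward clustering and kinship
mean-impute (imputation choices are stated per method below).

## Diversity summaries

Per subgroup and marker, `subgroup_freqs()` reports the alternate-allele
frequency *p* on non-missing calls, MAF = min(*p*, 1 − *p*), and expected
heterozygosity He = 2*p*(1 − *p*), the diversity measure used throughout.
A marker with no calls in a subgroup is undefined there, not monomorphic.
`polymorphic_fraction()` counts markers with 0 < *p* < 1 and reports two
denominators — the full filtered marker set (the convention behind printed
panel percentages) and the subgroup-defined markers — because the right
denominator is genuinely ambiguous. `joint_maf()` bins two subgroups' MAFs
into a B×B contingency table (default width 0.05, ten bins over [0, 0.5],
half-open with the last bin closed); its diagonal mass is the scalar used
to compare stages: subgroups connected by one breeding step share more
diagonal mass than stages at opposite ends of the process.

## F_ST scans and permutation thresholds

Per-locus differentiation uses the Weir–Cockerham (1984) two-population
theta-hat from the variance components *a* (among populations), *b* (among
individuals within populations) and *c* (within individuals), computed from
per-group sample size, allele frequency and observed heterozygosity.
Negative estimates are retained. A locus is undefined when both groups are
fixed for the same allele or a group has fewer than two genotyped
individuals. Nei's G_ST is available as a sensitivity switch
(`estimator = "nei"`), since printed single-SNP maxima from other tools can
depend on this unstated choice.

Two genome-wide summaries are reported. The arithmetic mean of per-locus
theta-hat mirrors how scan means are usually quoted, but averaging
per-locus ratio estimators carries a downward Jensen bias of roughly 10% at
these sample sizes; the ratio-of-sums estimator sum(*a*) / sum(*a*+*b*+*c*)
is consistent and is what the package's own calibration checks use. Both
are in every `fst_scan` object and summary file.

Significance thresholds come from permutation: each of R iterations (1000
by default) shuffles the pooled membership labels of the two subgroups,
preserving group sizes, and recomputes per-locus theta-hat. By default all
defined permuted values across all iterations are pooled into one empirical
null and the 95th percentile is the threshold. Pooling matches thresholds
that scale inversely with group size (small subgroups produce noisy
per-locus nulls and high thresholds); a family-wise variant that keeps each
iteration's genome-wide maximum is available via `mode =
"per_iteration_max"` and is strictly more conservative. Thresholds are
deterministic given the seed.

## Reduction of diversity (ROD)

ROD at a locus is 1 − He_derived / He_ancestral, undefined where the
ancestral subgroup is monomorphic, negative where the derived subgroup is
the more diverse (never clamped). The four breeding steps of the cranberry
panel are built in: step 1 WLD→NS, step 2 NS→CLT1, step 3a CLT1→CLT2, step
3b NS→CLT2. `rod_scan()` reports the four headline bins (ROD = 0,
0 < ROD ≤ 0.2, 0.8 ≤ ROD < 1, ROD = 1) plus the middle band, negatives and
undefined loci, so the seven categories partition all markers. ROD = 1 is
decided exactly — derived subgroup fixed at an ancestrally polymorphic
locus, an integer-count condition — not by floating-point comparison;
ROD = 0 uses a 1e-12 tolerance on the He ratio.

## Linkage disequilibrium decay

LD between two loci is the squared Pearson correlation of dosage vectors
(composite, unphased r²) on pairwise-complete observations, requiring at
least three complete pairs and both loci polymorphic on the complete
subset. `ld_decay()` evaluates all intra-chromosomal pairs up to 500 kb,
bins distances into non-overlapping 10-kb windows, and pools pairs across
chromosomes (per-chromosome curves are also returned; pooling is the
default because bin counts per chromosome are small on sparse maps). The
half-decay distance is the upper edge of the first bin whose mean r² is at
most half the first bin's mean — the observed maximum, with no asymptote
subtraction. When no bin ever reaches that level the curve has no decay
structure (unlinked loci fluctuate around the 1/n noise floor) and the
first bin's upper edge is reported: LD is at its floor from the start.

## Population structure

PCA codes dosages to −1/0/+1, mean-imputes missing calls per marker,
centres columns and takes the SVD; explained-variance fractions are
eigenvalues over their sum. Ward clustering (`hclust`, `ward.D2`, Euclidean
distances on the same coded matrix) supplies the reticulation view and a
newick export.

Ancestry estimation factorises the individual allele-frequency matrix
P = dosage/2 as Q·F with Q row-stochastic (n×K ancestry proportions) and F
in [0,1] (K×L ancestral frequencies), missing entries excluded from the
loss rather than imputed. The solver alternates projected-gradient blocks —
simplex projection per Q row, box clipping for F — with backtracking line
search, so the masked least-squares training loss is non-increasing by
construction (`loss_path` records it). This is the same least-squares
family as sparse-NMF ancestry tools; as there, the binomial cross-entropy
on a held-out mask of observed entries (5% by default) is the
model-selection criterion, not the training objective. Per replicate a
fresh mask and a k-means-on-PCs initialisation are drawn from derived
seeds; the best replicate (lowest held-out CE) is returned, and
`select_k()` takes the K minimising the mean CE over replicates, ties to
the smallest K. Numerical guards: predictions are clipped to
[1e-6, 1 − 1e-6] inside the log loss; ancestry components are identifiable
only up to relabeling, so all comparisons go through
`align_ancestry()`'s best-permutation search.

A practical limitation, visible in the package's own selection checks: the
held-out CE curve typically drops steeply to the true K and then flattens,
so the strict argmin can wander one K upward on a minority of data draws
when populations are weakly separated or the marker set is small. Larger
held-out masks sharpen the minimum; the validation scenario uses a 25%
mask and ~1200 markers, where selection is stable across seeds.

## Genomic BLUP with spatial adjustment

Per trait, `fit_gblup()` fits the record-level mixed model
y = μ + u_g + u_year + u_spatial + e, with u_g ~ N(0, K σ²_g) for a
VanRaden relationship matrix K, iid year effects, and a spatial surface
over field (row, col) built from a tensor-product B-spline basis (8×8
marginal bases by default) whose coefficients are one iid random effect —
a P-spline-style approximation to a full 2-D spline with difference
penalty, adequate for the smooth fertility trends it has to absorb.
Variance components are estimated by direct REML: quasi-Newton optimisation
of the restricted log-likelihood over log variances on the record-level
covariance (records per trait number in the hundreds to low thousands, so
dense Cholesky per evaluation is cheap). BLUPs come from the mixed-model
equations at the REML estimates; fixing `varcomp` skips REML, which the
limit-case tests use. Traits are modelled separately. Omnibus subgroup
differences use one-way ANOVA with Tukey HSD on the per-accession values;
p-values below machine precision are reported as the smallest positive
double, never literal zero. Trait correlations are signed Pearson
coefficients with test p-values.

## Association scans

`vanraden_kinship()` builds A = WWᵀ / (2Σp(1−p)) with W the mean-imputed
dosage matrix centred at twice the in-sample frequencies; in-sample
centring makes rows of W sum to ~0, so off-diagonals average −1/(n−1)
rather than 0 — worth knowing when reading the matrix. `mlm_scan()` is the
EMMAX/P3D scheme: eigendecompose K once on the scan subset, REML-estimate
the variance ratio δ under the covariates-only null by 1-D optimisation,
then test each marker by generalized least squares with a Wald t-test.
Variance components are not refit per marker; at these sample sizes the
P3D approximation is standard and the per-marker refit would not be
reproducible anyway. Covariates default to PC1–10 plus the ancestry matrix
with one column dropped (Q rows sum to one, so the full matrix is
collinear with the intercept); rank-deficient covariate sets are pruned by
QR. Markers collinear with the covariates, or below a 5% within-subset
MAF in subgroup scans, are flagged and not tested. Discovery control is
Benjamini–Hochberg at FDR 0.1 via `p.adjust`.

Because breeding stages differ strongly in yield-related traits, a pooled
scan can promote markers whose effect is carried entirely by
between-subgroup contrasts. `stratification_audit()` cross-tabulates
genotype by subgroup, contrasts the pooled additive slope with
within-subgroup slopes, and flags associations with no same-direction
nominally significant support inside any subgroup — the signature of
stratification leakage. Per-subgroup scans (the NS-only mode) rerun the
same covariate recipe inside the subset.

## The synthetic panel generator

`simulate_panel()` emulates the statistical structure the analyses assume,
with known ground truth, under a four-stage nested bottleneck:

* **Wild base.** Ancestral frequencies are drawn from a scaled Beta(0.5,
  0.5) on [0.05, 0.95]; demes (4 by default) get Balding–Nichols
  frequencies at F = 0.03. Haplotypes are first-order Markov chains along
  each chromosome with adjacent-locus correlation exp(−d/d₀), d₀ = 30 kb —
  chosen for its closed-form decay target (half-decay d₀·ln 2) and
  desk-scale speed; it matches no particular demographic history. The
  correlation of each adjacent pair is capped at the bivariate-Bernoulli
  feasibility bound so marginal frequencies are preserved exactly; for
  strongly asymmetric frequency pairs realized LD therefore sits below the
  nominal curve.
* **Breeding stages.** NS is truncation selection (default: top half) from
  an oversampled wild pool on a noisy index of the selected traits; CLT1
  descends from 7 NS founders through two generations of crosses with
  recombination at 1 cM/Mb; CLT2 crosses CLT1×CLT1 and CLT1×NS with the
  extra NS parent as the 8th grandparent. Stage sizes default to the
  cranberry panel's 121/111/26/104. A `degenerate_bottleneck` switch
  derives CLT1 from a single doubled founding haplotype — the limit in
  which stage diversity is exactly zero and ROD = 1 at every ancestrally
  polymorphic locus; a literal clone of a heterozygous plant would retain
  He = 0.5 at its heterozygous loci, so the degenerate limit is defined at
  the haplotype, not the plant. Clonal propagation is otherwise not
  modelled.
* **Phenotypes.** Each trait has a sparse polygenic background (300 loci)
  scaled to a stated genetic SD in trait units, plus listed major QTL
  (e.g. 0.5 g per allele on fruit weight) placed at intermediate-frequency
  loci. Records are accession × year on a field grid with a smooth
  low-frequency cosine surface; environmental variance is calibrated to
  the realized panel-wide breeding-value variance so the configured h² is
  exact on the panel scale, split 20% year, 20% spatial, 60% residual.
  Defaults use 3 years (the cranberry records span 7; 3 is enough to
  separate the year component at desk scale).
* **Missingness** is masked completely at random at 10% by default (the
  empirical panel allowed up to 30%).

What passing the synthetic checks shows — and does not. The generator
reproduces the features the statistics rely on: HWE within demes,
Balding–Nichols differentiation, exponential LD decay, nested founder
bottlenecks, polygenic-plus-QTL traits, spatial field trends, MCAR
missingness. It does not reproduce selfing and clonal replanting,
overlapping generations, ascertainment of GBS markers, non-random
missingness, or any calibrated cranberry demography (historical selection
intensities are unrecorded, so defaults are chosen for testability, not
historical fidelity). Recovery of a planted
parameter here certifies the estimator's logic, not its behaviour under
those unmodelled features.

## Validation scales and numerical conventions

The package's acceptance checks (tests/testthat/test-acceptance.R and
scripts/acceptance.R) run at fixed desk scales chosen to finish in minutes:
oracle equivalences on ≤10-accession toys against brute-force
reimplementations (nested-ANOVA theta, raw-sum Pearson, exhaustive BH,
element-loop VanRaden, Lance–Williams Ward); permutation type-I error at
n = 60, L = 2000 unlinked loci, R = 200; F_ST calibration against
Balding–Nichols F = 0.05 at n = 100 per deme, L = 2000, with a
delete-one-chromosome jackknife SE; LD recovery at d₀ = 30 kb on a
6-chromosome, 8-kb-spaced map; ancestry recovery at n = 75, L = 1200,
K = 1..6; GWAS null calibration pooled over ten 300-accession panels and
power over 50 seeds for a QTL explaining 20% of phenotypic variance at
FDR 0.1. Reproduction of the published cranberry panel's printed numbers
is a separate tier that requires the deposited data and is exercised only
when a user supplies it.

Conventions worth restating: coordinates are 1-based as in VCF; all
stochastic functions take explicit seeds and derive internal streams via
`derive_seed()`; quantiles are R's default type 7; permutation thresholds
compare with strict inequality; undefined statistics propagate as `NA`
rather than being silently dropped, and every scan object reports how many
loci were defined.
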