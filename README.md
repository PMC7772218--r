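# bogdiv

Population-genetic analysis of crop diversity panels that span successive
domestication and breeding stages. The motivating system is the American
cranberry (*Vaccinium macrocarpon*), domesticated within the last two
centuries: panels divide into wild clones (WLD), first-generation native
selections (NS), first-generation hybrid cultivars bred from a handful of
founders (CLT1), and advanced selections tracing to a small grandparent set
(CLT2). The package is for breeders and population geneticists who want the
whole stage-wise analysis — from VCF to selection scans, diversity loss,
LD, structure and association — as tested, scriptable R functions rather
than a pile of one-off scripts.

## What it computes

* **Marker filtering** (`read_vcf`, `filter_markers`): biallelic SNP
  dosages; drop markers with > 30% missing calls or panel MAF < 0.05.
* **Diversity** (`subgroup_freqs`, `polymorphic_fraction`, `joint_maf`,
  `expected_het`): per-subgroup allele frequencies, MAF spectra and
  joint-MAF contingency tables; He = 2p(1−p).
* **Selection scans** (`fst_scan`, `fst_permutation_threshold`,
  `rod_scan`): per-locus Weir–Cockerham
  θ̂ = a / (a + b + c) from the among-population / among-individual /
  within-individual variance components, with empirical 95% thresholds
  from membership-permutation nulls (R = 1000); reduction of diversity
  ROD = 1 − He_derived/He_ancestral across the four breeding steps
  (WLD→NS, NS→CLT1, CLT1→CLT2, NS→CLT2) with the
  ROD = 0 / (0, 0.2] / [0.8, 1) / ROD = 1 bin counts.
* **LD decay** (`pair_r2`, `ld_decay`): composite r² (dosage correlation)
  pooled in 10-kb distance bins per chromosome; half-decay distance.
* **Structure** (`pca_genotypes`, `ward_tree`, `snmf_fit`, `select_k`):
  PCA on −1/0/+1-coded genotypes; Ward (`ward.D2`) clustering with newick
  export; sparse-NMF-style ancestry (Q·F factorisation, masked
  cross-entropy choice of K).
* **Phenotypes** (`fit_gblup`, `subgroup_compare`, `trait_correlations`):
  spatially adjusted genomic BLUPs (REML; genomic + year + 2-D-spline
  field + residual components), subgroup ANOVA/Tukey, trait correlations.
* **GWAS** (`vanraden_kinship`, `mlm_scan`, `bh_fdr`,
  `stratification_audit`): EMMAX/P3D mixed-model scans with PC + ancestry
  covariates, BH discovery control at FDR 0.1, and an audit that flags
  associations carried purely by between-subgroup stratification.
* **Synthetic panels** (`scenario_config`, `simulate_panel`,
  `make_fixtures`): a coalescent-free four-stage bottleneck simulator with
  known ground truth (Balding–Nichols demes, Markov-chain LD, founder
  crosses, polygenic + QTL traits, spatial field, MCAR missingness).
* **Orchestration** (`run_config`, `run_pipeline`): the full pipeline from
  one (YAML-able) config, with a manifest of seeds, checksums and outputs.
  A thin CLI wrapper lives at `inst/scripts/bogdiv.R`.

## Worked example

The package ships a frozen 40-accession × 200-marker synthetic panel:

```r
library(bogdiv)
panel <- system.file("extdata", "sim_panel", package = "bogdiv")
inp <- read_vcf(file.path(panel, "sim.vcf"),
                file.path(panel, "panel_metadata.tsv"))
flt <- filter_markers(inp$genotypes)
flt$report
#> marker filter: 200 input SNPs; 0 removed (missing > 0.3); 38 removed (MAF < 0.05); 162 retained

fst_permutation_threshold(flt$genotypes, inp$metadata, c("WLD", "CLT2"),
                          R = 1000, seed = 17)
#> F_ST scan WLD vs CLT2 (wc): 162 defined loci; mean 0.04022; max 0.4827; perm p95 0.1393 (24 significant, R = 1000)

rod_scan(flt$genotypes, inp$metadata, step = "step2")
#> ROD scan (step2): NS -> CLT1, 162 markers
#>     rod_eq_0 rod_0_to_0.2 rod_0.8_to_1     rod_eq_1      rod_mid rod_negative
#>            3           26            0           21           37           74
#>    undefined
#>            1

ld_decay(flt$genotypes, inp$metadata, "WLD")
#> LD decay, subgroup WLD: 1001 pairs in 10-kb bins; first-bin mean r2 0.3565; half-decay at 20 kb

K <- vanraden_kinship(flt$genotypes)
fit_gblup(read.delim(file.path(panel, "phenotypes.tsv")), K, "fruit_weight")
#> GBLUP fit for fruit_weight: 80 records, 40 accessions
#>   variance components: genomic=0.1878, year=0.08959, spatial=0.03505, residual=0.06439
```

Reading the output: 24 loci exceed the permutation threshold between the
wild and advanced-selection stages; 21 markers lost all diversity crossing
the NS→CLT1 founder bottleneck (ROD = 1) while 74 gained diversity
(negative ROD — crosses among few founders push intermediate frequencies);
LD falls to half its first-bin value within 20 kb; and about half the
fruit-weight variance on this panel is genomic. On a 40-accession toy the
subgroup ANOVA is underpowered — run the same calls on a full-size panel
(or `simulate_panel(scenario_config(), seed = 1)`, which defaults to the
cranberry stage sizes 121/111/26/104) for stable stage contrasts.

The methods vignette (`vignettes/domestication-genomics.Rmd`) documents the
estimators, their assumptions, all tunable parameters, and what the
synthetic validation does and does not establish.

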