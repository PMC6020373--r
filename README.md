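# diseqtl

Comparative analysis of whole-blood transcriptomes across inflammatory
disease cohorts — for example juvenile idiopathic arthritis (JIA)
sub-types contrasted with inflammatory bowel disease (IBD). The package is
aimed at statistical geneticists and immunogenomics groups who want to ask,
on cohorts of a few hundred subjects, whether the genetic regulation of
blood gene expression is shared or disease-specific, and whether regulated
risk genes discriminate patient groups.

## What it computes

Given a gene-level RNA-seq count matrix, genotype dosages, sample metadata,
gene-set definitions and GWAS summary statistics, `diseqtl` provides:

* **Preparation** — FPKM, expressed-gene filtering, log-CPM normalization,
  surrogate-variable-style latent-factor removal with *protected*
  variables (disease sub-type, medication, disease duration), and
  PLINK-style genotype QC (biallelic sites, Hardy-Weinberg equilibrium
  `p ≥ 1e-3`, MAF ≥ 1%, missingness ≤ 5%).
* **Immune signatures** — PC1 scores over gene sets (blood-informative
  axes and transcript modules), Ward clustering of samples, principal
  variance component analysis, two-group differential expression with
  Benjamini-Hochberg FDR, one-way ANOVA across sub-types.
* **cis-eQTL mapping** — for SNPs within ±250 kb of each gene, the
  additive model `y_i = α + β g_i + γᵀc_i + ε_i` per pair, the per-gene
  peak eSNP, and an empirical FDR from expression-permutation.
* **Genotype-by-disease interaction** — the joint model
  `y = α + β_g g + β_d d + β_gd (g·d) + ε` over the pooled cohorts, with
  Wald p for the product term, BH control at FDR 10%, a cross-cohort
  effect-size comparison, and a single-outlier leverage audit for low-MAF
  calls.
* **Colocalization** — Wakefield approximate Bayes factors
  `log ABF = ½[log(se²/(se²+W)) + z²·W/(se²+W)]` combined into posterior
  probabilities for the five standard hypotheses H0–H4 (no signal /
  one-trait-only / two distinct causal variants / one shared causal
  variant).
* **Transcriptional risk score (TRS)** — for genes supported by coloc H4,
  `TRS_s = Σ_g π_g z_gs` where `π_g = +1` if the GWAS risk allele
  increases expression of gene *g* and `−1` if it decreases it; group
  contrasts in pooled-SD units (∆s.d.) with ANOVA.
* **A synthetic cohort generator** with full ground truth (HWE genotypes
  with LD blocks, co-expression modules, planted shared and
  disease-specific eQTL, group shifts, latent confounders, GWAS summaries
  with known risk-allele directions), so every stage is testable without
  access to patient data.

## Worked example

A synthetic 202-sample cohort (12 controls; 43/46/26 oligoarticular,
polyarticular and systemic JIA; 60 Crohn's; 15 ulcerative colitis) with 20
planted cis-eQTL of |β| = 0.8:

```r
library(diseqtl)
cfg0 <- sim_config(seed = 42, maf_range = c(0.2, 0.5))
plan <- auto_eqtl_plan(cfg0, 20, 0.8 * rep_len(c(1, -1), 20))
cfg  <- sim_config(seed = 42, maf_range = c(0.2, 0.5), eqtl_plan = plan)
sim  <- simulate_cohort(cfg)

norm <- normalize_expression(filter_expressed_genes(sim$counts))
adj  <- adjust_latent_factors(norm, data.frame(group = sim$labels),
                              n_factors = 10)
geno  <- qc_genotypes(sim$genotypes)
pairs <- build_cis_pairs(adj, geno)

jia <- names(sim$labels)[sim$labels %in% c("oligoJIA", "polyJIA", "sJIA")]
ibd <- names(sim$labels)[sim$labels %in% c("CD", "UC")]
cs_jia <- call_eqtls(pairs, subset_genotypes(geno, samples = jia),
                     subset_expression(adj, samples = jia),
                     n_perms = 20, cohort = "JIA", seed = 1)
cs_ibd <- call_eqtls(pairs, subset_genotypes(geno, samples = ibd),
                     subset_expression(adj, samples = ibd),
                     n_perms = 20, cohort = "IBD", seed = 2)
cs_jia
#> EqtlCallSet [JIA]: 20 eGenes at p <= 0.0001 (of 500 genes); empirical FDR 0.022 (20 perms)
cs_ibd
#> EqtlCallSet [IBD]: 16 eGenes at p <= 0.0001 (of 500 genes); empirical FDR 0.025 (20 perms)
```

The JIA cohort (n = 115) recovers all 20 planted loci; the smaller IBD
cohort (n = 75) recovers 16, both with empirical FDR near 2%. Pooling and
interaction testing:

```r
pooled <- pool_cohorts(cs_jia, cs_ibd, tag_a = "JIA", tag_b = "IBD")
table(pooled$discovery)
#> both  IBD  JIA
#>    9    7   11
disease <- setNames(factor(ifelse(sim$labels %in% c("CD", "UC"),
                                  "IBD", "JIA"),
                           levels = c("JIA", "IBD")), names(sim$labels))
recs   <- test_interactions(pooled, geno, adj, disease[c(jia, ibd)])
called <- call_interactions(recs)
#> interactions: 1 significant at FDR 10%, 2 nominal at p < 0.02
```

The planted effects are shared across diseases, so nominal interaction
hits at this rate are the expected false-positive background — the
single BH call sits at q = 0.055, just under the 10% bar, and the
per-disease slopes (`beta_ref`, `beta_alt`) show why it was flagged.
`run_pipeline()` wires all of this (plus coloc and the TRS) behind one
seeded, manifest-writing driver; see the vignette in `vignettes/` for the
modelling details.

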