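---
title: "Comparative blood eQTL mapping and transcriptional risk scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative blood eQTL mapping and transcriptional risk scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `diseqtl`, the
defaults and why they were chosen, what the bundled synthetic-cohort
generator does and does not emulate, and the numerical and design choices
a maintainer should know about.

## The analysis problem

Autoimmune and inflammatory diseases share much of their genetic
architecture, yet GWAS loci are often disease-specific. One mechanistic
question is whether the *regulatory* effects of risk variants — their
cis-eQTL effects on blood gene expression — differ between diseases, or
whether disease specificity arises downstream of shared regulation.
Answering it on clinical cohorts means comparing eQTL maps built in two
patient groups of modest size (on the order of 50–110 genotyped subjects
per disease), testing genotype-by-disease interactions jointly, and
summarising the regulated risk genes per patient as a transcriptional
risk score.

## Expression preparation

**Filtering.** A gene is retained when more than 10 individuals show more
than 6 reads *and* its FPKM exceeds 0.1. The FPKM criterion is
implemented as *mean FPKM across samples* > 0.1; the alternative "at
least one sample above 0.1" reading is selectable via
`fpkm_rule = "any"`. Both count thresholds are strict inequalities,
matching the usual phrasing of the rule. FPKM uses the sample's total
mapped reads as library size; a filtering step records those totals so
that refiltering reuses them, which is what makes the filter exactly
idempotent.

**Normalization.** `log2(CPM + 1)`. The downstream models are all linear
on the log scale, so a count-model normalization (TMM plus a
negative-binomial GLM) would add machinery without changing any of the
quantities this package estimates; the transform is recorded in the
matrix's unit tag so the provenance is explicit.

**Latent-factor adjustment.** Technical and unmodelled biological
variation is removed in two documented steps: (1) each gene is
residualized on the *protected* design (disease sub-type, plus optional
medication and disease-duration indicators supplied as extra protected
columns — there is no separate code path for those covariates); the top
`n_factors` principal components of the residual matrix are the latent
factors; (2) genes are refit jointly on protected design + factors and
only the factor contribution is subtracted. The two-step residualization
is an explicit approximation to a joint supervised-normalization fit: how
protected variables should interact with estimated surrogate variables is
not uniquely defined, and the two-step form has the property we actually
need — protected group structure is preserved up to numerical tolerance
while planted orthogonal confounders are removed (this is tested). The
default `n_factors = 15` is a conventional choice for whole-blood studies
of roughly 200 samples; scaled-down simulations in the test suite use
5–10 factors to match their smaller dimensionality.

**Genotype QC.** Biallelic sites only; HWE p ≥ 1e-3; MAF ≥ 1%;
missingness ≤ 5%. The HWE test is the exact test whenever any expected
genotype-class count is below 5 and the 1-df chi-square otherwise.
Missing dosages are mean-imputed *after* QC for the regression stages —
with ≤ 5% missingness guaranteed, mean imputation perturbs slopes by at
most a few percent of an SE.

## Signatures

Axis and module scores are the first principal component of the set's
genes, computed on per-gene standardized expression. Standardization
makes the score invariant to per-gene affine rescaling; the sign is
oriented so that the mean gene loading is positive (a high score means
high average expression of the set — PCA itself leaves the sign
arbitrary). The proportion of variance explained is reported because a
coherent blood co-expression axis typically concentrates well over half
of the set's variance in PC1, and a low value is a red flag for a poorly
matched gene set.

PVCA regresses each of the top `n_pc` expression PCs on the experimental
factors and weights each factor's sequential (type-I) eta-squared by the
PC's share of total variance; the residual closes the budget to 1.
Sequential sums of squares were chosen over a random-effects REML fit for
transparency: the caller controls factor order, and nested designs
(sub-type within disease) are handled naturally because a nested factor
is only reported for the variance it adds beyond its parent. A factor
that adds no rank at all is rejected as aliased.

Differential expression is a per-gene two-group linear model (pooled-SD t
test) on log-CPM with BH adjustment and direction labels. This is
deliberately not a count-model engine: the DE step here feeds descriptive
contrasts, and its calibration and power are validated by simulation in
the test suite. Clustering is Ward linkage (`ward.D2`) on Euclidean
distances of z-scores, cut at `k = 6` by default, with per-sub-type
cluster membership proportions.

## cis-eQTL mapping

SNP-gene pairs are enumerated for SNPs within ±250 kb of the gene's start
and stop, bounds inclusive (a SNP at exactly `stop + window` is paired).
Each pair is fit by OLS, `expression ~ intercept + dosage (+ covariates)`;
covariates (e.g. ancestry PCs) are residualized out of both sides first
(Frisch–Waugh), which is exactly equivalent and lets thousands of pairs
share one QR decomposition. A kinship-based mixed model was considered
and rejected: at cohort sizes of 50–110 the kinship estimate is noisy,
the interaction stage uses a plain joint linear model anyway, and OLS
keeps the permutation scheme exact.

Per gene, the minimum-p (peak) SNP is retained; conditional scans for
secondary signals are out of scope (they are underpowered at these sample
sizes, and secondary eQTL are noted as a caveat rather than modelled).
eGenes are called at p < 1e-4, and the empirical FDR is estimated as the
mean number of peak hits over permuted expression divided by the observed
hit count. Permutations relabel samples once per replicate, shared across
genes, preserving both LD and gene-gene correlation; 100 permutations by
default (fewer than 10 flags the estimate low-confidence). Reported
p-values are floored at 1e-300.

Because low-MAF eQTL can be driven by a single minor homozygote with
outlying expression, `maf_significance_check()` (a) correlates MAF with
−log10 p across calls — there should be no systematic relationship — and
(b) refits every call after deleting the single most extreme expression
value among minor-allele homozygotes, flagging calls that no longer clear
the threshold.

## Genotype-by-disease interactions

Candidates are the union of peak pairs significant in either cohort,
with discovery provenance. The joint model is
`y = α + β_g g + β_d d + β_gd (g·d) + ε` with a 0/1 disease indicator;
the interaction p is the Wald t-test of the product term (for OLS this is
equivalent to the likelihood-ratio test and simpler to report).
Per-disease marginal slopes are derived from the joint fit
(`β_ref = β_g`, `β_alt = β_g + β_gd`) and are algebraically identical to
per-cohort OLS slopes — an identity the tests check to 1e-10. BH at FDR
10% is used for calling (the FDR procedure itself is a design choice; BH
is the standard default), with the nominal p < 0.02 count reported for
comparability. Pairs monomorphic within either disease, or with fewer
than 10 samples in a group, are flagged untestable rather than fit.

Cross-cohort effect-size comparisons report the Pearson correlation of
the marginal betas and the mean |β| ratio stratified by discovery cohort.
Both carry a winner's-curse caveat: effects are overestimated in the
cohort where they were discovered, so a discovery-stratum ratio above 1
is expected even under fully shared effects, and the cross-cohort
correlation is attenuated toward
`var(β) / sqrt((var(β)+mean(se_A²)) (var(β)+mean(se_B²)))`. The test
suite verifies both geometries on simulations with known shared effects.

## Colocalization

Per-SNP evidence is the Wakefield approximate Bayes factor
`log ABF = ½[log(se²/(se²+W)) + z² W/(se²+W)]` with prior effect variance
`W`. Under the single-causal-variant assumption the five hypothesis sums
are combined with priors `p1 = p2 = 1e-4` (SNP causal for one trait) and
`p12 = 1e-5` (causal for both); all sums are done in log space with
log-sum-exp, and the H3 term uses `log1p` to subtract the shared-SNP
configurations stably. Prior effect SDs default to 0.15 for quantitative
traits and 0.2 (log-odds) for case-control — the conventional choices —
and are exposed as arguments since there is no principled way to infer
them from a single locus. For a case-control trait only the z-scores are
informative: standard errors are recast on a canonical `1/sqrt(n)` scale,
which makes the posteriors invariant to any common rescaling of that
trait's betas and SEs. Only SNPs shared between the two series enter the
computation.

## Transcriptional risk score

Genes qualify when the locus colocalizes (H4 posterior ≥ 0.5 by default —
the threshold is a flag because "H4-validated" has no canonical cutoff).
GWAS and eQTL records are harmonized by matching the risk allele to the
eQTL's effect or other allele, with a strand-flip rescue; irreconcilable
genes are dropped with a warning, never silently. Polarity is +1 when the
risk allele increases expression and −1 when it decreases it, so a
positive score always means risk-like expression. The score is the sum of
polarity × per-gene z-score; z-scores are computed across *all* samples
of the latent-factor-adjusted matrix (no reference group is singled out;
standardizing to a control group instead, or using the unadjusted matrix,
are both caller choices — pass a different matrix or subset). Group
contrasts report the difference from a reference group in pooled-SD units
(Cohen's d with pooled SD — "standard deviation units" admits several
estimators, and the pooled form is the one that converges to the planted
shift in the consistency test) plus a two-group p and an overall ANOVA.

## The synthetic cohort generator

The generator's defaults are the study conditions used throughout the
tests: a six-group cohort of 202 subjects (12 controls, 43 oligoarticular
/ 46 polyarticular / 26 systemic JIA, 60 Crohn's, 15 ulcerative colitis);
genotypes as sums of two haplotypes whose alleles copy their left
neighbour within an LD block with probability `ld_rho` (HWE holds by
construction; first-order copying is sufficient to create the
shared-vs-distinct-peak LD patterns colocalization must distinguish,
without a coalescent simulator); expression on the log scale as module
loadings × latent factors + per-group factor shifts + planted eQTL ×
dosage + confounder loadings × confounders + Gaussian noise. A raw-count
view is produced by exponentiation and per-sample multinomial sampling so
that the count-based filters can be exercised; counts are not the primary
simulation scale because every downstream model is linear on logs. GWAS
summaries place a risk signal (odds ratio 1.3, 5000 cases / 5000
controls by default) at each planted SNP, propagate it to the locus
through the realized LD (`z_j = r_j z_causal + noise`), and record the
true TRS polarity of every planted gene.

Where the tests assert recovery of 50 planted eQTL of effect size 0.8,
the effects are planted with alternating sign (±0.8): a constant planted
vector would make the effect-size correlation degenerate, and mixed signs
are also the realistic case. The planted case/control TRS shift of
d = 1.1 at n = 75 vs 12 is assessed as the mean recovered ∆s.d. over 25
replicates because a single Cohen's d at those group sizes has a standard
error near 0.32 — far larger than the recovery question being asked.

What the generator does *not* emulate: population structure and
admixture, sequence-level read noise, cell-type composition shifts,
negative-binomial overdispersion, and medication effects that correlate
with disease severity. Passing tests therefore demonstrate correctness of
the estimators under the stated generative model, not robustness to
those real-data phenomena; the latent-factor adjustment and the ancestry
covariate hooks are the designed mitigations, and the ancestry-covariate
invariance of interaction recovery is itself tested.

## Numerical choices and scaling

p-values are floored at 1e-300; perfect fits report that floor rather
than zero. Degenerate inputs are handled explicitly: constant genes get
p = 1 with a flag in DE, monomorphic SNPs are flagged in eQTL fits,
zero-library samples are errors. Peak selection breaks exact ties by the
first minimal index (deterministic). All randomized stages take explicit
seeds; the pipeline derives per-stage seeds from one top-level seed and
records output-file hashes in its manifest, and a double run under the
same seed is asserted hash-identical. Test and acceptance simulations use
150–500 genes, 300–1000 SNPs and 20 permutations — sizes chosen so the
full validation battery expresses every property being checked while
running in well under a minute per stage on a single core; the defaults
users see (`n_perms = 100`, 250 kb window, FDR thresholds) are the
analysis-scale values.

## The pipeline

`run_pipeline()` executes simulate → preprocess → signatures | eQTL →
interaction → coloc → TRS from one flat, stage-sectioned configuration
(unknown keys are errors, catching typos in threshold names; dependencies
are validated before any stage runs; a failing stage leaves a partial
manifest with the failure recorded). The package's functions, this
vignette and `scripts/acceptance.R` are the intended interfaces;
interchange with other tools goes through the plain-text formats
(counts/dosage TSV, VCF v4.2, BED, GMT, GWAS TSV, JSON reports).

## Limitations

Single-causal-variant colocalization only (no SuSiE-style multi-signal
decomposition); one peak eSNP per gene (no conditional secondary
signals); two-disease interaction models (more than two sub-types must be
collapsed to the contrast of interest); no trans-eQTL; no LD-reference
handling beyond the genotypes supplied.
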