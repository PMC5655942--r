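---
title: "Network-propagation SNP prioritization and ensemble prediction of radiographic progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-propagation SNP prioritization and ensemble prediction of radiographic progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragnet)
```

## The problem

Radiographic joint damage in rheumatoid arthritis (RA), quantified by the
Sharp/van der Heijde score (SHS) from hand X-rays, progresses at very
different rates between patients and is substantially heritable.
Predicting, early in the disease course, which patients will progress
severely is a prerequisite for treat-to-target decisions. Single-variant
association scans at cohort sizes of a few hundred patients are badly
underpowered, and sets of SNPs picked purely by association p-value are
unstable: each training subsample picks a different set of noise variants.

`ragnet` implements a post-GWAS strategy for this setting: association
evidence is combined with prior biological knowledge, so that the ranking
of candidate SNPs leans on information that does not vary with the
training subsample. The pipeline has five stages, each exposed as an
ordinary function, plus a single fitting entry point (`ragnet_cv()`) and
an orchestrator (`run_pipeline()`).

## Outcome definition

For a cohort with two hand X-rays per patient, the yearly progression rate
is `(SHS_followup - SHS_baseline) / interval`; with one X-ray, the
estimated rate `total SHS / disease years` is used instead
(`classify_progression()`, modes `two_xray` / `one_xray`). Patients are
split at the empirical 1/3 and 2/3 quantiles of the rate: the low tertile
is the *no progression* class, the high tertile the *severe* class, and
the middle tertile is excluded from analysis. Tertile membership is by
quantile interval (at or below the lower cut = low, at or above the upper
cut = high); with continuous rates ties at the cuts essentially never
occur, but the convention matters for degenerate inputs and is fixed here
once. Samples with nonpositive denominators are excluded and reported in
an error record rather than failing the run.

## Association scan

Variants pass QC when MAF ≥ 0.005, per-variant call rate ≥ 0.95, and
exact Hardy–Weinberg p > 5×10⁻⁷ (`qc_filter()`). The HWE test is the
conditional exact test (enumeration over heterozygote counts given allele
counts); at thresholds as extreme as 5×10⁻⁷ the chi-square approximation
is unreliable in the tail, so the exact test is the default and chi-square
is an option. Per-variant association is an additive-coded logistic
regression of severe vs. no progression fit by IRLS, adjusted for six
clinical covariates (baseline SHS, disease duration, HAQ, anti-CCP, BMI,
ESR) and the top ten genotype principal components, with the Wald p-value
on the dosage term (`logistic_assoc()`). The significant set is
`p < 0.05`, strict. Missing dosages are handled complete-case per variant
in association and mean-imputed per variant in PCA and SVM features;
missing covariates drop the sample with a logged count. Variants with
constant dosage, non-convergent fits, or quasi-separation (standard error
above 10³) are flagged and never enter the significant set.

One numerical subtlety is worth recording: with integer dosages, balanced
classes, and *no* continuous covariate, the score statistic at β = 0 can
be exactly zero by an integer-lattice coincidence, which puts a point mass
at p = 1 in a null scan. This is discreteness, not miscalibration — the
rejection rate at 0.05 stays correct — and it disappears under the
covariate-adjusted model actually used by the pipeline. The null-scan
uniformity test therefore uses the adjusted model.

## SNP-to-gene mapping

Each significant SNP, together with its LD proxies at r² > 0.8 (strict;
no transitive closure), is mapped to genes through five evidence channels
(`map_snp_to_genes()`): gene bodies, promoters, enhancers (via
enhancer→gene links), miRNA regions (via miRNA→target links), and
significant eQTL links. All intervals are 0-based half-open on one
coordinate system. The promoter is the 2 kb immediately upstream of the
transcription start site — `[TSS−2000, TSS)` on the plus strand and the
mirrored window past the gene end on the minus strand. Containment is by
the SNP's point position; evidence sources are recorded but not weighted,
and proxy-derived hits are treated identically to direct hits, since the
downstream score sums gene scores without source weights. eQTL links
arrive pre-thresholded as a significance flag.

## Disease network prior and propagation

The prior for gene *v* is `Y(v) = max over diseases d of GDA(v,d) × DS(d, target)`
(`assign_prior()`): the strongest route from the gene to the target
disease either directly or through a phenotypically similar disease.
`DS(target, target) = 1`; genes with no gene–disease association get 0.
The adjacency of the gene-interaction graph is normalized symmetrically,
`W'ᵢⱼ = Wᵢⱼ/√(DᵢDⱼ)`, which bounds the spectral radius by 1, and the prior
is propagated by `F ← αW'F + (1−α)Y` from `F₀ = Y` to its fixed point
`(1−α)(I−αW')⁻¹Y` (`propagate()`; tol 1e−9, max 10 000 iterations,
non-convergence is an error carrying the residual). Unit edge weights are
assumed when the edge list carries no weight column; confidence-weighted
lists are accepted as-is.

Two genuinely open choices were closed as follows. The restart parameter α
is not dictated by the method; the default is 0.5, and
`alpha_sensitivity()` reports score vectors and their Spearman rank
correlations over α ∈ {0.3, 0.5, 0.7, 0.9} so users can check ranking
stability. Classic formulations of this propagation squash the prior
through a logistic before diffusing; because the prior here is already the
explicit `Y(v)` product formula, the default applies no transform, and
`prior_transform = "logistic"` restores the classic behaviour.

## Reprioritization and selection

A SNP's reprioritization score is the sum of the propagated scores of its
mapped genes, deduplicated so no gene counts twice for one SNP
(`score_snps()`). Ranking (`rank_and_select()`) is by descending score
with ties broken by ascending association p-value and then lexical id;
the comparison baseline `gwas_p` ranks by ascending p-value alone.
Zero-score SNPs remain rankable so a top-k set is always defined.
Selection stability across folds is summarized by the mean pairwise
Jaccard index of the per-fold top-k sets (`overlap_ratio()`). The Jaccard
definition is this package's choice — published overlap summaries of this
kind do not always state a formula, so absolute values may not be
comparable across implementations, only the contrast between strategies.

## Cross-validated ensemble

`ragnet_cv()` runs stratified tenfold cross-validation in which *all*
supervised steps — QC, PCs, association, mapping, scoring, ranking, and
SVM training — are recomputed on the nine training folds only; network
propagation uses no sample data and is computed once. For each k in the
grid (default 10 to 150 by 5), the genetic arm is an RBF-kernel SVM on the
top-k mean-imputed, standardized dosages; k* maximizes mean held-out
accuracy with ties to the smallest k (parsimony). The clinical arm is an
RBF SVM on the six standardized covariates. Both arms emit Platt-type
probabilities calibrated within the training folds. The final probability
is `w·p_SNP + (1−w)·p_clinical`; w* maximizes accuracy of the pooled
held-out predictions over a grid of step 0.01 (ties to the smaller w),
pooling rather than per-fold optimization because the pooled curve is much
less noisy at these sample sizes and uses every held-out prediction once.
SVM hyperparameters are cost 1 and the kernel-width default γ = 1/p on
standardized features; no inner tuning loop is run by default, keeping one
model per fold. Decision threshold is 0.5 throughout. Accuracy is
(TP+TN)/N; AUC uses the rank formula
`(ΣRank(pos) − #pos(#pos+1)/2) / (#pos·#neg)` with midranks for ties,
i.e. the Mann–Whitney concordance normalized by the number of
case–control pairs — the only denominator for which perfect separation
yields exactly 1. Paired AUC differences are tested with the DeLong
structural-components test by default (bootstrap optional).

Cross-cohort replication (`cross_cohort_transfer()`) supports both the
direct carry-over of the selected SNP ids (reporting which are present in
the new cohort, then cross-validating an SNP-only SVM on those) and the
primary mode of rerunning the whole pipeline inside the new cohort,
SNP-arm only, since replication cohorts may lack clinical covariates —
association is then covariate-free.

## What the synthetic generator emulates — and what it does not

The generator (`sim_config()`, `simulate_study()`) produces the full input
suite: genotypes, SHS trajectories, clinical covariates, annotation
tracks, link tables, LD proxies, the gene-interaction graph, and the
GDA/DS prior tables. Its defaults describe the study design the pipeline
assumes: 240 patients (so that two tertiles give ≈160 analysis samples),
biallelic variants at MAF 0.05–0.5 with 2% missingness, ten causal
variants at a per-allele odds ratio of 2 on the liability scale, six
clinical covariates with standardized liability coefficients
(0.35, 0.20, 0.40, 0.60, 0.25, 0.30), Gaussian liability noise of unit
SD, and a preferential-attachment gene network in which genes carrying
causal variants lie within two hops of nonzero-GDA genes. The progression
rate is a strictly increasing function of the liability, so tertile
classing recovers the liability ordering; follow-up SHS is baseline plus
rate times interval and never decreases. LD is injected by copying causal
genotypes with per-allele flip noise calibrated to the target r² of 0.9 —
exactly controllable, unlike coalescent simulation. Anti-CCP is Bernoulli
(rate 0.7); the other covariates are continuous with plausible locations
and scales, with no claim to match any real cohort's distributions.

Real data differ in ways the generator deliberately ignores: population
structure and relatedness, LD beyond the manufactured proxy pairs,
multi-chromosome layout, allele-frequency spectra, imputation artifacts,
and annotation databases with their own ascertainment biases. Passing
tests therefore demonstrate that the machinery is correct and that the
method's qualitative advantage (stability and rank improvement from
sample-independent prior information) holds when its assumptions hold —
not that any particular accuracy is attainable on a real cohort.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run the full pipeline at
deliberately small scale — cohorts of 90–300 samples, 60–2000 variants,
15–300 genes — chosen so that the whole suite completes in minutes while
every statistical check retains power (Monte-Carlo tolerances are stated
per test). The pipeline itself has no such limits; stages scale linearly
in variants and samples except dense propagation, which is cubic in genes
if solved directly and is therefore iterative here.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))
fit <- ragnet_cv(study$cohort, study$bundle, study$network,
                 k_grid = seq(10, 60, 5), seed = 1)
summary(fit)
plot(fit)

baseline <- ragnet_cv(study$cohort, study$bundle, study$network,
                      strategy = "gwas_p", k_grid = seq(10, 60, 5), seed = 1)
compare_auc(fit$probabilities$ensemble,
            baseline$probabilities$ensemble[names(fit$y)], fit$y)
```

## Known limitations

* The per-fold association scan refits one IRLS model per variant; at
  hundreds of thousands of variants a score-test screen would be the
  natural optimization.
* The overlap-ratio definition (mean pairwise Jaccard) is one of several
  reasonable stability summaries; compare contrasts, not absolute values.
* Tertile cut points are estimated once on the full cohort before
  cross-validation. The outcome definition is part of the phenotype, not
  of model selection, but users should note that alternatives (per-fold
  classing) exist.
* With training sets under ≈100 samples and the full covariate set
  (6 clinical + 10 PCs), quasi-separation of the per-variant logistic fits
  becomes common; such variants are flagged and dropped from the
  significant set rather than rescued by penalization.
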