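# ragnet

Biologically informed prediction of severe radiographic progression in
rheumatoid arthritis (RA) from genotype and clinical data.

## The problem

Joint damage in RA, measured by the Sharp/van der Heijde score (SHS) on
hand X-rays, is substantially heritable, but association scans at cohort
sizes of a few hundred patients are underpowered and SNP sets chosen by
p-value alone are unstable across training subsamples. `ragnet`
implements a post-GWAS strategy: association-significant SNPs are mapped
to biologically related genes and re-ranked by prior disease relevance
propagated over a gene-interaction network, so the ranking leans on
evidence that does not change with the training subsample.

## The method

1. **Outcome.** The yearly progression rate ΔSHS/year (two X-rays), or
   total SHS / disease years (one X-ray), is tertile-classed: low tertile
   = no progression, high tertile = severe, middle excluded.
2. **Association.** After QC (MAF ≥ 0.005, call rate ≥ 0.95, exact HWE
   p > 5×10⁻⁷), each variant's dosage enters a logistic model adjusted
   for six clinical covariates and the top ten genotype PCs; the
   significant set is Wald p < 0.05.
3. **Mapping.** Each significant SNP and its LD proxies (r² > 0.8) map to
   genes via gene bodies, 2 kb promoters, enhancer links, miRNA-target
   links, and significant eQTLs.
4. **Network scoring.** Gene priors Y(v) = max_d GDA(v,d)·DS(d,RA) are
   diffused over the degree-normalized interaction network,
   F ← αW′F + (1−α)Y, to the fixed point (1−α)(I−αW′)⁻¹Y; a SNP's score
   is the sum of F over its mapped genes.
5. **Prediction.** Stratified tenfold cross-validation reruns steps 2–4
   inside each training partition, selects the SNP count k* by mean
   held-out accuracy of an RBF-SVM on the top-k dosages, and combines the
   genetic arm with a clinical-covariate SVM arm as
   p = w·p_SNP + (1−w)·p_clin, with w chosen on pooled held-out
   predictions. Evaluation uses (TP+TN)/N accuracy, the rank-based
   (Mann–Whitney) AUC, and paired DeLong tests for AUC differences.

A seeded synthetic-data module generates every input — genotypes, SHS
trajectories, clinical covariates, annotation tracks, LD tables, the
gene network, and disease-prior tables — with causal variants whose genes
sit near high-prior genes in the network.

## Worked example

```r
library(ragnet)

study <- simulate_study(sim_config(n_samples = 240, n_variants = 800,
                                   n_genes = 150, seed = 11))
fit <- ragnet_cv(study$cohort, study$bundle, study$network,
                 k_grid = seq(10, 40, 10), seed = 11)
summary(fit)
#> Cross-validated progression model (network_score)
#>   analysis samples: 160 (80 severe / 80 no progression)
#>   selected SNP count k*: 20   ensemble weight w*: 0.38
#>   held-out accuracy: SNP arm 0.7375 | clinical arm 0.7438 | ensemble 0.8438
#>   held-out AUC:      SNP arm 0.7956 | clinical arm 0.8131 | ensemble 0.9019
#>   at threshold 0.5: sensitivity 0.8625, specificity 0.8250, PPV 0.8313
```

Reading the output: of the 240 simulated patients, the rate tertiles give
160 analysis samples. The nested cross-validation picked 20 SNPs (k*) and
a weight of 0.38 on the genetic arm; the ensemble's held-out accuracy
(0.84) and AUC (0.90) beat both single arms, and the same fit under
`strategy = "gwas_p"` gives a lower-ranked causal recovery and a less
stable per-fold SNP set — the package's central, testable claim.

`run_pipeline()` drives the whole analysis from one configuration and
writes accuracy curves, per-fold SNP sets, held-out probabilities, ROC
points, and a strategy-comparison report with fold-overlap ratios and
DeLong p-values.

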