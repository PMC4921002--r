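# mdcall — mixture-model genotype calling for two-channel SNP arrays

`mdcall` infers genotypes (AA, AB, BB) from raw two-channel SNP-array
fluorescence intensities, with particular care for **rare variants**. It is
aimed at statistical geneticists and methods developers who need a
population-based caller that does not fall apart when a genotype cluster
holds only a handful of samples — the regime where classical per-SNP
mixture callers lose clusters and SNP-based callers start violating
Hardy–Weinberg equilibrium.

## The method

Every sample contributes an intensity pair *x<sub>is</sub> =
(r<sub>is</sub>, g<sub>is</sub>)* (one channel per allele) at every SNP.
SNPs are partitioned by estimated minor allele frequency (MAF) and
per-cluster sample sizes *n<sub>ks</sub>*, and each group is called by its
own model:

| group | condition | model |
|---|---|---|
| g1 | MAF ≥ 0.05 | three-component bivariate Gaussian mixture, fitted by EM |
| g2 | MAF < 0.05 and some cluster has b₁ ≤ n<sub>ks</sub> < b₂ (defaults 3, 10) | Dirichlet Process Gaussian mixture, collapsed Gibbs sampling |
| g3 | the remaining rare SNPs | DP mixture fitted jointly with an automatically selected reference SNP |

The DP mixture places a Chinese-restaurant-process prior over partitions
(concentration α with prior 1/α ~ Gamma(1, mean 1)) and a conjugate
Normal–Wishart prior on component parameters, so the number of occupied
genotype clusters is inferred from the data. For extremely rare SNPs the
rich-gets-richer property of the CRP would swallow one- or two-point minor
clusters; such a T-SNP is therefore stacked with a reference SNP — a
preceding SNP with MAF > 0.15, all three cluster proportions ≥ 10%, and
minimal pooled-covariance Mahalanobis cluster distance
*D<sub>t</sub>* — whose populated clusters anchor the sparse ones.

Each call carries a **posterior rate** (PR), the posterior probability of
its assigned cluster; calls with PR < 0.85 are withheld (NC), which is
also how abnormal intensities are rejected. Per-SNP quality is the
**average posterior rate** (APR). Evaluation helpers compute call rate,
pairwise concordance, accuracy against truth, and per-population
Hardy–Weinberg equilibrium tests. A bundled simulator generates synthetic
BeadArray-style panels with ground truth, including pinned rare-variant
regimes and abnormal-intensity contamination.

See `vignettes/genotype-calling.Rmd` for the full model description,
hyperparameter rationale and numerical choices.

## Worked example

```r
library(mdcall)

specs <- study_panel_specs(n_common = 20, n_g2 = 4, n_g3 = 2, n = 200,
                           seed = 11)
panel <- simulate_panel(specs, populations = 2, seed = 11)
fit   <- run_md(panel$dataset, md_config(seed = 11))
summary(fit)
#> M-D calling summary
#>   SNPs: 26  calls: 5200  call rate: 99.71%
#>   groups:  g1=22 g2=2 g3=2
#>   models:  DP-GMM=2 DP-Ref=2 GMM=22
#>   APR quartiles: 0.996 0.998 0.999 1.000 1.000
accuracy(fit, panel$truth)
#> [1] 99.30569
```

The 26-SNP panel (20 common, 4 rare, 2 extremely rare; 200 samples; 1%
abnormal intensities) routes 22 SNPs to the EM mixture, 2 to the DP
mixture and 2 to reference-assisted calling; 99.71% of cells are called
and 99.3% of calls match the simulator truth. Per-SNP detail lives in
`fit$snp_summary` — for example a rare SNP called by the DP mixture with
cluster sizes 194/0/6 and MAF 0.026:

```r
head(subset(fit$snp_summary, group != "g1"), 2)
#>            snp       apr        maf group  model n_AA n_AB n_BB n_NC
#> 22 RARE_G2_002 1.0000000 0.02551020    g2 DP-GMM  194    0    6    0
#> 24 RARE_G2_004 0.9992115 0.04750000    g2 DP-GMM  189    3    8    0
```

A thin command-line front end is included:

```sh
Rscript inst/scripts/mdcall.R simulate --out-dir demo --seed 3
Rscript inst/scripts/mdcall.R run --intensities demo/intensities.tsv \
        --out-dir demo_out --seed 3
Rscript inst/scripts/mdcall.R eval --calls demo_out/calls.tsv \
        --truth demo/truth.tsv
```

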