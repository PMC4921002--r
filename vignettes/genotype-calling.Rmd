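---
title: "Mixture-model genotype calling for two-channel SNP arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model genotype calling for two-channel SNP arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcall)
```

## The problem

A two-channel SNP array measures, for every sample $i$ and SNP $s$, a pair
of raw fluorescence intensities $x_{is} = (r_{is}, g_{is})$, one channel
per allele. Within a SNP, samples fall into up to three genotype clusters
(AA, AB, BB) plus occasional abnormal measurements. Calling genotypes means
assigning each intensity pair to a cluster — easy for common SNPs whose
three clusters are all well populated, hard for rare variants where one or
two clusters hold a handful of points or are missing entirely, so that
both the number of clusters and their boundaries are uncertain.

`mdcall` implements a three-model calling procedure that routes each SNP
to the cheapest model able to call it well:

* **g1 (common)** — a per-SNP three-component bivariate Gaussian mixture
  fitted by EM (`fit_gmm()`);
* **g2 (rare, moderately populated minor cluster)** — a Dirichlet Process
  Gaussian mixture (`fit_dp_gmm()`), which infers the number of occupied
  clusters from the data;
* **g3 (extremely rare)** — the DP mixture fitted jointly with a
  carefully selected good-quality *reference SNP*
  (`call_with_reference()`), whose populated clusters anchor the target
  SNP's sparse ones.

## Model I: Gaussian mixture with EM

Each sample carries a latent indicator $z_{is} \in \{1,2,3\}$ with mixing
proportions $\pi_{ks}$, and cluster $k$ is a bivariate normal
$\Psi(x; \mu_{ks}, \Sigma_{ks})$. The E-step computes responsibilities

$$f_k(x_{is}) = \frac{\pi_{ks}\,\Psi(x_{is};\mu_{ks},\Sigma_{ks})}
  {\sum_u \pi_{us}\,\Psi(x_{is};\mu_{us},\Sigma_{us})},$$

and the M-step re-estimates $\mu_{ks}$ as the responsibility-weighted mean
and $\Sigma_{ks}$ as the responsibility-weighted scatter about the new
mean. Iteration stops when the relative log-likelihood change falls below
`gmm_tol` ($10^{-8}$ by default, capped at 500 iterations).

Call quality is scored per sample by the **posterior rate** (PR) — the
converged responsibility of the assigned cluster — and per SNP by the
**average posterior rate** (APR), the mean PR over assigned samples. Calls
with PR below the threshold (0.85 by default, inclusive: PR $\ge$ 0.85 is
called) are withheld as NC. This posterior filter is also how abnormal
("null") intensities are rejected: they are not modelled as a fourth
mixture component.

Numerical choices:

* Initialization splits samples along the contrast
  $y = (r-g)/(r+g)$ at the fixed cutoffs $\pm 0.5$ (AA / AB / BB) and
  refines by k-means started at the group means. The refinement is
  accepted only if every refined center stays inside its contrast region:
  with very unbalanced clusters (a 290-point major cluster next to a
  5-point minor one), unconstrained k-means lowers total within-cluster
  sum of squares by splitting the major cloud and merging the sparse
  clusters, which is exactly wrong here.
* A contrast group that is empty gets a synthetic center at the canonical
  contrast position, far from the data; the corresponding component is
  starved in the first E-step and frozen (proportion floored at
  $10^{-10}$), so a SNP with a missing cluster degrades gracefully to a
  2- or 1-component fit.
* Densities are evaluated in log space; responsibilities of far-out
  points are normalized via log-sum-exp and never underflow to NaN.
* Covariances get an $\varepsilon I$ ridge ($\varepsilon = 10^{-6}$ times
  the mean diagonal) only when the smallest eigenvalue falls below that
  floor, so the EM ascent is exact on healthy data and protected on
  degenerate clusters.
* **Component-to-genotype mapping.** Components are ordered by the
  contrast of their means; when the three means occupy distinct contrast
  regions the order maps to (AA, AB, BB). When two components share a
  region — typical when a genotype cluster is missing and the spare
  component settles inside the major cloud — both take that region's
  genotype. A strict rank mapping would call roughly half of a split
  major cluster heterozygous, inflating the MAF estimate and misrouting
  the SNP.

## Model II: Dirichlet Process Gaussian mixture

For rare SNPs the number of occupied clusters is itself unknown. The DP
mixture places a Chinese-restaurant-process prior over partitions with
concentration $\alpha$, and a conjugate Normal–Wishart prior on component
parameters: precision $R_k \sim W(\nu, S^{-1})$ and mean
$\mu_k \mid R_k \sim N(m, (r R_k)^{-1})$. The indicator conditional for
sample $i$ is proportional to $n_{-i,k}$ times the component density for
an existing cluster $k$, and to $\alpha$ times the prior predictive — a
closed-form bivariate Student-t — for a new cluster
(`crp_indicator_conditional()`, `new_cluster_predictive()`). The prior on
the concentration is $1/\alpha \sim \mathrm{Gamma}(1, \text{mean } 1)$,
sampled with a log-scale random-walk Metropolis step.

**Sampler.** The reference update operations are exposed and tested
individually in the form above (instantiated parameters for existing
clusters). The compiled fitting engine, however, resamples indicators with
the component parameters *integrated out*: an existing cluster attracts a
point with weight $n_{-i,k}$ times its Normal–Wishart posterior-predictive
Student-t given its other members, the same formula that at empty
sufficient statistics gives the new-cluster prior predictive. Both schemes
target the same partition posterior, but the instantiated form mixes
poorly on unimodal data — it can split one Gaussian into two overlapping
halves whose adapted covariances lock the split in place for thousands of
sweeps — while the collapsed form merges such splits readily. Defaults are
2000 sweeps with 500 burn-in.

**Reported fit.** Label switching is avoided by reporting a *consensus
partition*: the post-burn-in sample maximizing the average pairwise
co-assignment agreement with all post-burn-in samples. Component estimates
are conjugate posterior means conditioned on that partition, and PR/APR
are computed from them exactly as in Model I. Clusters map to genotypes by
the contrast region of their means (shared regions share a genotype, as in
Model I); if more than three clusters are occupied, the three largest take
genotype labels and members of the extras are NC.

**Hyperparameter defaults** (all overridable via `dp_hyper()`):

* $m$ = data mean, $r = 0.05$ — the mean prior is a twentieth of an
  observation, so cluster means are essentially data-driven;
* $\nu = 20$, $S = 3(\nu - 3)\hat\Sigma_w$, where $\hat\Sigma_w$ is the
  pooled within-group covariance of the rough contrast clustering. Basing
  the scale on $\hat\Sigma_w$ rather than the total covariance matters:
  for a multi-cluster SNP the total covariance is dominated by
  between-cluster spread and would let clusters engulf their neighbours.
  The moderately strong $\nu$ stops sparse chance clumps from fitting
  their own tight covariance and splitting off, and the factor 3 inflates
  the prior scale just enough that a cluster's own 2–3$\sigma$ tail is
  absorbed rather than shredded, while genotype clusters six channel
  standard deviations apart still separate cleanly. These values were
  calibrated once on simulated one-, two- and three-cluster SNPs and then
  frozen.

## Model III: reference-assisted calling

The DP mixture alone under-serves *extremely* rare SNPs: by the
rich-gets-richer property, a minor cluster of one or two points tends to
be absorbed into the major cluster. Such a SNP (the T-SNP) is therefore
called jointly with a reference SNP chosen in three steps:

1. **R1** — SNPs before the T-SNP in array order with estimated MAF above
   0.15 (strict), capped at the nearest 200 predecessors;
2. **R2** — R1 candidates whose rough contrast clustering puts at least
   10% (inclusive) of observations in *each* genotype cluster;
3. **R-SNP** — the R2 candidate minimizing the cluster distance
   $D_t = \sum_k \mathrm{tr}\{(x_{kt}-\mu_{kd})
   ((\Sigma_{kt}+\Sigma_{kd})/2)^{-1} (x_{kt}-\mu_{kd})^{T}\}$, i.e. the
   summed pooled-covariance Mahalanobis form of the T-SNP's cluster
   members about the candidate's cluster means. Clusters missing in the
   T-SNP contribute zero; ties break by nearest array position, then id.

The T-SNP's rows are stacked with the R-SNP's and the DP mixture is fitted
to the augmented data; only the T-SNP rows' calls are returned. If no
candidate survives steps 1–2 the search falls back to SNPs after the
T-SNP, and failing that the SNP is called by the plain DP fit and flagged
in the run log.

## The routing rule

After an initial EM pass over every SNP, MAF is estimated by allele
counting over called samples and cluster sizes $n_{ks}$ are taken from the
calls. A SNP goes to g1 if MAF $\ge$ 0.05; otherwise to g2 if at least one
cluster satisfies $b_1 \le n_{ks} < b_2$ (defaults $b_1 = 3$, $b_2 = 10$;
empty clusters never qualify); otherwise to g3. Raising $b_1$ moves rare
SNPs from g2 to g3, raising $b_2$ the other way. The MAF used for routing
and for reference selection is the pass-1 estimate; it is not recomputed
after the pass-2 refits.

## Evaluation metrics

`call_rate()` is the percentage of observed cells called non-NC;
`concordance()` the agreement percentage over cells called by both of two
call sets; `accuracy()` the concordance against a truth table over called,
truth-covered cells. `hwe_test()` checks genotype counts per population
against Hardy–Weinberg expectations at the estimated allele frequency with
a 1-df chi-square goodness-of-fit statistic (monomorphic SNPs pass with
statistic 0); an exact heterozygote-enumeration test is available via
`method = "exact"`. SNPs failing at $p < 10^{-4}$ are counted per
population by `hwe_failures()`.

## The simulator

`simulate_snp()` draws genotypes from Hardy–Weinberg frequencies
$((1-q)^2,\; 2q(1-q),\; q^2)$ at the spec's MAF $q$ (or uses pinned
genotype counts for rare regimes), places cluster centers by (contrast,
total intensity) geometry — defaults $y = +0.8/0/-0.8$ at total intensity
2000 — adds per-channel Gaussian noise, truncates at zero, and replaces an
`outlier_frac` subset with uniform draws over the intensity bounding box
(flagged in truth). The default noise sd of 188 intensity units puts
adjacent genotype clusters about six per-channel standard deviations
apart; the default outlier fraction is 1%. `make_rare_snp_fixture()` pins
minor-homozygote cluster sizes to the g2 regime ([3, 10)), the g3 regime
([0, 3)) or monomorphic, and `study_panel_specs()` assembles the standard
validation panel: 70 common SNPs (MAF uniform on [0.2, 0.4]) placed ahead
of 20 g2-regime and 10 g3-regime SNPs, 300 samples.

What the simulator does *not* emulate: probe/beadpool replicate structure,
batch and plate effects, intensity-dependent (heteroscedastic) noise,
cross-hybridization shifts, or cluster positions varying across SNPs.
Passing tests therefore demonstrate correctness of the statistical
machinery under the models' own assumptions, not performance on any real
array product.

## Validation problem sizes

The test suite exercises: EM update correctness against brute-force
oracles on 5–10-point fixtures; EM mean recovery over 20 replicates of
600-sample three-cluster SNPs; DP indicator conditionals against direct
enumeration for up to 6 points and the prior predictive against $10^6$
Monte-Carlo draws; DP model selection over 10 seeds for each true cluster
count in $\{1,2,3\}$ at 150 samples; reference assistance against the
plain DP fit on 20 replicates of rare SNPs with a two-point minor cluster;
and the full procedure on a 100-SNP $\times$ 300-sample panel. These sizes
make the whole suite run in a few minutes on one core while keeping every
statistical check meaningfully powered.

## Known limitations

* Intensities are modelled raw, with no background correction or affine
  normalization; arrays needing normalization should be preprocessed
  upstream.
* Genotypes are unphased cluster labels (AA/AB/BB relative to the two
  channels); no reference alleles, no VCF emission, no binary IDAT/GTC
  parsing.
* The DP cluster count is a posterior summary via the consensus
  partition; on genuinely ambiguous data different seeds can report
  different occupied-cluster counts.
* Reference search is confined to the same array ordering (no
  cross-chromosome search) and uses a single reference SNP; no
  multi-reference augmentation.

## A worked example

```{r example, eval = FALSE}
library(mdcall)

specs <- study_panel_specs(n_common = 20, n_g2 = 4, n_g3 = 2, n = 200,
                           seed = 11)
panel <- simulate_panel(specs, populations = 2, seed = 11)
fit <- run_md(panel$dataset, md_config(seed = 11))
summary(fit)
accuracy(fit, panel$truth)
plot(fit)
```
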