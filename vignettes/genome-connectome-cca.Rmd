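---
title: "Modes of genome-connectome covariation: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modes of genome-connectome covariation: model, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocca)
```

## The scientific question

Psychiatric disorders share genetic risk and clinical features across
diagnostic boundaries. One way to look for a shared neurobiological
substrate is to ask whether a weighted combination of established risk SNPs
covaries, across healthy subjects, with a weighted combination of
white-matter connection strengths — a *mode of genome-connectome
covariation*. `neurocca` implements that analysis as a reusable pipeline:

1. select analysis SNPs from a GWAS-catalog-like table
   (genome-wide significance `p < 5e-8`, LD proxies with `r² > 0.8` for
   SNPs absent from the genotype data);
2. residualize each of the `n_nodes (n_nodes - 1) / 2` connection
   strengths on age, sex, scanner and genetic ancestry factors (GAFs);
3. reduce both blocks to `K` principal components (default 100, centered
   but not variance-normalized) and fit canonical correlation analysis;
4. calibrate mode significance with a max-statistic permutation test and
   compute per-feature *canonical strengths* (feature-score correlations)
   with per-feature permutation p-values and grouped Benjamini-Hochberg
   FDR;
5. relate the connectomic canonical score to polygenic risk scores
   (clumping + thresholding over a dense p-threshold grid, permutation
   corrected), to behavior variables (permutation-based combined
   probability test on one-tailed p-values), and to mediation of genetic
   risk through the connectome;
6. stress the result with a robustness battery (split-half, PC-count
   sweep, SNP subsets, subject exclusion, network summaries).

Because the cohorts such analyses run on are controlled-access, the package
ships a synthetic-data generator that emulates every input and plants a
joint latent mode of known canonical correlation, so every downstream claim
is testable end to end.

## The generative model

`sim_config()` fixes the study conditions. Defaults mirror a pediatric
imaging-genetics cohort: 678 subjects, 1877 risk SNPs, a 120-region
parcellation (7140 connections), a planted canonical correlation
`rho = 0.74`, and a behavior questionnaire observed in a 117/678 subsample.

The planted structure is rank one on each side (a single latent per
domain, because subsequent modes are assumed — and simulated — to be
null; a multi-block extension would only change `simulate_joint_mode()`):

* genetic latent `g`: a standardized weighted sum of causal-SNP dosages;
* connectomic latent `m = rho * g + sqrt(1 - rho²) * e`, standardized, so
  the population correlation of the latents is exactly `rho` (`rho = 1`
  together with positive edge noise is rejected as unattainable);
* connection strengths: baseline fascicle-FA drawn `Uniform(0.2, 0.8)` —
  the lower bound matches the tractography stopping rule, so retained
  connections always exceed 0.2 — plus `effect * m` on the signal
  connections, linear covariate effects, and i.i.d. Gaussian noise
  (`noise_sd = 0.02` fFA units). Matrices are symmetric with a zero
  diagonal by construction.

### Why causal SNPs form LD blocks

The one structural choice that deserves emphasis: by default the causal
SNPs are organized into LD blocks ("risk loci", `causal_ld = list(size =
10, r2 = 0.8)`), with the latent weight shared across a locus. The reason
is geometric. The pipeline compresses the genotype block to `K` principal
components before CCA. A sparse weight vector over *independent* SNPs is an
essentially random direction in SNP space, and a random direction retains
only about `K/p` of its variance under a rank-`K` PCA projection — with
1877 SNPs and 100 components, 5%, which makes any planted correlation
invisible to CCA regardless of its size. Real risk SNPs, however, tag
extended LD regions: a locus of correlated SNPs is a *variance-dominant*
direction that PCA keeps. Organizing the causal SNPs into loci (background
SNPs stay independent) therefore reproduces the regime in which this
analysis can work at all, and is the package's explicit modelling choice
rather than an incidental convenience. Setting `causal_ld = NULL` restores
fully independent causal SNPs and demonstrates the attenuation.

### Parameters the paper-like design does not pin down

Where no study value exists, the generator fixes one realistic value once:

| parameter | default | units / meaning |
|---|---|---|
| `n_causal_snps` | 100 | SNPs carrying latent weight (10 loci of 10) |
| `n_signal_connections` | 200 | connections loaded by `m` |
| `connection_effect_mean/sd` | 0.03 / 0.01 | absolute edge loading, fFA units |
| `prop_hypo` | 0.7 | fraction of negative loadings (hypoconnectivity) |
| `noise_sd` | 0.02 | i.i.d. edge noise, fFA units |
| `confound_effect_sd` | 0.01 | per-edge covariate coefficients, fFA units |
| `n_scanners`, `n_gafs` | 3, 4 | confound dimensionality |
| `gwas_base_n` | 5e4 | base-GWAS sample size scaling summary-stat SEs |
| `behavior_noise_sd` | 1 | residual SD of continuous behaviors |

The per-edge effect-size distribution is deliberately a config knob, not a
claimed empirical quantity. Behaviors use separate noise from the edges
(`behavior_noise_sd` vs `noise_sd`) because the two live on different
scales; a single shared noise value would be realistic for neither.

One master seed drives named sub-seeds (`sim_seeds()`), so regenerating
one component (say, behaviors) never perturbs another.

### What the generator does *not* emulate

Real LD from reference panels, Hardy-Weinberg deviations, genotyping
missingness patterns, site-by-age interactions, non-Gaussian fFA noise,
and heavy-tailed behavior distributions. Tests passing on this synthetic
family show the pipeline's *statistical machinery* is correct and
calibrated; they do not certify performance on any real cohort.

## Inferential machinery

**CCA.** Both centered blocks are QR-orthogonalized and the singular value
decomposition of `Qu' Qv` gives all canonical correlations at once;
canonical scores are standardized to unit variance. On PCA scores the
problem is well-conditioned, so no ridge term is used. Row permutations
commute with centering and QR, which is why the permutation loop can reuse
the observed bases and costs one small matrix product plus one SVD per
permutation.

**Max-statistic permutation test.** The subject rows of one block are
shuffled relative to the other (which block is shuffled is immaterial; a
test checks the null distributions agree), CCA is refit, and the largest
absolute canonical correlation is recorded. Every observed mode is compared
against this max-r distribution, controlling the familywise error across
modes. P-values use the add-one convention `(1 + exceedances) / (B + 1)`,
so the smallest attainable p at `B = 10000` is `1e-4` and zero p-values
cannot occur.

**Canonical strengths.** Per-feature correlations with the mode-1 score
are recomputed inside every permutation, giving each feature its own null
(streamed as exceedance counters to bound memory; a pooled-null variant is
available via `strength_pvalues(pooled = TRUE)`). BH-FDR is applied to all
connections as one group and to genetic strengths within each phenotype.
Mode-1 nulls are used because mode 1 is the mode under test; the
variance-explained null (mean squared strength per permutation) comes for
free from the same counters.

**Variance explained** is defined as the mean over features of the squared
feature-score correlation, computed on the pre-PCA adjusted block. This is
one concrete operationalization of "variance explained by the mode
relative to the null"; the ratio reported is observed / mean(null).

**Sign convention.** CCA modes are sign-indeterminate. `orient_mode()`
flips both score vectors jointly so the mean canonical connection strength
is nonpositive — higher canonical scores then mean globally weaker
connectivity, matching the hypoconnectivity orientation the synthetic
default (70% negative edge loadings) plants. Any reference vector can
override this.

**PRS.** Scores are plain weighted dosage sums (`sum beta_j * dosage_ij`
over SNPs with `p_j <= threshold`); averaging per allele would only rescale
them, and the downstream `delta R²` is invariant to affine maps. Missing
dosages impute as twice the sample allele frequency. Clumping is greedy by
ascending p with default `r² = 0.1` over a user-supplied LD table; with no
table nothing is clumped (the synthetic default has independent
non-causal SNPs). The threshold grid runs from `5e-8` in steps of `5e-5`
up to the base study's optimal threshold. The permutation correction
shuffles the target, repeats the whole scan, and compares best p-values;
computationally each permutation reduces to inner products because the
full-model t-test of the PRS coefficient equals the partial-correlation
t-test after residualizing both sides on the covariates (an identity the
test suite verifies against `lm()`).

**Behaviors and mediation.** Behavior variables are filtered (more than
ten observations, strictly; minority level at least 5% for dichotomous
variables) and adjusted for age and sex — OLS residuals for continuous
variables, response residuals `y - p̂` from a logistic fit for dichotomous
ones (deviance residuals behind a switch; separation falls back to
linear-probability residuals with a warning). One-tailed p-values for
positive correlation with the connectomic score feed Fisher's
`T = -2 Σ log p`, calibrated by shuffling the score and recomputing the
whole p-set so the dependence between behaviors is preserved. Mediation
uses the two-OLS-equation form (`m ~ x`; `y ~ x + m`) with the Sobel
standard error for the indirect effect `a·b` — the single-mediator,
observed-variable case in which full SEM software reduces to exactly these
regressions — and its combined test permutes the *mediator* against the
`(x, y)` pairs, the minimal scheme that severs both the `a` and `b` paths
while preserving the direct x-y relation. Input p-values of zero are
clamped to `1/(B+1)` before logs.

**Robustness battery.** Every scenario (split halves, PC counts 50-150,
SNP subsets, subject exclusion, genotype-side ancestry adjustment) is an
input transformation around the single `run_cca_pipeline()` code path.
Reproduced strength vectors are sign-aligned (the reported correlation is
the absolute value) because CCA sign is arbitrary across refits. Hubs sum
the significant incident canonical connection strengths per node
(mean-aggregation behind a flag); negative sums are hypoconnectivity hubs,
exact zeros class as none.

## Numerical choices and degenerate inputs

* Connectome symmetry is enforced within `1e-10`, naming the worst entry
  and subject; NaN entries are rejected.
* Confound designs are checked for rank; collinear columns are named.
  Residualization is exact QR orthogonalization, so post-adjustment
  feature-covariate correlations sit at machine precision (tested against
  `1e-8`).
* Zero-variance features are excluded from strengths, variance-explained
  means and PCA inputs with messages; zero-variance CCA input columns are
  an error.
* Proxy ties in SNP selection break lexicographically; "over ten
  observations" reads strictly `> 10`, "at least 5%" reads `>= 5%`.
* Edge ordering is row-major upper triangle with 0-based internal column
  positions and 1-based node labels in all files.

## Problem sizes used in the shipped checks

The test suite exercises the machinery at reduced but non-trivial sizes
chosen to keep the full run in the tens of minutes on one core: type-I
calibration of the mode test uses 200 replicates of independent 200 x 20
blocks at `B = 499`; parameter recovery uses 20 replicates of the planted
`rho = 0.7` design (500 subjects, 500 SNPs, 60 nodes, `K = 20`,
`B = 999`); the robustness battery runs at 600 subjects, 200 SNPs and 60
nodes. `scripts/acceptance.R` runs the full default study
(678 x 1877 x 7140, `K = 100`, `B = 10000` for modes and PRS, 1000 for
behavior/mediation) in a few minutes.

## Known limitations

* The permutation scheme is unrestricted (no exchangeability blocks per
  scanner, no Freedman-Lane covariate-aware variant).
* Sparse or regularized CCA variants are out of scope; with `K`
  components per block the classical estimator is already stabilized by
  the PCA step.
* Mediation offers Sobel inference only (no bootstrap CIs, no latent
  variables, single mediator).
* PRS handles exact effect-allele matches only; strand-ambiguous or
  flipped alleles are dropped, not resolved.
* With very strong planted connectomic signal, a genotype subset carrying
  *no* causal SNPs can still reproduce parts of the network pattern
  through the dominant connectome principal component; the SNP-subset
  scenario is therefore reported with a permutation p rather than treated
  as a hard null.
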