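---
title: "Twin-cohort smoking methylation and expression analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-cohort smoking methylation and expression analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipotwin)
```

## What the package does

`adipotwin` implements an integrated analysis of smoking effects on DNA
methylation and gene expression in a twin cohort:

1. **EWAS / TWAS**: per-site linear mixed models contrasting current and
   never smokers, with family and zygosity random effects and
   Benjamini–Hochberg FDR control;
2. **integration**: gene-level overlap of differentially methylated sites
   (DMS) and differentially expressed genes (DES), and covariate-adjusted
   Spearman correlation between paired methylation and expression levels;
3. **cessation reversal**: a nonparametric statistic quantifying how many
   ex-smokers have reverted toward never-smoker levels, by quit-year bin;
4. **prediction**: repeated stratified split-sample AUC for classifying
   current versus never smokers from marker levels;
5. **cis-meQTL mapping**: per-site regression of covariate-adjusted
   residuals on nearby SNP dosages, keeping the top SNP;
6. **adiposity phenotypes**: marker–phenotype main and interaction models,
   longitudinal cessation categories, and prediction of future
   visceral-fat change after quitting.

Because the motivating data are individual-level human measurements, the
package ships a **synthetic twin-cohort generator** whose defaults encode
the cohort structure the analyses assume. Every stage is exercised and
tested end-to-end on generated data with known ground truth.

## The association model

For each CpG site (or gene), methylation beta values (or log abundances)
are rank inverse-normal transformed per site and modelled as

$$ y_{ij} = \beta_0 + \beta_s\, \text{smoke}_{ij} + \mathbf{x}_{ij}^\top
\boldsymbol\gamma + a_{f(ij)} + b_{m(ij)} + \varepsilon_{ij}, $$

where `smoke` is 1 for current and 0 for never smokers (ex-smokers are
excluded from this contrast), $\mathbf{x}$ collects age, BMI, alcohol
intake and batch, $a_f \sim N(0, \sigma^2_F)$ is a family random
intercept, and $b_m \sim N(0, \sigma^2_M)$ is an extra pair intercept
active only within MZ pairs — this is how "family and zygosity" enter as
random terms: DZ pairs share $a_f$ only, MZ pairs share $a_f + b_m$.
Significance comes from a 1-df likelihood-ratio test of the full model
against the null without `smoke`, both fitted by maximum likelihood
(`lme4`). A Wald-F approximation is available via
`model_spec(p_method = "f")`; the two agree closely for a single binary
term at these sample sizes. When no random term is identifiable (an
all-singleton cohort), the engine reduces exactly to OLS — the test suite
checks this equivalence against a plain `lm()` oracle.

Numeric covariates are centred and scaled inside the design builder: this
leaves the exposure coefficient and test untouched and avoids
conditioning problems in the mixed-model optimizer. For scan speed, one
full and one null model template are fitted per matrix and refitted with
each site's outcome (`lme4::refit`), which is exact because the design is
shared across sites; refit failures fall back to fresh fits. The
equivalence of the fast path and fresh per-site fits is asserted in the
tests.

Genome-wide significance is controlled at FDR 1% with the
Benjamini–Hochberg step-up procedure (`bh_fdr()`, backed by
`stats::p.adjust`); the FDR procedure is not named in the motivating
analysis, and BH is the standard choice. `bonferroni_threshold(alpha, m)`
reports `alpha/m` to three significant figures for fixed-panel lookups.

Direction conventions follow the reference table shipped with the
package: a **positive** coefficient denotes **hypermethylation in current
smokers**; a coefficient of exactly zero is counted as hyper (an
arbitrary, documented, probability-zero tie rule).

## The reversal statistic

For a site with covariate-adjusted residual medians $m_c$ (current
smokers) and $m_n$ (never smokers), the reversal threshold at fraction
$f$ (default 0.25) is

$$ t = m_n - f\,(m_n - m_c), $$

i.e. an ex-smoker counts as *reversed* once it has covered at least
$1-f$ of the gap toward the never-smoker median (overshoot counts). With
medians $-0.234$ and $0.037$ the threshold is $-0.031$ and the gap
$0.271$. The phrase "revert to 25% of the change" could also be read as
*covering* 25% of the gap; the worked numbers above force the
remaining-gap reading, which is the default. The alternative is available
via `reversal_spec(gap_covered = TRUE)` for sensitivity analysis.
Reversal rates are reported per quit-year bin (defaults `< 1`, `1–5`,
`> 5` years); empty bins are reported missing, never as zero. Medians
are taken on residuals from one joint covariate adjustment excluding
smoking status (`residualize_matrix()`).

## Prediction

`repeated_split_auc()` draws a stratified training set of fixed
composition (default 27 current + 145 never smokers), fits a plain
logistic regression on the features, scores all held-out subjects, and
averages the validation AUC over repeats (default 1000). A *non-mixed*
logistic model is used deliberately: prediction on held-out families
cannot use their BLUPs, so family random effects add nothing to
out-of-sample scores. Training fits with complete separation are refitted
with a small ridge penalty (IRLS with an L2 term, intercept unpenalized,
$\lambda = 10^{-3}$) and counted. The AUC itself is the Mann–Whitney
statistic with ties counted one half; tests verify it against pairwise
enumeration and an independent ROC implementation.

## cis-meQTL mapping

Following the two-step design, covariates (including family structure)
are first absorbed by the mixed-model residualization; the residuals are
then regressed on each SNP within ±100 kb of the site by simple linear
regression, keeping the minimum-p SNP per site (significance threshold
$5 \times 10^{-5}$). The cis window is not stated in the motivating
analysis; ±100 kb is the package default and configurable. The window is
a closed interval. Monomorphic SNPs are skipped and counted; sites with
no cis SNP are reported untested rather than dropped. Twin relatedness
slightly inflates the null minimum-p distribution; this residual-on-SNP
design mirrors the two-step description and is left uncorrected,
as the tests document.

## Phenotype analyses

`assign_cessation_category()` classifies longitudinal smoking
trajectories into S-S, S-E, E1-E5 (1–5 quit years at the first time
point), E5+ and N-N; relapse paths and ex-smokers with under one quit
year are `unclassified` (the "recent ex-smoker" boundary follows the
category label; the prose gives both "1–4" and "1–5" years).
`predict_future_change()` contrasts the exposure-change group (S-E ∪
E1-E5) against everyone else: it fits
`Δphenotype ~ marker * group (+ covariates)`, reports the
full-vs-reduced interaction p-value, and the marker's unadjusted $R^2$
(as a percentage) within the exposure-change group — "variance
explained" is deliberately the marginal, unadjusted $R^2$ of the marker
alone, which is what a within-group scatterplot shows. Panel significance
is computed as `0.05 / m` for the panel actually tested, never
hard-coded.

## The synthetic cohort generator

Defaults mirror the motivating study design: 84 MZ pairs + 112 DZ pairs +
150 singletons (542 female twins), 54 current / 197 ex / 291 never
smokers, ex-smoker quit years gamma-distributed with mean 24.8 and SD
13.2 years (truncated at 0.25 years — quit for at least three months),
2,000 probes, 1,000 genes, 5,000 SNPs.

Effects are injected on the **logit (latent) scale**: the latent value of
probe $j$ in subject $i$ is

$$ \ell_{ij} = \mu_j + a_{f(i)} + b_{m(i)} + c_{\text{batch}(i)} +
\delta_j\, s_\text{tot}\, d_i + \beta^{\text{QTL}}_j s_\text{tot}
(g_{ij} - \bar g_j) + \varepsilon_{ij}, $$

with beta value $\text{logit}^{-1}(\ell_{ij})$ — guaranteed strictly
inside $(0,1)$. The smoking multiplier is $d_i = 1$ for current smokers,
$\exp(-q_i/\tau)$ for ex-smokers with $q_i$ quit years, and 0 for never
smokers: exponential decay reproduces the qualitative reversal dynamics
(rapid early reversal, then plateau). Effect sizes $\delta_j$ are in
units of the total latent SD $s_\text{tot}$ (default variance components
0.30 family, 0.20 extra-MZ, 0.05 batch, 0.45 residual, so
$s_\text{tot} = 1$). Defaults: 100 signal probes at 1.5 latent SD, 90.5%
of them negative (hypo-methylation in smokers); decay constants
$\tau_\text{meth} = 15$ y and $\tau_\text{expr} = 1.5$ y encode the
"stronger on expression but longer-lasting on methylation" asymmetry —
with $\tau = 1.5$, an ex-smoker one year out retains half the expression
effect, while with $\tau = 15$ the methylation effect is still 94%
intact.

Expression is generated on a log-abundance scale with the same component
structure and exponentiated (non-negative, RPKM-like). Five designated
*coupled* genes subtract $\kappa$ (default 0.5) times the centred latent
of a paired probe from their expression latent, inducing the negative
methylation–expression correlation of regulatory smoking signals; coupled
probes are hypo-methylated and coupled genes up-regulated in current
smokers, so the gene-level overlap is direction-concordant by
construction.

Genotypes use **explicit parental transmission**: per family two parental
diplotypes are drawn (allele frequencies uniform on (0.05, 0.5), i.e. all
SNPs common), MZ twins receive identical transmissions and DZ twins
independent ones — giving exact MZ identity and expected DZ dosage
correlation 0.5 without any tuning. SNPs are anchored round-robin at
probe positions (offsets up to 50 kb) so every probe has cis SNPs; a
configurable fraction of probes (default 10%) receives a cis effect of
0.5 latent SD per allele from its anchored SNP.

Longitudinal phenotypes (VFM, TFM, AGR, BMI at two time points ~5.1 y
apart) include a positive adiposity gain in subjects who quit recently
(S-E and E1-E5) and a marker-by-group interaction at one designated probe
and one designated gene: within the exposure-change group the VFM change
is `interaction_beta` (VFM units per marker SD, default 0.2) times the
standardized marker level. Against the residual change SD of 0.25, the
default puts the marker's within-group variance explained near 40%,
the scale of the reported future-visceral-fat interactions. Exact category
sizes (default 12/5/13/92/124, combining to the 18 vs 228 contrast) are
honoured when the simulated pools allow.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses assume — twin
variance components, bounded beta values, decaying smoking effects,
cis genetic effects, negative methylation–expression coupling, group
composition. It does **not** emulate probe-type chemistry, background
fluorescence, cell-type composition, genomic autocorrelation between
neighbouring probes, LD between SNPs, or realistic minor-allele spectra.
Passing tests therefore demonstrate that the estimators recover the
effects they target under the assumed model, not that the model captures
every property of array or RNA-seq data.

## Numerical and design choices

* **Rank inverse-normal transform** uses the Blom offset 3/8
  ($\Phi^{-1}((r - 3/8)/(n + 1/4))$), average ranks for ties, missing
  values passed through; the offset is configurable. Rank-INT is applied
  per site to the raw values before covariate adjustment.
* **QC**: sites with more than 1% masked subjects and sites on
  chromosomes X/Y are removed; the filter is idempotent and order
  preserving; per-site complete-case analysis handles any remaining
  missingness.
* **Spearman p-values**: exact (or Edgeworth, under ties) small-sample
  distribution below n = 20 via `stats::cor.test`, t approximation
  otherwise; verified against full permutation enumeration at n = 6.
  Groups with fewer than five subjects report rho with the p flagged
  unreliable. Group-wise correlations recompute ranks within the group.
* **Degenerate inputs**: constant vectors refuse the rank transform;
  equal group medians make reversal undefined and the site is skipped
  with a warning; monomorphic SNPs are skipped; one-class AUC input is an
  error; rank-deficient designs name the collinear columns.
* **Determinism**: a single global seed is expanded into fixed per-stage
  substreams, so disabling one pipeline stage never changes another
  stage's draws; rerunning a configuration reproduces every output table
  byte for byte.

## Problem sizes used by the tests

The packaged checks run the full synthetic study at 542 subjects, 2,000
probes, 1,000 genes, 5,000 SNPs and 1,000 prediction splits (a few
minutes on one core), plus targeted smaller simulations: null-calibration
EWAS at 2,000 probes; 200-replicate comparisons of first-year reversal
rates between expression and methylation; recovery checks for injected
cis-meQTLs and coupled genes. The first-year reversal comparison uses a
test cohort with quit-year mean 1.5 years and 400 ex-smokers: under the
default quit-year distribution (mean 24.8 y) essentially no ex-smoker has
quit within a year, so the first-year bin would be empty — the default
describes the cohort history, the test configuration probes the early
reversal dynamics.

## Known limitations

* The mixed-model engine assumes a shared design across sites for its
  fast path; heavy, site-specific missingness degrades it to per-site
  fits (correct, slower).
* The overlap of FDR-controlled DMS and DES is a set intersection: at
  FDR 1% an occasional false-positive site can land on a significant
  gene, so "exactly the coupled genes" holds with high but not full
  probability across seeds.
* No trans-QTL scan, LD pruning, cell-type deconvolution or
  normalization (BMIQ-class preprocessing is assumed upstream of the
  package's entry point).
* The prediction module reports discrimination (AUC) only — no
  calibration, no hyperparameter tuning.
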