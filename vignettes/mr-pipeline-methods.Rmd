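---
title: "Methods: summary-statistics Mendelian randomization with mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics Mendelian randomization with mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stonemr)
```

## The problem and the model

Observational associations between adiposity and kidney stone disease are
vulnerable to confounding and reverse causation. Two-sample Mendelian
randomization (MR) sidesteps both by using genetic variants as instruments:
if a variant affects the outcome only through the exposure (exclusion
restriction), the ratio of its outcome association to its exposure
association estimates the causal effect. `stonemr` implements the full
summary-statistics workflow for one binary outcome (kidney-stone-like,
effects on the log-odds scale), one or more continuous exposures
(BMI/WHR-like, SD units) and a continuous mediator (serum-calcium-like).

Per SNP $j$, write $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) for the exposure
association and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) for the outcome
association after harmonization to a common effect allele. The estimators:

* **Wald ratio** $\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$, first-order
  SE $\sigma_{Yj}/|\hat\beta_{Xj}|$ (a second-order version adding the
  exposure-uncertainty term is available behind a flag).
* **IVW**: weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the
  origin with weights $\sigma_{Yj}^{-2}$, equivalently the inverse-variance
  weighted mean of Wald ratios. The SE uses multiplicative random-effects
  inflation floored at one, $\mathrm{SE} = \mathrm{SE}_{\mathrm{fixed}}
  \cdot \max\{1, \sqrt{Q/(k-1)}\}$, with Cochran's $Q$ over the ratios under
  first-order weights. The floor makes the estimator exact-fixed-effects
  under homogeneity and conservative under heterogeneity.
* **MR-Egger**: the same weighted regression with an intercept, after
  orienting each SNP so $\hat\beta_{Xj} \ge 0$ (without a fixed orientation
  the intercept has no meaning). A non-zero intercept estimates the average
  directional pleiotropic effect; the slope is the pleiotropy-adjusted
  causal estimate.
* **Weighted median**: the inverse-variance weighted median of Wald ratios,
  interpolated at cumulative weight 0.5; consistent when at least half the
  weight is on valid instruments. Its SE comes from a seeded parametric
  bootstrap (default 1000 resamples) of both association vectors.
* **Contamination mixture**: each SNP's ratio is modelled as either valid
  (normal around the causal effect $\theta$ with its first-order SE) or
  invalid (normal around zero with variance inflated by $\psi^2$); the
  profile log-likelihood over a $\theta$ grid takes the better of the two
  per SNP. The estimate is the grid argmax and the 95% confidence set is
  the $\{\theta: \ell(\theta) \ge \ell_{\max} - 1.92\}$ slice, which can be
  a union of disjoint intervals — reported as such.

**Estimator selection** follows the pre-specified rule: when the Egger
intercept is compatible with zero ($p \ge 0.05$) the IVW estimate is the
estimate of best fit; otherwise the Egger slope is. The boundary is strict:
$p = 0.05$ selects IVW.

## Meta-analysis, instruments, harmonization

Cohorts are pooled per variant by fixed-effects inverse-variance weighting
of log odds ratios, $\hat\beta = \sum w_i b_i / \sum w_i$,
$w_i = s_i^{-2}$, with Cochran's $Q$ and
$I^2 = \max\{0, (Q - \mathrm{df})/Q\} \times 100$. Variants with $I^2$
strictly above 75 are excluded; variants present in a single cohort pass
through unchanged with $I^2 = 0$. Printed "OR (95% CI)" records are
consumed via $\beta = \ln \mathrm{OR}$,
$s = (\ln \mathrm{hi} - \ln \mathrm{lo}) / (2 z_{0.975})$. A cohort-level
MAF < 0.01 pre-filter is available (on by default in `meta_analyse`),
matching common release practice.

Instruments are associations with $p < 5\times10^{-8}$ (strict), clumped
greedily: the lowest-p unclaimed SNP becomes an index and discards unclaimed
SNPs with $r^2 \ge 0.01$ to it within 10 Mb; ties in p break by chromosome,
position, then identifier. Strength is summarised by
$R^2_j = 2\hat a_j^2 \mathrm{MAF}_j (1-\mathrm{MAF}_j)$ (exposure effects in
SD units), total $R^2 = \sum_j R^2_j$, and
$F = R^2 (N - 1 - K) / ((1 - R^2) K)$.

Harmonization aligns each further trait to the exposure's effect allele:
label swaps negate the beta and complement the frequency; strand flips
(allele complements) are reconciled silently. Palindromic SNPs (A/T, G/C)
are undecidable from alleles, so the strand is inferred from allele
frequencies — discordant frequency sides reveal a complementary-strand
report and undo the naive alignment. SNPs whose frequency is within 0.08 of
0.5 in either trait are dropped as ambiguous; the window is configurable,
and 0.08 is the conventional compromise between losing common variants and
mis-orienting them. Indels and irreconcilable allele pairs are dropped with
a logged reason. Matching is by variant identifier; position disagreements
warn rather than fail (files from different builds should be reconciled
upstream; liftover is out of scope).

## Sensitivity analyses

* **Cochran's Q** over ratios flags instrument heterogeneity for every fit.
* **Leave-one-out** refits the estimator omitting each SNP; a SNP whose
  omission flips the sign or moves the estimate by more than one full-set SE
  is flagged as a driver.
* **Steiger directionality**: per SNP, variance explained in the exposure
  ($2\beta^2\mathrm{MAF}(1-\mathrm{MAF})$ for SD-scale traits;
  $Z^2/(Z^2+N)$ for the log-odds outcome — the standard approximation when
  only summary data exist) is compared between traits; a SNP supports
  exposure → outcome only if it explains strictly more variance in the
  exposure. The p-value uses Fisher's z for independent correlations, which
  is what the two-sample setting gives. Filtering keeps
  direction-consistent SNPs and refits.
* **BH-FDR** adjusts the family of IVW p-values across the configured
  screen (default family: all exposures against one outcome).

## Multivariable MR and mediation

With several exposures, the outcome effects are regressed on the matrix of
exposure effects (no intercept, weights $\sigma_{Yj}^{-2}$); each
coefficient is a direct effect conditional on the co-exposures. Exposure
columns that are exactly zero carry no instrument strength and are dropped
with an `NA` estimate (this also makes the nested single-exposure case
reduce to univariable IVW); genuinely collinear columns raise an error
naming the exposures. The residual-based SE inflation mirrors the IVW
convention.

The mediation decomposition is the product method: with total effect $c$
(exposure → outcome), $A$ (exposure → mediator) and $B$ (mediator → outcome
adjusted for the exposure, taken from the multivariable fit), the indirect
effect is $A \times B$ with delta-method variance
$A^2\mathrm{var}(B) + B^2\mathrm{var}(A)$, and the proportion mediated is
$A B / c$ with the corresponding delta-method SE (covariances across the
three fits are ignored — they come from separate instrument sets, and the
simulation-based coverage check in the test suite supports the
approximation). The difference method $c - c'$ is reported alongside; the
product method is primary. The decomposition is invariant to rescaling the
mediator's units ($A \to sA$, $B \to B/s$), so mmol/L-versus-SD ambiguities
in inputs affect $A$ and $B$ individually but never the indirect effect or
the proportion.

## The synthetic-data generator

`simulate_sumstats()` emulates the two-sample, optionally two-cohort
setting directly at the summary-statistics level (no individual-level
genotypes — this matches what the estimators consume and keeps a full
calibration study at seconds of runtime). The structural model is
exposure → mediator → outcome with direct effect $c'$, paths $A$ and $B$:

* instrument SNPs: $\gamma_j \sim N(0, \sigma_\gamma^2)$ on the exposure;
* mediator-specific instruments: $\eta_j \sim N(0, \sigma_\eta^2)$ on the
  mediator. These are essential, not decorative: if the mediator's only
  genetic signal is $A\gamma_j$, its effect column is exactly proportional
  to the exposure's, multivariable MR is unidentified (only $c' + AB$ is
  estimable), and no estimator could recover $(c', B)$. Real mediators such
  as serum calcium have their own loci, which is what $\eta_j$ encodes;
* invalid instruments: a fraction of exposure instruments receive a direct
  outcome effect $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$, applied on
  the exposure-increasing allele coding
  ($\mathrm{sign}(\gamma_j)\,\alpha_j$). Allele coding is arbitrary, so a
  fixed-sign $\alpha$ on raw codings washes out under Egger orientation and
  "directional" pleiotropy would be undetectable by construction; applying
  it on the oriented coding makes $\mu_\alpha \ne 0$ directional in the
  sense the Egger intercept estimates;
* optional reverse-causal block: SNPs with direct outcome effects
  $\delta_j$, transmitted to the exposure as
  $\mathrm{reverse\_path}\cdot\delta_j$ — the target population for Steiger
  filtering.

True marginal effects are exposure $\gamma_j$, mediator
$A\gamma_j + \eta_j$, outcome
$(c' + AB)\gamma_j + B\eta_j + \mathrm{sign}(\gamma_j)\alpha_j + \delta_j$.
Observed effects add independent normal noise with
$\mathrm{se} = (2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$ for SD-scale
traits and $(2\,\mathrm{maf}(1-\mathrm{maf})\,n\,v(1-v))^{-1/2}$ for the
binary outcome with case fraction $v$; two-cohort mode redraws the outcome
noise per cohort. Everything is deterministic given the seed.

Defaults are fixed once as the stated world: $\sigma_\gamma = \sigma_\eta =
0.05$ SD per allele (per-SNP variance explained around 0.1%, the scale of
lead adiposity and serum-biochemistry loci; 100 instruments then explain
roughly 10% of the exposure, in line with modern anthropometric GWAS), MAF
uniform on (0.05, 0.5), $n = 10^5$ per trait, case fraction 0.5
(case-control-like outcome sample), and $(c', A, B) = (0.1, 0.5, 0.2)$ so
that half the total effect is mediated.

**What a green test does and does not establish.** The generator draws
independent SNPs (LD enters only through the separate block-diagonal
`simulate_ld()` used to exercise clumping), simulates no confounding beyond
the pleiotropy term, no sample overlap between the exposure and outcome
GWAS, no liability-scale subtleties for the binary trait, and no selection
effects. Parameter recovery and calibration under this model verify the
estimators and their plumbing — they do not certify behaviour under
correlated instruments, population stratification, or winner's curse
(which the pipeline tests do exhibit when instruments are selected within
the simulated exposure GWAS, as a real analysis would).

## Numerical choices and edge cases

* Contamination mixture: $\psi$ defaults to 1.5 × SD of the Wald ratios and
  the grid to 1/1000 of the padded ratio range; both are conventions, not
  reproductions of any published configuration, and are configurable (an
  explicit grid can be supplied, which the oracle-equivalence tests use).
* Weighted median: bootstrap seeded from the run configuration; the RNG
  state of the caller is saved and restored.
* Clumping ties in p break deterministically by (chromosome, position,
  identifier); candidates missing from the LD matrix are treated as
  unlinked and logged.
* $I^2$ is floored at 0; single-study variants report $Q = 0$,
  $\mathrm{df} = 0$, $I^2 = 0$.
* p-values from the generator are floored at the smallest positive double
  so they stay in $(0, 1]$.
* Degenerate inputs fail loudly: zero exposure effect in a Wald ratio,
  fewer than 2/3 SNPs for IVW/Egger-class estimators, non-positive SEs,
  empty variant intersections, $R^2 \ge 1$, rank-deficient MVMR designs.
* Sensitivity stages (leave-one-out, Steiger) run conditionally on post-FDR
  significance, with an `always_sensitivity` override.

## Known limitations

No correlated-instrument (generalized) IVW, MR-PRESSO, or mode-based
estimators; no liability-scale conversion for the binary outcome; no LD
computation from genotype panels (LD is supplied or simulated); single
mediator per decomposition; FDR family sizes are user-defined rather than
inferred.
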