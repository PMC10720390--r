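---
title: "Methods: joint rare-variant and PRS risk modelling"
author: "polyrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint rare-variant and PRS risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models and rules it implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where more than one
reasonable convention exists.

## 1. Variant classification

A rare variant (minor allele frequency < 1%, strict) is classified P/LP/D
(pathogenic / likely pathogenic / deleterious) when

* its consequence is protein-truncating — frameshift indel, stop gain, or
  loss of an essential splice donor/acceptor — with no further evidence
  required; or
* it is a missense or exon start/end codon change asserted pathogenic or
  likely pathogenic in ClinVar by **one or more** clinical laboratories
  (a conflicting benign assertion elsewhere does not veto this, but is
  audited as `clinvar_conflict`); or
* such a missense variant without a qualifying ClinVar assertion reaches
  the in-silico consensus over PolyPhen2-HumDiv, PolyPhen2-HumVar, LRT,
  MutationTaster and SIFT.

Intronic, 5'/3'-UTR, in-frame indel, synonymous and near-splice (outside
the 2 bp consensus site) variants are excluded *unconditionally*: no
combination of frequency, ClinVar or predictor evidence can rescue them.
This dominance is property-tested over randomized evidence fields.

**Consensus policy.** The sources that define this classification scheme do
not pin down the five-predictor vote, so it is a configuration knob
(`insilicoRule`): `"all"` (default — every available predictor damaging,
with at least three available), `"majority"`, or `"any"`. The default is
the most conservative rule that still tolerates missing predictions;
predictors returning no call are simply unavailable rather than votes
against.

**MAF source.** The 1% filter uses the `maf` column of the annotation
input; whether that frequency comes from study controls or a reference
panel is the caller's choice and should be stated alongside the annotation
provenance.

**Gene panels.** The default panel is {BRCA2, ATM, NBN, PALB2}; a secondary
panel {BRCA1, RAD50, MLH1, MSH6} (genes with weaker disease association) is
supported by passing `genePanel`. Variants in genes outside the panel are
skipped with an `outside_panel` audit note, never an error.

## 2. PRS scoring and tertiles

The score is the plain weighted sum of effect-allele dosages
$s_i = \sum_j w_j g_{ij}$, $g_{ij} \in [0,2]$. Scores are **not**
standardized by default — published per-allele weights produce raw sums
whose absolute scale is meaningful across datasets (here typically in the
mid-20s) — but `standardize = TRUE` is available.

* *Polymorphic filter*: variants with control MAF ≤ 1% or absent from the
  dosage table are removed before scoring, with a per-variant report.
* *Missingness*: sporadically missing dosages are imputed as twice the
  control effect-allele frequency (the standard PRS mean-imputation);
  individuals missing > 10% of model variants get a missing score rather
  than a biased one. Post-imputation array data typically have no
  missingness; this path exists for user-supplied and synthetic data.
* *Tertiles*: cut points are the 1/3 and 2/3 type-7 quantiles of the
  **control** score distribution; everyone (cases included) is categorized
  by those control-anchored cut points, left-closed
  (low < q1 ≤ intermediate < q2 ≤ high). Any consistent quantile/boundary
  rule would serve; this one is fixed and documented, and yields exact
  33/33/33 splits of continuous control scores.

## 3. Association models

Case status is modelled by maximum-likelihood logistic regression
(binomial IRLS, log-likelihood tolerance 1e-8, max 100 iterations):

* **Joint model** — five indicators for the six PRS-by-carrier categories,
  reference intermediate-PRS non-carriers, adjusted for age (continuous,
  years), study (indicators; dropped if the subset has one study) and the
  first 10 ancestry PCs. Outcomes: overall (unclassified cases included),
  aggressive, nonaggressive, metastatic — each versus all controls.
  Unclassified cases are excluded from the aggressiveness contrasts only,
  mirroring how clinical tables report non-summing subgroup counts.
* **Marginal models** — carrier alone (non-carrier reference) and PRS
  tertile alone (intermediate reference), same covariates.
* **Sparse cells** — plain ML is the default even when carrier-by-tertile
  cells are nearly empty, deliberately reproducing the conventional very
  wide Wald CIs of such analyses; a warning fires below 5 cases or
  controls per cell, a category with *zero* cases or controls is excluded
  from the likelihood and reported with an undefined OR
  (`undefined_empty_cell`), and estimates with |log OR| > 15 are flagged
  `possible_separation`. A Jeffreys-prior penalized fit (`firth = TRUE`,
  hat-diagonal adjusted score IRLS, implemented in-package) is available
  for users who prefer shrunken sparse-cell estimates.
* **Interaction** — the likelihood-ratio test compares the main-effects
  model (2 tertile indicators + carrier) against the model adding the two
  product terms (2 df), alongside the joint Wald test on the product
  coefficients. Whether such interaction tests are better run on the
  tertile or the continuous score scale is genuinely open; both are
  implemented (`scale = "tertile"` default, `"continuous"` = 1 df product
  with the standardized score). Empty product cells reduce the df with a
  warning.

Wald 95% CIs are $\exp(\hat\beta \pm 1.96\,\mathrm{se})$ and p-values are
two-sided normal.

## 4. Absolute risk

Odds ratios are carried to the absolute scale as relative risks
($r_g = \mathrm{OR}_g$) — a rare-ish-disease approximation that
overstates relative risk when the category-specific cumulative risk is
large; this is the field-standard convention and a documented limitation.

1. *Population frequencies*: $p_g = \pi f_{\text{case},g} +
   (1-\pi) f_{\text{ctrl},g}$ with prevalence $\pi = 0.167$ by default
   (the lifetime frequency in the target population); boundary values
   $\pi \in \{0, 1\}$ are permitted and give the pure control/case mixtures.
2. *Calibration*: $\lambda_0(t) = \lambda_{\text{pop}}(t) / \sum_g p_g r_g$
   with static frequencies, so $\sum_g p_g r_g \lambda_0(t) =
   \lambda_{\text{pop}}(t)$ holds exactly at every age — the identity the
   test suite checks to machine precision.
3. *Accumulation*: $AR_g(a) = \sum_{t} \min(r_g\lambda_0(t),1)
   \prod_{s<t} (1 - h_g(s) - \mu(s))$, survival floored at zero, risk
   clamped to $[0,1]$. The default grid is ages 40–85 in 1-year steps:
   lifetime risk is conventionally reported "by age 85", and 60/70 are the
   usual screening-discussion ages.
4. *Case-mix weighting*: overall-disease ORs are
   $w\,\mathrm{OR}_{\text{agg}} + (1-w)\,\mathrm{OR}_{\text{nonagg}}$ with
   $w = 0.37$, arithmetic on the OR scale — the most direct reading of
   "weighted ORs"; the log-scale (geometric) alternative is one flag away
   since the convention is not recoverable from the published description.
5. *Monte Carlo CIs*: 1,000 draws of the category coefficient vector from
   $\mathcal{N}(\hat\beta, \hat\Sigma)$ (joint sampling with the fitted
   covariance — sampling categories independently is the undocumented
   alternative), each converted to relative risks and re-run through
   calibration and accumulation. The reported point estimate is the
   iteration mean (the plug-in curve is available separately via
   `absoluteRiskCurve`), and the bands are empirical 2.5/97.5 percentiles;
   results are bit-reproducible for a fixed seed. The covariance is
   eigenvalue-checked (tolerance −1e-10) before sampling. When aggressive
   and nonaggressive tables are combined, their draws are independent —
   the shared-control correlation between the two fits is ignored, which
   widens the weighted bands slightly.

**Static vs dynamic frequencies.** The static calibration ignores that
high-risk categories are depleted with age. Measured against the
one-category population curve, the p-weighted average of static category
curves is accurate to ~1% at age 60 and ~2.5% at 70 but drifts to ~6%
relative error by age 85 at a tertile OR spread of 0.57–3 and ~17%
lifetime risk. `calibrateBaseline(..., dynamic = TRUE)` recalibrates
against the depleted mixture $p_g(t+1) \propto p_g(t)(1-h_g(t)-\mu(t))$
each year and reproduces the population curve to machine precision; the
static mode remains the default because it preserves the exact closed-form
identity above.

**Rates.** Registry schedules are supplied per 100,000 person-years and
divided by 100,000 — no exponential conversion, because yearly rates at
these magnitudes differ from hazards only in the fourth decimal and the
division matches how registry rates are tabulated and re-published.

## 5. The synthetic-data generator

`generateCohort()` emulates exactly the structure the analysis assumes:
independent PRS variants with dosages $\mathrm{Bin}(2, f_j)$,
$f_j \sim U(0.005, 0.49)$; fixed log-normal per-allele weights (median
0.19, chosen so raw control scores land in the mid-20s, the scale typical
of published multi-ancestry weight sets); Bernoulli carrier status at 0.6%
(the printed control carrier frequency); and disease from a logistic model
that is log-additive in carrier status (log OR log 4.5) and PRS tertile
(log 3.0 high, log 0.57 low vs intermediate — the printed marginal
associations), with small nuisance effects (log OR ≤ 0.1) of age, study
and two PCs so covariate adjustment is exercised without built-in
confounding. The optional interaction term is added to *both*
carrier-by-low and carrier-by-high products, matching the 2-df test.

The intercept is solved numerically (`uniroot` on the population mean of
`plogis`) so the *population* prevalence equals the configured 16.7%; the
cohort is then sampled outcome-dependently to the configured case fraction
(default 1796/3220), mirroring a case-enriched design — the prevalence is
recorded separately so prevalence-weighted frequency reconstruction can be
exercised meaningfully. Case types follow the configured 37% aggressive
share (30% of those metastatic), and the clinical fields (Gleason, stage,
PSA, death; PSA-only rules for the Ugandan study, including PSA > 100 as
metastatic and controls screened at PSA < 4) are filled so that
`classifyPhenotype()` reproduces the intended class exactly — the
generator's truth is checked *through* the phenotype classifier, not
around it.

Deliberately **not** emulated: linkage disequilibrium between PRS
variants, realistic haplotypes or relatedness, imputation dosage
uncertainty, ancestry-correlated PCs, and PRS-carrier correlation (the
generator draws them independently). Passing tests therefore demonstrate
the correctness of the statistical machinery under the assumed model, not
robustness to the correlation structure of real genotype data.

`generateRates()` produces registry-like schedules; the exponential
default (incidence anchor 1.2e-3 at age 40, doubling per decade;
competing mortality anchor 5e-3) gives ~1%/year incidence at 70,
~11% competing mortality at 85, and a population lifetime (40–85) risk of
~17%, consistent with the prevalence weight used elsewhere.
`generateAnnotations()` emits records covering every classifier branch
with truth labels valid under the default `"all"` consensus rule.

## 6. Problem sizes in the test suite

The suite favours a few deep checks over many shallow ones: contingency
oracle equivalence over 100 random 2×2 tables; six-category parameter
recovery and Wald coverage over 200 generated cohorts of n = 5,000
(seeds 1–200, pooled over estimable replicate × category pairs);
interaction-LRT calibration over 100 cohorts of n = 20,000 (a 60-variant
PRS in that loop — tertiles of a continuous score are unaffected by the
variant count, and the smaller genotype matrix keeps the loop tractable);
classifier truth recovery at 51 true / 100 false records plus a
1,000-record exclusion-dominance property; and machine-precision identity
checks for the calibration and closed-form risk limits. The interaction
power property (log OR 1.2 at n = 12,000 rejects at p < 0.001) is checked
on a single seeded cohort.

## 7. Known limitations

* OR-as-RR overstates absolute risk for the largest categories (high-PRS
  carriers), exactly where CIs are widest anyway.
* Static-frequency calibration under-tracks depletion beyond age ~80 (see
  §4); use `dynamic = TRUE` when late-age population consistency matters
  more than the closed-form identity.
* Plain ML in near-empty carrier-by-tertile cells gives noisy point
  estimates with honest (very wide) CIs; the penalized option trades that
  honesty for stability.
* The Monte Carlo point estimate (iteration mean of a log-normal-ish
  functional) sits above the plug-in curve when coefficient variance is
  large; both are reported.
* No LD, no ancestry-correlated structure, no family history modelling;
  PRS weights are taken as given and never re-estimated or recalibrated.
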