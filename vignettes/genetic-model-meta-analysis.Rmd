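---
title: "Meta-analysis of case-control genetic association studies with assocmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of case-control genetic association studies with assocmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocmeta)
```

## The problem

A single case-control study of a biallelic variant (here a G>A
polymorphism) reports six genotype counts: GG, GA and AA in cases and in
controls. Individual studies are usually too small to settle whether the
variant changes disease risk, so evidence is pooled across studies. This
package implements that pooling pipeline end to end: contrast derivation,
quality checks on the control arms, fixed- and random-effects estimation,
heterogeneity, publication-bias diagnostics, sensitivity analysis and
multiple-testing adjustment. The bundled data set, `rs671_gastric()`, holds
twelve East Asian case-control studies (6,420 cases, 8,832 controls) of the
ALDH2 rs671 G>A (Glu504Lys) variant and gastric cancer and is used as the
worked example throughout.

## Genetic-model contrasts

Because the inheritance mode is unknown a priori, the association is
examined under five contrasts of "exposed" versus "unexposed"
(`genetic_models()`):

| model | exposed | unexposed | unit |
|---|---|---|---|
| `allele` | A alleles | G alleles | alleles (2 per subject) |
| `dominant` | GA + AA | GG | subjects |
| `recessive` | AA | GA + GG | subjects |
| `hom` | AA | GG | subjects (GA excluded) |
| `het` | GA | GG | subjects (AA excluded) |

`derive_two_by_two()` maps an arm's genotype counts to the `a, b, c, d`
cells of the contrast. The allele model treats the two alleles carried by a
subject as independent observations — a standard simplification that is
exact under Hardy-Weinberg proportions and multiplicative effects, and an
approximation otherwise. The co-dominant contrasts simply drop subjects
carrying the excluded genotype.

Zero cells never occur in the bundled data, but sparse tables do occur in
simulation and in small strata: `apply_continuity_correction()` adds 0.5 to
all four cells of the affected study only. Corrected tables feed the
per-study (inverse-variance) effects; the Mantel-Haenszel sums always use
the raw counts, which that estimator tolerates — adding constants to MH sums
would bias it, while the Woolf log OR is undefined at zero cells, hence the
split policy.

## Hardy-Weinberg screening

Control arms are screened for departure from Hardy-Weinberg proportions,
the usual red flag for genotyping error or unrepresentative sampling.
`hwe_chi2()` is the Pearson goodness-of-fit test on the three genotype
classes with the allele frequency estimated from the data (1 df, no Yates
correction); `hwe_exact()` conditions on the observed allele counts and
sums the probabilities of all heterozygote counts no more probable than the
observed one. The chi-square form is the default; across the bundled
control arms the two tests agree on significance at every study, and
exactly one control arm (Yuan 2016, p ≈ 0.031) is out of equilibrium. That
study is retained in all pooled analyses — flagging, not exclusion, is the
convention the bundled analysis followed — and its influence is
quantifiable with `leave_one_out()`.

## Pooling model

Per-study effects are Woolf log odds ratios `y_i = ln(a_i d_i / b_i c_i)`
with variance `1/a + 1/b + 1/c + 1/d`. The fixed-effect pooled estimate is
Mantel-Haenszel,

    OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i),

with the Robins-Breslow-Greenland variance for its logarithm — the standard
consistent choice, and the one that reproduces the published intervals of
the bundled analysis. Heterogeneity is Cochran's Q with inverse-variance
weights around the inverse-variance fixed-effect mean (the conventional
pairing even when MH is the reported estimator), summarised as
`I2 = max(0, (Q - df)/Q)` and converted to a between-study variance by the
DerSimonian-Laird moment estimator. Random-effects pooling reweights by
`1/(se_i^2 + tau2)` and reduces exactly to inverse-variance fixed-effect
pooling when `tau2 = 0`.

The method is chosen by the I-squared rule (`select_method()`): random
effects when I² exceeds 50%, fixed effect otherwise. Exactly 50% goes to
the fixed-effect model; every row of the bundled analysis is far from the
boundary (the largest overall I² is 23.2%), so the tie-break is a
convention, and the less-parameterised model is the natural default.
Pooled estimates are tested with the usual Z-test, and `power_hedges_pigott()`
gives the post-hoc power of that test against a hypothesised true effect.
Confidence intervals are Wald intervals at the normal quantile for the
requested level (1.96 at 95%).

```{r}
studies <- rs671_gastric()
pool_mh(model_tables(studies, "allele"))
```

## Publication bias and sensitivity

`egger_test()` regresses the standard normal deviate `y_i/se_i` on
precision `1/se_i` (ordinary least squares — algebraically the classic
weighted form) and t-tests the intercept on k−2 df; a constant-deviate fit
has zero residual variance and is returned flagged `degenerate` rather
than as an error. `begg_test()` standardises effects against the
fixed-effect mean and rank-correlates them with the variances (explicit
pair counting, tie-corrected tau, no continuity correction on z; published
Begg p-values from continuity-corrected software will differ slightly, in
the conservative direction). Both tests require k ≥ 3 and are known to
have low power at typical study counts, so they are diagnostics, not
gatekeepers. `funnel_data()` exports the study points and pseudo-confidence
funnel for plotting. `leave_one_out()` re-pools after omitting each study
in turn, re-selecting the method each time.

On the bundled data both bias tests are null for all five models, and the
leave-one-out analysis is where the pipeline earns its keep: the overall
pooled ORs are null, but omitting the single dominating study (Zhang 2017,
42% of all cases) makes the allele, dominant and het contrasts nominally
significant (e.g. allele OR 1.090 [1.015; 1.172]). A claim of robustness
based only on the recessive contrast would miss this.

## Multiplicity

Five correlated contrasts are tested per population category, so the
pipeline adjusts within each category's family of five p-values:
`bonferroni()` (multiply by 5, cap at 1) and `bh_fdr()` (Benjamini-Hochberg
step-up), both via `stats::p.adjust`. The family-of-five definition is the
one consistent with the published adjusted columns of the bundled analysis.
Adjustment is only attached when all five models were run; partial runs
report raw p-values with adjusted columns `NA`. Note that adjusted columns
recomputed from full-precision p-values can differ by one unit in the last
printed digit from columns computed off rounded ones (0.169 vs 0.170).

## The pipeline

`run_analysis()` orchestrates everything per category (Overall plus each
level of the grouping columns) and returns a tidy table; `write_result_table()`
renders it to TSV at reporting precision (ORs/CIs/p to 3 decimals, I² to 1)
— byte-identical across runs — or to JSON at full precision.

```{r}
res <- run_analysis(studies, group_by = c("country", "control_source"))
format_result_table(res[res$category %in% c("Overall", "Japan"), ])
```

Where primary reports only publish collapsed GA+AA versus GG counts per
stratum (sex, smoking, drinking), `read_collapsed_csv()` and
`run_collapsed_analysis()` run the same machinery on the dominant contrast
alone — the 2x2 tables are formed directly from the collapsed counts, and
multiplicity columns stay `NA` because there is no family to adjust over.

## The synthetic-study generator

`simulate_collection()` generates study collections with the structure the
pooling model assumes, so every stage can be validated against known truth:

* control genotypes are multinomial draws from Hardy-Weinberg proportions
  at minor-allele frequency `maf`, optionally perturbed by an
  inbreeding-style coefficient `F` (`(p² + Fpq, 2pq(1−F), q² + Fpq)`);
* case genotype probabilities are the control probabilities tilted by the
  genotype odds ratios `or_het`, `or_hom` and renormalised;
* between-study heterogeneity is one shared `Normal(0, tau2)` shift per
  study added to both genotype log ORs, so under multiplicative effects
  (`or_hom = or_het²`) the allele-model log OR inherits variance ≈ `tau2` —
  exactly the random-effects structure DerSimonian-Laird assumes;
* publication bias is selection-on-significance thinning: a study is
  retained with probability `exp(-bias_strength · Φ(−z))`, `z` its observed
  allele-model Wald statistic, and redrawn until `k` studies are kept. With
  `bias_strength = 0` nothing is thinned. Thinning only produces funnel
  asymmetry when study sizes vary, so power checks spread the per-study
  sizes over an order of magnitude.

All randomness flows from the single integer `seed`; the caller's RNG
state is saved and restored, so simulation is reproducible and
side-effect-free. What the generator does *not* emulate: covariates and
gene-environment interaction (strata are label-only), genotyping error,
overlapping samples between studies, and non-multiplicative joint effects.
Passing parameter-recovery tests on these simulations therefore validates
the estimators and the plumbing, not the epidemiological assumptions of
any real data set.

## Validation choices and problem sizes

The test suite validates the implementation three ways: closed-form
identities (single-study pooling, equal-weight means, the two-point
DerSimonian-Laird case), independent reference implementations (the MH, DL
and Egger routes are cross-checked against metafor), and parameter
recovery on simulation. The simulation scales were chosen to keep Monte
Carlo error well below the tolerances being asserted while running in
seconds-to-minutes on one CPU: 200 replicates of k = 20 studies at
2000/arm for DerSimonian-Laird recovery (mean absolute log-OR error
< 0.05); 1000 simulated control arms of n = 500 for the HWE test's size;
1000 meta-analyses of k = 15 null studies with sizes log-spaced 100–1000
for Egger's size (rejection rate in [0.02, 0.09]); 150 + 150 replicates at
`bias_strength` 6 versus 0 for Egger's power under selection; and 40
replicates of 7-study strata at 500/arm, true dominant OR 1.4, τ² = 0.02,
for the collapsed-stratum recovery. Seeds are fixed in the tests; the
properties hold across seed choices with margin.

## Known limitations

* Only biallelic variants and the five classical contrasts; no
  additive/trend model, no Peto pooling, no REML or Paule-Mandel τ², no
  Hartung-Knapp adjustment, no trim-and-fill.
* The allele model's independence assumption is only exact under HWE.
* Begg/Egger variants differ across software in small, documented ways
  (continuity correction, weighting); this package fixes one variant each
  and treats cross-software p-value differences as expected.
* Figures are not rendered; the package exports plot-ready tables instead.
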