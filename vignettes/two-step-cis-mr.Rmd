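---
title: "Two-step cis-MR: model, adjustment, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step cis-MR: model, adjustment, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

cis-Mendelian randomization instruments a drug-target exposure (typically a
protein, or a biomarker proxying its activity) with variants in or near the
encoding gene, and reads the variant-outcome association as quasi-experimental
evidence for on-target effects. Its characteristic failure mode is
*confounding by linkage disequilibrium*: the instrument is correlated with a
neighbouring causal variant that reaches the outcome through a different
phenotype. Multivariable MR, the usual repair for pleiotropic pathways, needs
several variants with non-collinear effects on the two phenotypes — precisely
what a single correlated *cis* region cannot supply.

The two-step adjustment implemented here works at the level of the GWAS
summary statistics instead. The crude variant-outcome association
$\hat\beta_{GY}$ decomposes into a path through the exposure and a path
through the confounder phenotype $C$:

$$\beta_{GY} = \beta_{GX}\,\theta + \beta_{GC}\,\theta_C,$$

where $\theta$ is the causal effect of interest and $\theta_C$ the
confounder-outcome effect. The confounder path is estimable from two
ingredients that do not require any *cis* multivariant machinery: the
variant-confounder association $\hat\beta_{GC}$ from a GWAS of the
confounder, and an MR estimate $\hat\theta_C$ of the confounder's effect on
the outcome using genome-wide (liability) instruments. Subtracting their
product gives the adjusted association

$$\hat\beta_{GY}^{adj} = \hat\beta_{GY} - \hat\beta_{GC}\,\hat\theta_C,$$

which feeds any downstream two-sample MR estimator in place of the crude
association. This is the product-of-coefficients device from mediation
analysis, repurposed for bias removal rather than mediation, and it inherits
the assumptions of both MR and the product method: correctly specified
pathway(s), no residual confounding of any ingredient estimate, linearity
and no effect modification, and — for multiple pathways — mutual
independence of the pathways (see "Limitations").

## Propagation of error

The three ingredient estimates come from non-overlapping samples, so they
are treated as independent. For independent normal errors the variance of
the adjusted association is **exact**, not first-order:

$$\mathrm{se}_{adj}^2 = \mathrm{se}_{GY}^2
  + \hat\beta_{GC}^2\,\mathrm{se}_{\theta_C}^2
  + \hat\theta_C^2\,\mathrm{se}_{GC}^2
  + \mathrm{se}_{GC}^2\,\mathrm{se}_{\theta_C}^2.$$

The final cross term is what distinguishes the exact product variance from
the common first-order approximation; it is never negative, so the exact
form never understates uncertainty. `adjust_association(first_order = TRUE)`
exposes the truncated version for comparison. The parametric bootstrap
(`bootstrap_se()`) redraws the ingredients from their estimated sampling
distributions; because the propagated variance is exact under normality, the
bootstrap SE converges to it as `n_boot` grows — the package's tests assert
agreement within 1% at $10^6$ replicates, and the simulation study tracks
the two side by side. Both standard errors are conditional on normality of
the ingredient estimates; with GWAS-scale samples that is a mild assumption.

Sequential adjustment for $K$ pathways subtracts $\sum_k
\hat\beta_{GC,k}\hat\theta_{C,k}$ and accumulates the variance increments
additively. `sequential_adjust()` warns unconditionally that this is valid
only for mutually independent pathways: if one confounder causes another,
the shared segment is subtracted twice (demonstrated in the
`two_dependent` simulation scenario).

## Estimator suite

Per-variant Wald ratios $\hat\beta_{GY}/\hat\beta_{GX}$ are pooled by four
standard meta-analytic estimators: fixed-effect IVW (first-order weights
$\beta_{GX}^2/\mathrm{se}_{GY}^2$), MR-Egger (weighted regression with free
intercept after orienting $\beta_{GX} \ge 0$), the weighted median
(cumulative-weight interpolation with the $S_j - w_j/2$ pivot), and the
weighted mode (argmax of the weighted normal-kernel density; bandwidth
$0.9\,\min(\mathrm{sd}, \mathrm{mad})\,n^{-1/5}$ scaled by
`bandwidth_factor`). Choices the literature leaves open and the defaults
taken here:

* **Wald SE.** First-order (`se_gy/|b_gx|`) by default; the delta form
  adding the denominator's uncertainty is opt-in. With genome-wide
  significant instruments the difference is second order, and first-order
  weights keep the simulation's crude and adjusted estimates comparable.
* **Median/mode bootstrap.** Parametric, seeded, weights and bandwidth held
  fixed across replicates; default 2,000 replicates (their SEs stabilise to
  a few percent well before that; the point estimates are deterministic).
* **Estimator policy.** `mr_fit()` reports everything and promotes the
  weighted median over IVW when Cochran's Q has $p <$ `q_pvalue_threshold`
  (default 0.05, configurable): under detected heterogeneity at least one
  ratio is inconsistent with a single effect, and the median tolerates up to
  half the weight being invalid.
* **Ties and degenerate inputs.** A single variant degrades every pooled
  method to the Wald ratio; MR-Egger refuses constant $|\beta_{GX}|$ (no
  regression variation); the mode returns the common value outright when
  all ratios coincide (zero bandwidth).

Instrument strength is summarised by $F = \beta_{GX}^2/\mathrm{se}_{GX}^2$,
the squared z-score, and instrument selection uses a strict
$p < 5\times10^{-8}$ threshold, with a two-sided normal p-value computed
from beta/se when a study reports none.

## Harmonization rules

`harmonize()` aligns a second study to the base study's effect allele:
matching pairs are kept, swapped pairs flip the sign of beta and complement
the allele frequency, and strand complements (A↔T, C↔G) are resolved before
aligning. For palindromic pairs the allele labels carry no strand
information, so orientation comes entirely from the allele frequencies —
flip when the two studies' EAFs fall on opposite sides of 0.5 — and the
variant is dropped when either EAF is missing or lies within
`palindrome_eaf_window` (default 0.08) of 0.5. The window default mirrors
common practice in two-sample MR tooling and is deliberately a flag, not a
constant. LD clumping is out of scope: the package is positionless (keyed
by variant id) and expects a pre-clumped instrument list.

## Simulation design

The simulation study (`run_simulation()`) draws, per repetition, a
three-level genotype (binomial(2, p), the standard Hardy–Weinberg reading
of a three-level variant), allele frequency $p \sim N(0.5, 0.1)$ truncated
to (0.01, 0.99), and per-allele variant effects $\sim N(0.1, 0.05)$ on the
exposure and on each confounder. All other nodes are standard normal with
unit structural effects, the exposure-outcome effect (the estimand) is 1,
and every association is estimated by OLS in its own independent sample of
200,000 individuals — five samples in the single-pathway scenario
(exposure, outcome, confounder GWAS, liability-confounder,
liability-outcome), three more per additional confounder. The
confounder-outcome ingredient is itself a Wald ratio: the genome-wide
liability score's association with the outcome over its association with
the confounder. In the `two_dependent` scenario the first confounder causes
the second with unit effect, both affect the outcome, and each keeps its own
liability instrument, so the two nominal pathways share a segment.

Two engines generate the repetition estimates:

* `engine = "individual"` builds every sample individual by individual and
  runs the regressions — the transparent reference implementation.
* `engine = "summary"` (default) draws the OLS estimates directly from
  their joint sampling distribution: slopes are exactly normal around the
  drawn structural truth with model-implied residual variances, estimated
  SEs carry chi-square noise, and the only approximation is
  $\widehat{\mathrm{var}}(G) = 2p(1-p)$ (relative error $\sim\!n^{-1/2}$,
  about 0.3% at these sizes). The test suite checks distributional
  agreement between the engines. At five samples of 200,000 individuals and
  thousands of repetitions only the summary engine is tractable; it is what
  the shipped acceptance script and the simulation tests use
  (5,000–10,000 repetitions, against 100,000 for a full-scale run, with
  tolerances stated in Monte Carlo SEs).

**The weak-instrument guard is load-bearing.** The per-repetition crude
Wald ratio divides by $\hat\beta_{GX}$, whose sampling density is positive
at zero (the drawn effect itself is $N(0.1, 0.05)$, so about 2% of true
effects sit within two SDs of zero). The ratio therefore has no finite
moments: an unguarded mean over repetitions does not converge, it is
dominated by whichever near-null instruments a given run happens to draw,
and two runs of the same design can "average" to visibly different values.
The package resamples any repetition whose estimated variant-exposure
z-score falls below `resample_z` (default 2 — the point at which the
instrument would not even be nominally significant), reports the resampling
count, and aborts with a typed error if the guard rejects essentially
everything (a null effect distribution with a strict guard). With the guard
in place all reported means have finite variance and stabilise across
seeds. The guarded crude mean sits near the truncated principal value of
$1 + E[\beta_{GC}]\,E[1/\hat\beta_{GX}]$ — far above the estimand, which is
the point of the exercise — while the adjusted mean is unbiased to Monte
Carlo error in the single-pathway and independent-pathway scenarios, and
over-adjusts by about $E[\beta_{GC,1}/\hat\beta_{GX}]$ when the pathways
share a segment. Exact values for the configured defaults are computed by
`scripts/acceptance.R` and the acceptance tests, not quoted here.

What the generator deliberately does **not** emulate: LD structure (the
confounded and causal variant are collapsed into one perfectly-correlated
variant), binary outcomes and liability-scale transformations, sample
overlap between the ingredient GWASs, weak-instrument selection bias in the
exposure GWAS (instruments are drawn, not selected from a genome), or
effect heterogeneity across variants. A green simulation suite therefore
says the arithmetic and its uncertainty accounting are right under the
stated graph, nothing more.

## Applied workflow

`run_pipeline()` chains the pieces on delimited GWAS files: instrument
selection (explicit list or p-threshold), harmonization with full logging of
every flip/drop decision, crude cis-MR, one confounder-outcome MR per
pathway (primary estimator by the Q rule), per-variant adjustment,
adjusted cis-MR, per-instrument F-statistics, both Q tests, and the percent
deflation $100(\hat\theta_{crude} - \hat\theta_{adj})/\hat\theta_{crude}$
comparing crude and adjusted pooled estimates under the same estimator.
Outputs contain no timestamps, so a rerun with the same configuration and
seed is byte-identical — determinism is a tested contract. The packaged
synthetic example (`inst/extdata/synthetic_*.tsv`, labelled synthetic and
built with a known truth of 0.5) exercises every branch: an allele flip, a
palindromic drop, a variant missing from the outcome study, and a
confounder MR whose heterogeneity (driven by the *cis* variant doubling as
a nominal confounder instrument) triggers the weighted-median promotion.

## Limitations

* The independence assumption across ingredient estimates is structural; no
  covariance inputs are accepted, so overlapping GWAS samples are out of
  scope.
* Sequential adjustment over dependent pathways over-corrects by
  construction; the package warns but cannot detect dependence from summary
  data.
* Binary phenotypes are handled on the log-odds scale as given; liability
  transformations are the user's responsibility.
* The simulation's crude-side summaries are meaningful only relative to the
  declared guard; reported resampling counts should accompany any quoted
  number.
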