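---
title: "Methods: probe-level reliability for methylation arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-level reliability for methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrel)
```

## The measurement problem

A methylation BeadChip reports, per CpG probe and sample, a β value — the
proportion of methylated signal, in [0, 1]. When one DNA extraction is
assayed twice (on two platforms, or twice on the same platform), the two β
values for a probe should agree. For many probes they barely do, and the
disagreement is not uniform across the array. Everything in this package
follows from treating that per-probe disagreement as a first-class
quantity.

## Reliability: ICC(A,2)

For probe *p* we arrange the paired measurements as an n × 2 matrix
(subjects × measurement occasions) and compute the intraclass correlation
for the *average* of k = 2 ratings under a two-way random-effects,
*absolute-agreement* model:

$$\mathrm{ICC}(A,2) \;=\; \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}$$

with $MS_R$, $MS_C$, $MS_E$ the between-subject, between-rater and
residual mean squares of the two-way ANOVA. Choices worth making explicit:

* **Absolute agreement, not consistency.** A platform that reads
  systematically 5% higher than the other can correlate perfectly with it
  while disagreeing on every value. The $MS_C$ term charges that offset to
  the reliability estimate; the Pearson r (also reported per probe) does
  not. `compute_icc_ak()` returns the three mean squares so the components
  of any estimate can be audited.
* **Negative estimates are kept.** The estimator's range extends below
  zero and real panels produce negative values; truncating at zero would
  bias every summary of the distribution. With adversarial inputs
  (no between-subject variance at all) the point estimate can even exceed
  1 because the denominator can change sign; we report what the estimator
  produces rather than patching it, since such probes are biologically
  meaningless and sit far inside the "poor" band in any case.
* **Categories.** poor < 0.4 ≤ fair < 0.6 ≤ good ≤ 0.75 < excellent. The
  boundary handling (0.4 and 0.6 open that side, 0.75 closed into "good")
  is a convention fixed here because prose definitions of the bands are
  ambiguous at the boundaries.
* **Missing data.** The missingness policy for paired panels is not
  something the measurement model dictates; we use complete pairs per
  probe, require at least 3 of them, and flag probes that fall short
  (`insufficient_n`) or have zero total variance (`degenerate`) instead of
  failing. Flags propagate to the output table.
* **Scale.** ICCs are computed on whatever scale the matrices carry.
  β values are bounded and skewed; the M transform
  `beta_to_m()` (`log2(β/(1−β))`, with a 1e-6 offset applied only at
  exactly 0 or 1) is provided for users who prefer the variance-stabilized
  scale. On our synthetic panels the two scales rank probes nearly
  identically, which mirrors how little the choice mattered in practice.

`reliability_table()` vectorizes all of this across probes (the two-rater
mean squares reduce to row/column sums, so a 20,000 × 350 panel is a
sub-second computation) and attaches a distribution summary.

## Twin ACE decomposition

To connect reliability with genetic architecture, per-probe trait variance
is split into additive-genetic (A), shared-environment (C) and
unique-environment (E) proportions from MZ/DZ twin pairs. We maximize the
bivariate-normal log-likelihood of the standardized pairs with model
correlations $r_{MZ} = a^2 + c^2$ and $r_{DZ} = a^2/2 + c^2$ and unit
total variance — the same likelihood a structural-equation fit of the
classical twin model optimizes, without an SEM toolchain. Numerical
choices:

* The likelihood is written on symmetric sufficient statistics
  ($\sum y_1^2 + y_2^2$, $\sum y_1 y_2$ per zygosity group), so co-twin
  ordering cannot change the fit, and per-probe fitting over large panels
  is O(1) per likelihood evaluation after one pass over the data.
* The simplex constraint is handled by a triangular map from the unit box,
  optimized with L-BFGS-B from 3 fixed starts (tolerance 1e-8 on the
  log-likelihood). Components are therefore nonnegative by construction;
  boundary solutions (a² or c² at 0) are flagged, not forbidden.
* The Falconer closed form ($a^2 = 2(r_{MZ} - r_{DZ})$,
  $c^2 = 2r_{DZ} - r_{MZ}$, $e^2 = 1 - r_{MZ}$, truncated and
  renormalized) serves as cross-check and as fallback if the optimizer
  fails; the tests require ML to match it within 1e-3 on
  exact-correlation inputs and to dominate it in likelihood elsewhere.
* Twin models are fit on standardized values (the decomposition is scale
  free); whether the underlying trait is β or M is the caller's choice,
  and the default analyses use β.

## Enrichment along the reliability ranking

Whether a probe set (a methylation clock, an mQTL list, an
expression-correlated set) concentrates at the reliable end is tested with
a weighted Kolmogorov–Smirnov running sum over the ICC ranking: hits add
$|s_i|^w$ (normalized over the in-set total), misses subtract
$1/(N - m)$, and the enrichment score is the signed extremum. Conventions,
fixed because published numbers rarely pin them down:

* weight exponent w = 1 by default (w = 0 gives the classic unweighted
  statistic);
* ties in the ranking statistic are broken by probe id, so rankings are
  deterministic;
* the null permutes **set membership** (random same-size probe sets), the
  appropriate null for a preranked statistic, with NES = ES divided by the
  mean |null ES| of matching sign, and the add-one p-value
  $(1 + \#\{ES_{null} \ge ES\})/(B + 1)$, whose lower bound
  $1/(B+1)$ is attained by a fully top-loaded set.

The extremum is computed from hit positions only (O(m) per permutation),
which makes 10,000 permutations cheap; the implementation is checked
against exhaustive enumeration at small N and against an independent
preranked-GSEA implementation at machine precision.

## Replication, external statistics, expression

Cross-study replication of EWAS hits is tallied per probe as the number of
studies listing it with the majority direction of effect; what "consistent
direction" means for a probe listed both up and down is genuinely open, so
the majority rule is the default and a strict rule (mixed ⇒ 0) is
available via `mixed_rule = "zero"`. Exact ties are labeled `tie`. The
association report gives the count–ICC Pearson r plus group means for
ICC < 0.4 and ICC > 0.75.

External per-probe statistics (blood–brain concordance, published
heritabilities) are correlated with ICC (Pearson or Spearman) and binned
low/≤ 0.4, mid/(0.4, 0.75], high/> 0.75 — boundary values to the lower
bin, matching the reliability-category convention. Methylation–expression
coupling is evaluated per TSS link by Pearson correlation across shared
samples with the exact t-transform p-value on n − 2 degrees of freedom
(the test the correlation coefficient itself warrants; the choice is ours,
as published analyses rarely state it).

## Replicate subsampling

`subsample_sensitivity()` asks the design question directly: draw
`n_replicates` pairs without replacement, recompute every ICC, flag
probes above the threshold, and compare with the full-panel flags.
Sensitivity is averaged over 100 independent draws by default (whether a
published figure of this kind averages draws or reports one subsample is
usually unstated; averaging is the stable choice and the per-draw values
are returned). Probes that become degenerate in a subsample count as not
flagged — the conservative direction for a screen. Specificity is
reported alongside even when only sensitivity is quoted, since a screen
that flags everything is trivially sensitive.

## The synthetic-data generator

Everything above is testable because the generator emits ground truth
alongside data. Design:

* **Latent logit scale.** Per probe, a true score
  $T_{pi} \sim N(\mu_p, \sigma_{T,p}^2)$, a per-probe-and-platform offset
  $c_{pj} \sim N(0, \sigma_c^2)$ and noise
  $e_{pij} \sim N(0, \sigma_{E,p}^2)$ combine to
  $y_{pij} = T_{pi} + c_{pj} + e_{pij}$, and β = inverse-logit(y), so
  outputs respect (0, 1) by construction.
* **Variance split from the target ICC.** Rather than drawing
  $\sigma_T$ and deriving the noise (undefined at ICC 0, explosive near
  it), each probe draws a total single-occasion SD from `sigma_range`
  (default 0.3–1.0 on the logit scale, the magnitude of M-value SDs seen
  on arrays) and splits it via the k = 2 identity
  $\mathrm{ICC} = \sigma_T^2 / (\sigma_T^2 + (\sigma_c^2 +
  \sigma_E^2)/2)$. This is exact on the logit scale for every target in
  [0, `icc_max`]; `icc_max = 0.98` because ICC 1 requires zero noise.
* **Calibrated ICC mixture.** The default true-ICC distribution is a
  four-part mixture — 30% point mass at 0.01, 45% Beta(1.1, 6),
  18% Beta(2.5, 2.5), 7% Beta(8, 2), truncated at 0.98 — calibrated once
  so that draws land in the windows median [0.05, 0.13], mean
  [0.17, 0.25], P(> 0.75) [0.04, 0.09] that characterize a zero-skewed
  between-array panel. The tests verify the windows at n = 50,000.
* **Attenuation is measured, not corrected.** The inverse-logit
  compression makes β-scale ICC estimates slightly smaller than the
  logit-scale targets; recovery tests therefore evaluate on the logit
  scale (where the target is defined), and `analysis/02` prints the
  measured β-scale attenuation (of the order of 0.01 on this panel) so
  users can see its size rather than trust a correction.
* **Couplings.** The twin generator can add a per-probe noise term with
  variance $(1 - \mathrm{ICC})/(\mathrm{ICC} + 0.5)$ (a smooth, bounded,
  decreasing function of reliability) that loads entirely on E — the
  mechanism by which unreliable probes masquerade as
  environment-dominated. The study-hit generator detects effect probes
  with probability given by a monotone coupling of true ICC (logistic by
  default; constant gives the null), and the expression generator places
  linear effects on designated probes.
* **Determinism.** Every generator takes a mandatory seed, uses R's
  default Mersenne-Twister through a wrapper that restores the caller's
  RNG state, and derives child seeds (kept below 2³¹) for multi-part
  runs.

What the generator does **not** emulate: Infinium I/II chemistry
differences, cell-composition heterogeneity, batch and chip-position
artifacts, spatially correlated probes, and the long tail of
cross-reactive probes. Passing tests on synthetic panels therefore
demonstrate that the estimators and the pipeline are correct and
well-calibrated under the stated model — not that any particular real
cohort has these exact properties. Real-data magnitudes of, for example,
the reliability–heritability correlation depend on cohort data the
generator does not model; the tests check sign patterns and
generator-implied magnitudes only.

## Problem sizes and tolerances

The bundled analyses use a 4,000 × 350 panel (scripts) and panels of
2,000–20,000 probes in the tests and the acceptance script — sizes chosen
so each estimator's sampling error is comfortably below the windows being
checked. Key tolerances: ICC vs ANOVA-oracle agreement 1e-10; grid
recovery of true ICCs at n = 350 within 0.02 of the mean; ACE bias over a
component grid below 0.02 and replicate-averaged recovery within 0.05 at
the 1,000 + 1,000-pair design (a single fit at that design has sampling
SD ≈ 0.05, so means over replicates are the informative check); ML vs
Falconer within 1e-3 on exact-correlation inputs; enrichment p-values
uniform under the null (KS) and exactly bounded below by 1/(B + 1).

## Known limitations

* ICC variants other than (A,2) (single-rating, consistency, one-way) are
  out of scope, as are bootstrap confidence intervals on ICCs.
* The ACE fitter has no covariates, no sex-limitation or ADE variants,
  and reports no standard errors.
* Enrichment handles one set at a time (Bonferroni across sets is left to
  the caller) and does not report leading-edge subsets.
* The replication module consumes study hit lists as given; it does not
  model differing study sizes or significance criteria.
* With ≤ 10 paired samples, per-probe ICC estimates are nearly
  uninformative (the demo fixture shows estimates as low as −5); the
  package reports them faithfully rather than shrinking them.
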