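---
title: "Two-sample Mendelian randomization of leptin levels on anorexia nervosa risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR of leptin on anorexia nervosa: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leptinmr)
```

## The question and the design

Anorexia nervosa (AN) is characterised by underweight and abnormally low
circulating leptin, and genetic correlation studies suggest a shared
predisposition to low leptin and AN risk. Whether low leptin *causes*
higher AN risk cannot be read off a correlation: leptin falls as fat mass
falls, so observational associations are hopelessly confounded by the
disease process itself. Two-sample Mendelian randomization (MR) breaks
this circle by using genetic variants as instruments: alleles associated
with lifelong lower leptin are randomized at conception, long before
disease onset, so their association with AN risk reflects the causal
pathway (if the instrument assumptions hold).

`leptinmr` implements the complete analysis: instrument quality control,
allele harmonization across the two studies, nine causal estimators with
complementary robustness properties, pleiotropy/heterogeneity/outlier
diagnostics, a binary-outcome power calculator, and a synthetic
summary-statistic generator with known ground truth against which every
stage is validated. The package bundles the published per-SNP instrument
tables for a leptin GWAS (5 variants, sexes combined) and a leptin
exome-array study in Europeans (9 variants), each paired with the variants'
AN case-control associations (16,992 cases / 72,517 total; effects on the
log-odds scale, odds ratios converted with the natural logarithm).

## Data model and harmonization

Summary statistics are per-SNP association records (alleles, effect-allele
frequency, beta, SE, p-value) read from a TSV dialect with a configurable
column map. Validation is strict and row-indexed: non-positive SEs,
p-values outside (0, 1], invalid or identical alleles, and duplicated SNP
ids are errors, never silent drops.

Harmonization expresses the outcome effect on the exposure's effect
allele: allele-swapped records are sign-flipped, opposite-strand records
are complemented first, and anything else is an error. Strand-ambiguous
(palindromic A/T and C/G) variants are resolved by policy:

* `"eaf-resolve"` (default): allele frequencies decide the strand when
  both studies' frequencies are informative (more than 0.08 away from
  0.5 — far enough that sampling noise in the frequency cannot plausibly
  put the two studies on opposite sides); otherwise a user-supplied
  proxy-direction table is consulted; otherwise the variant is dropped
  with a warning.
* `"strict"`: drop all palindromic variants.
* `"keep"`: trust the printed orientation (appropriate for curated tables
  that already report both traits on a shared effect allele, as the
  bundled fixtures do).

The bundled `fixture_proxy_directions()` table records that the
palindromic leptin instruments (the C/G variant near *LEP* with frequency
0.50, and the A/T variant in *FTO*) were strand-confirmed externally
through non-palindromic variants in high LD (r² = 0.98), reproducing the
keep decisions of the published analysis under the default policy.

After harmonization every instrument is re-oriented so the exposure
effect is non-negative ("exposure-positive"). All estimators are invariant
to this joint sign flip; MR-Egger *requires* it, because the sign of its
intercept is only meaningful relative to a fixed orientation.

## Instrument quality control

Instrument strength is measured by the approximate F-statistic
$F = (\beta/\mathrm{se})^2$; variants with $F < 10$ are excluded as weak
(the boundary $F = 10$ is retained). The significance filter is
genome-wide ($p < 5\times10^{-8}$) by default, with an opt-in relaxed
threshold ($p < 0.05$, `subgroup = TRUE`) for instruments discovered in a
larger sample but re-estimated in a subgroup. The bundled tables need the
relaxed threshold: two of the printed GWAS leptin p-values sit above
$5\times10^{-8}$ even though the loci were discovered as genome-wide
significant, and the exome-array effects are European-subgroup estimates.
On the European exome-array set the F filter removes exactly the two weak
variants (F = 1.31 and F = 9.00), leaving seven instruments.

Instruments missing from the outcome study can be substituted by LD
proxies chosen from a supplied candidate table ($r^2 \ge 0.80$), ranked by
highest $r^2$, then smallest distance to the lead SNP, then preferring
strand-unambiguous alleles, with a lexicographic id tie-break for
determinism. No live LD queries are made.

A leptin-specific filter, `exclude_bmi_nonrobust()`, removes instruments
whose leptin association disappears after BMI adjustment ($p \ge 0.05$):
such variants plausibly act on leptin only through adiposity and violate
the exclusion restriction. In the bundled data this removes the *FTO*
variant from each instrument set — the same variant MR-PRESSO flags as a
pleiotropic outlier.

## Estimators

With per-SNP ratio estimates $r_j = b_{Y,j}/b_{X,j}$ and inverse-variance
weights $w_j = b_{X,j}^2/s_{Y,j}^2$:

* **Wald ratio** (single SNP): $r_j$ with first-order delta-method SE
  $s_{Y,j}/|b_{X,j}|$.
* **IVW**: $\hat\theta = \sum w_j r_j / \sum w_j$, equal to weighted least
  squares of $b_Y$ on $b_X$ through the origin. The variance model is
  multiplicative random effects with the residual scale floored at one:
  $\mathrm{se} = \max(1, \sqrt{Q/(J-1)})/\sqrt{\sum w_j}$. The floor
  means a homogeneous set reports the fixed-effect SE unchanged while a
  heterogeneous set is penalised; this single convention reproduces both
  published SEs (0.244 for the homogeneous 4-SNP set, 0.369 for the
  heterogeneous 5-SNP set).
* **MR-Egger**: weighted least squares *with* an intercept; the slope is
  the causal estimate under InSIDE (instrument strength independent of
  direct effects) and the intercept estimates average directional
  pleiotropy. SEs are scaled by the residual SD floored at one; inference
  uses a t distribution with $J-2$ df (with $J = 4$ instruments the
  printed intercept p-value 0.421 is only reproduced by $t_2$, not by a
  normal reference).
* **Median family**: weighted 50th percentile of the ratios with linear
  interpolation over standardized cumulative weights
  $p_j = (\mathrm{cumsum}(w) - w_j/2)/\sum w$; simple (equal weights),
  weighted ($w_j$), and penalised weighted, which multiplies weights by
  $\min(1, 20 q_j)$ with $q_j$ the upper-tail $\chi^2_1$ probability of
  the SNP's heterogeneity contribution. Consistent while up to half the
  weight comes from invalid instruments.
* **Mode family**: argmax of a weighted normal-kernel density over the
  ratios (zero-modal pleiotropy assumption). Bandwidth
  $\phi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,J^{-1/5}$ with
  $\phi = 1$ by default; 512-point grid spanning the ratios plus three
  bandwidths; density ties broken toward the smaller magnitude. If all
  ratios coincide the common value is returned.
* **MR-RAPS**: solves the profile score
  $\sum_j b_{X,j}\,\psi\!\big((b_{Y,j}-\theta b_{X,j})/\sigma_j\big)/\sigma_j = 0$
  with $\sigma_j^2 = s_{Y,j}^2 + \theta^2 s_{X,j}^2 + \tau^2$, accounting
  for exposure-side measurement error that IVW ignores. The
  overdispersion $\tau^2 \ge 0$ (systematic pleiotropy) is estimated
  jointly from the second-moment equation and truncated at zero when
  residuals are underdispersed; $\psi$ is the identity (`l2`) or a Huber
  score bounding idiosyncratic pleiotropy. The SE is the profile
  information $1/\sqrt{\sum b_{X,j}^2/\sigma_j^2}$ (inflated by the usual
  efficiency factor under the Huber score): with a handful of instruments
  the empirical sandwich middle term is far too unstable to use.
  Non-convergence after 100 iterations is an error, never silent.

Median and mode SEs come from a parametric bootstrap (1000 replicates by
default) redrawing $b_Y \sim N(b_Y, s_Y)$ and $b_X \sim N(b_X, s_X)$
under a mandatory, recorded seed; results are bit-reproducible given
(replicates, seed), and the caller's RNG state is never consumed.
Confidence intervals are uniformly $b \pm 1.96\,\mathrm{se}$, which
reproduces the published bounds exactly at the printed precision.

## Diagnostics

**Cochran's Q** about the IVW estimate ($\sum w_j (r_j - \hat\theta)^2$,
$J-1$ df) or about the Egger fit (weighted residual sum of squares,
$J-2$ df) tests whether the per-SNP ratios are mutually consistent; the
per-SNP contributions decompose Q exactly. **Leave-one-out** re-estimates
the effect omitting each variant in turn. **Plot data** (funnel, scatter
with per-method regression lines, forest, leave-one-out) are emitted as
tables; rendering is deliberately out of scope.

**MR-PRESSO** simulates the no-pleiotropy model: each variant's expected
outcome effect is its leave-one-out IVW prediction, and `n_sim` parametric
datasets ($b_Y^* \sim N(\hat\theta_{(-j)} b_{X,j}, s_{Y,j})$,
$b_X^* \sim N(b_{X,j}, s_{X,j})$) yield the null distribution of the
residual sum of squares (global test) and of each squared residual
(outlier test, Bonferroni-adjusted at level 0.05). Empirical p-values use
the $(1+k)/(1+n)$ estimator so they are never zero. When outliers are
found, the corrected estimate is IVW on the remainder, and a distortion
test compares the all-SNP versus outlier-removed estimates against a
bootstrap over non-outlier SNPs. On the five-instrument leptin set the
*FTO* variant is flagged and the corrected estimate equals the 4-SNP IVW.
The global-test p-value is a simulation quantity: it is checked for
uniformity on synthetic null data, not against any single published
draw.

## Power

For a binary outcome the package uses the standard normal approximation:
with outcome sample size $N$, case fraction $K$, instrument-explained
exposure variance $R^2$ and alternative odds ratio $\mathrm{OR}$, the
non-centrality is $z = |\ln \mathrm{OR}|\sqrt{N R^2 K(1-K)}$ and two-sided
power at level $\alpha$ is $\Phi(z - z_{1-\alpha/2}) +
\Phi(-z - z_{1-\alpha/2})$. At $\mathrm{OR} = 1$ this returns exactly
$\alpha$. The published power statements (80% at OR 1.08, "100%" at
OR 1.14 for the GWAS instruments) are treated as band checks
(0.75–0.85 and > 0.99), because the published text does not print its
formula: the recomputed values are 78.1% and 99.6%.

## The synthetic-data generator

`simulate_summary_stats()` emits two independent association tables over a
shared instrument panel under the structural model: latent exposure
effects $\gamma_j$, observed $b_{X,j} = \gamma_j + N(0, s_X^2)$, and
$b_{Y,j} = \theta\gamma_j + \alpha_j + N(0, s_Y^2)$ with pleiotropy
$\alpha_j$ that is absent, balanced, directional, or correlated 0.5 with
instrument strength (InSIDE-violating); `n_outliers` variants receive a
gross direct effect of `outlier_scale` times $s_Y$. Defaults mirror the
leptin/AN study scale: effects of a few hundredths of a unit,
$s_X = 0.005$, $s_Y = 0.0136$.

Two labeling choices matter. Effect alleles are labeled as the
exposure-increasing allele, so $\gamma_j = |N(0, \gamma_{sd}^2)|$ in the
emitted orientation: allele labels are arbitrary, and fixing them this way
makes the *direction* of planted pleiotropy well defined relative to the
orientation in which the Egger intercept is estimated. Alleles are
non-palindromic A/G pairs with frequency uniform on (0.1, 0.9), so
simulated data exercise the harmonization plumbing without strand
ambiguity.

What the generator does **not** emulate: LD between instruments (the
published instruments are treated as independent), winner's-curse
selection of instruments, sample overlap between the two studies, allele
frequency–dependent effect sizes, and non-linear exposure–outcome
relationships. Passing tests therefore certify the statistical machinery
under the stated model, not robustness to these real-data complications.

Validated properties (fixed seeds throughout): IVW equals a brute-force
weighted-normal-equations oracle to 1e-12; IVW 95% CI coverage is
0.95 ± 0.02 over 500 null replicates at $J = 50$ (the floored
multiplicative-random-effects SE makes it very slightly conservative);
the Egger intercept recovers planted directional pleiotropy of 0.05
within Monte-Carlo error *after* the weak-instrument filter — near-null
instruments have ill-defined orientation and would otherwise attenuate
the intercept, which is precisely why QC precedes Egger in the pipeline;
the weighted median is less biased than IVW when 40% of instruments are
invalid; MR-PRESSO detects a planted 10-SD outlier in ≥ 95% of replicates
at $J = 20$ and its global p is uniform on null data; Q is
$\chi^2$-calibrated on homogeneous data.

## Numerical and design choices

* Expected values in fixture-based checks carry 1–2% tolerance: the
  published inputs are printed to about two significant figures, and the
  unrounded values behind them are unavailable. Quantities that depend
  only on printed numbers (F-statistics, Wald SEs, the fixed-effect IVW
  SE, CI arithmetic) are checked at the printed precision.
* The p-value reference is normal for Wald/IVW/median/mode/RAPS and
  $t_{J-2}$ for both Egger coefficients.
* The Egger intercept's *sign* is orientation-dependent; under the
  exposure-positive convention the recomputed six-instrument exome-array
  intercept is $-0.037$ where $+0.038$ was published (magnitude and
  p-value agree).
* Degenerate inputs: identical ratios give Q = 0 and a zero mode
  bandwidth (the common value is returned); a single instrument falls
  back to the Wald ratio with a warning; zero instruments after QC is an
  error that lists every exclusion and its reason.
* When the best LD proxy is itself absent from the outcome study the
  next-ranked candidate is taken (the published procedure is silent on
  this case).
* Replicate counts in the test suite (100–500 Monte-Carlo replicates,
  MR-PRESSO at 300–1000 simulations) were chosen so the full suite
  completes in well under a minute while keeping Monte-Carlo error far
  below the asserted tolerances.

## Limitations

The estimators assume independent instruments and non-overlapping
samples; neither is enforced beyond documentation. No multivariable MR,
no contamination-mixture or Bayesian model-averaging estimators, no
Steiger directionality filtering, no genotype-level computation (LD is
always supplied as a table), and no figure rendering. Heritability
estimation and genomic-inflation diagnostics require full genome-wide
summary statistics and are out of scope; the variance explained entering
the power calculation is taken as an input.
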