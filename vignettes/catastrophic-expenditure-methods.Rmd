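---
title: "Measuring catastrophic household health expenditure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring catastrophic household health expenditure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathex)
```

## The measurement problem

In countries where most health care is paid for out of pocket (OOP), a
single illness episode can absorb a large share of a household's monthly
budget. The standard way to quantify this burden treats a household as
having experienced *catastrophic health expenditure* when its OOP health
spending over a reference period exceeds a threshold share $z$ of its total
consumption expenditure over the same period. This package implements the
complete analysis chain for that definition on complex-survey microdata:
incidence and intensity measures, their distribution over the economic
gradient, attribution of jointly reported comorbidity costs to individual
illnesses, and illness-specific risk models — together with a synthetic
survey generator with known ground truth against which every estimator is
validated.

## Incidence and intensity

With budget share $s_i = T_i / x_i$ (OOP total over total expenditure,
uncapped — spending financed from savings or debt can exceed current
consumption), sampling weight $w_i$, and flag
$E_i = \mathbf{1}(s_i > z)$:

* **headcount ratio** $H = \sum w_i E_i / \sum w_i$ — the weighted share of
  households above the threshold;
* **catastrophic overshoot** $O = \sum w_i (s_i - z) E_i / \sum w_i$ — the
  mean excess share over *all* households;
* **mean positive overshoot** $MPO = O / H$ — the mean excess among
  *catastrophic* households only.

The identity $O = H \cdot MPO$ holds by construction whenever $H > 0$ and is
asserted on every emitted table row. When $H = 0$, `MPO` is an explicit
undefined marker (`NA`), never zero: coding it as zero would silently break
the identity check. The threshold comparison is strict by default
("more than $z$"), with `strict_threshold = FALSE` available for the
inclusive variant. The headcount standard error uses Taylor linearization
of the ratio estimator with PSUs (census enumeration areas) as
with-replacement first-stage units.

The default $z = 0.10$ of *total* expenditure — rather than a share of
non-food or "capacity to pay" — is the variant the package targets; the
denominator includes the health spending itself. Whether transport costs
belong in $T_i$ is genuinely ambiguous in this literature, so the transport
component is included by default and excluded by a config flag
(`include_transport`).

## Living standards and the economic gradient

Households are ranked by expenditure per adult equivalent. The equivalence
scale is the standard two-parameter family

$$AE = (n_{\text{adults}} + c \cdot n_{\text{children}})^\theta,$$

children being members under 15, with defaults $c = 0.5$ and
$\theta = 0.9$. Surveys of this kind typically cite an external
equivalence scale without printing its functional form; a configurable
two-parameter scale is the reproducible choice, and both parameters sit in
`analysis_config()`.

Weighted fractional ranks place each household at the midpoint of its
normalized-weight interval in the ascending ordering,
$r_i = \sum_{j<i}\hat w_j + \hat w_i/2$. Tied values share their block's
midpoint rank, which keeps the weighted mean rank at exactly $0.5$ — a
property the concentration index inherits. Quintiles cut the weighted rank
at $0.2, 0.4, 0.6, 0.8$; a household straddling a cut point goes to the
lower quintile (deterministic and reproducible). Quintile construction
weights households by the sampling weight by default; weighting by
weight × household size is exposed as `quintile_weighting = "person"`
because survey reports are not always explicit about this choice.

## The concentration index

Inequality in any household variable $y$ over the wealth ranks is measured
by the concentration index

$$C = \frac{2\,\mathrm{cov}_w(y, r)}{\mu}, \qquad \mu = \text{weighted mean of } y,$$

negative when $y$ concentrates among the poor. $C \in [-1, 1]$ always, and
for binary $y$ the sharper bounds $\mu - 1 \le C \le 1 - \mu$ are asserted
on every result (no Erreygers/Wagstaff rescaling is applied — the bounds
are checked, not corrected).

Two variance estimates are reported side by side, because survey reports
in this field commonly cite both a delta-method SE and bootstrap intervals
without stating which produced which:

* **delta method** — the convenient-regression formulation: WLS of
  $(2\,\mathrm{var}_w(r)/\mu)\,y_i$ on $r_i$; the slope *is* $\hat C$ and
  its heteroskedasticity-robust (cluster-robust over PSUs when available)
  SE is the delta-method SE;
* **cluster bootstrap** — PSUs resampled with replacement $B$ times
  (default $B = 100$), percentile 2.5/97.5 interval, p-value from
  $\hat C / \mathrm{SD}_{\text{boot}}$ against the standard normal.
  Fractional ranks are rebuilt *inside* each replicate: resampling
  clusters changes the wealth distribution, so rank uncertainty must
  propagate.

$B = 100$ mirrors common reporting practice but is known to be
anti-conservative for percentile intervals; the package warns through
documentation rather than silently raising $B$, and the coverage achieved
at $B = 100$ is itself measured in the test suite (it must reach at least
88% where nominal is 95%).

An independent oracle backs the implementation: on equal-weight instances,
$C$ from the covariance form must equal the sorted-pairs double sum
$\sum_{ij}(y_i - y_j)\,\mathrm{sign}(r_i - r_j)\,/\,(2 n^2 \mu)$ to
$10^{-12}$.

## Comorbidity cost allocation

Respondents who treated concurrent illnesses together usually report one
joint cost for the comorbidity. The package allocates such costs by a
regression-based attribution: OLS of cost-group totals on illness presence
indicators, *without intercept* — an intercept would create cost
attributable to no illness, breaking conservation. Predicted components
$c_j = \beta_j x_j$ are floored at zero and renormalized so the group's
allocations are non-negative and sum to the reported cost exactly (checked
to machine precision). Single-illness groups bypass the regression; a group
whose predicted components are all floored falls back to an equal split.
The regression pools all households into one model: per-quintile sample
sizes for individual illnesses are far too small to support stratified
attribution. Illness pairs that never appear separately make the indicator
matrix rank deficient; this raises an error naming the confounded codes
rather than returning an arbitrary least-squares solution.

Illness-specific catastrophe measures then apply the $H/O/MPO$ machinery to
the allocated cost of each illness (allocated cost over total expenditure
against the same threshold $z$). The alternative reading — "household
catastrophic *and* has the illness" — is deliberately not the default,
because intensity measures require illness-specific costs; per-illness
headcounts therefore need not sum to the overall headcount.

## Illness-specific risk: Poisson rate ratios

The risk model is a log-link Poisson regression of the binary catastrophe
flag, fitted separately within each quintile, with cluster-robust sandwich
variance over PSUs and Wald 95% intervals. A Poisson model on a binary
outcome estimates prevalence (rate) ratios directly — unlike odds ratios,
these are interpretable multiplicative effects — and the robust variance
repairs the misspecified Poisson variance. The canonical adjustment set is
hospitalization in the recall period, household size, provider type, head
age, head education (collapsed to primary-or-lower / secondary / higher),
counts of members under 5 and over 65, and one indicator per illness.
Illness exposure is coded "at least one episode in 30 days". Whether such
analyses should also apply the sampling weights is usually under-specified
in reports; cluster-robust unweighted estimation is the default and weights
are accepted as an option.

Degenerate cells are first-class: covariates constant within a stratum and
separated fits (a coefficient diverging, detected by $|\hat\beta| > 15$ or
a robust SE above 10, or a stratum with no outcome variation) yield an
explicit not-estimable marker, mirroring the `NA` cells of published
quintile tables. The saturated single-covariate case has a closed form —
the ratio of (weighted) outcome means — and the implementation must match
it to $10^{-10}$.

Cross-quintile differences in illness prevalence are tested by the plain
Pearson $\chi^2$ on unweighted counts (no continuity correction), with the
degenerate no-variation table returning statistic 0 and $p = 1$.

## The synthetic survey generator

Because household expenditure microdata of this kind are confidential, the
package ships a generator that emulates the survey's design and margins
while making the estimands exactly known:

* **design** — 100 PSUs × 20 households; PSU-level weights lognormal
  (log-SD 0.25 by default, approximating PPS selection with imperfect
  measures of size), constant within PSU, normalized to mean 1;
* **demographics** — household size $1 + \mathrm{Poisson}(3.4)$ (mean 4.4);
  the first member is the head, aged $\mathcal N(46, 13^2)$ truncated to
  21–90; other members mix ~10% under-5, ~5.5% over-65; head sex 15.9%
  female; education distribution (24/13.4/31.6/31%);
* **economics** — total expenditure lognormal (median ≈ 25 000 currency
  units, log-SD 0.7); OOP budget shares zero-inflated lognormal with
  quintile-level mean targets (10.7/14.8/8.3/10.3/6.9% among the ~76% of
  households reporting any OOP spending);
* **illness** — household-level Bernoulli flags at the ten illness
  prevalences (cold/cough/fever 12.8% … hyperuricaemia 0.7%), adult-only
  conditions restricted to households with a member over 20; episode costs
  lognormal around per-illness means, jointly reported with probability
  0.5 when a household has several episodes;
* **catastrophe** — the key inversion: each household's catastrophe
  probability is either a constant `p_cat` or a linear gradient
  $p(r) = a + br$ over its (endogenous) wealth rank, multiplied by the
  configured rate ratio of every illness it carries. The OOP total is then
  scaled so the budget share lands strictly above $z$ exactly when the
  drawn status is catastrophic, with excess $\sim \mathrm{Exp}(0.332)$
  (matching a mean positive overshoot of 33.2%), and at or below $z$
  otherwise.

Wealth ranks are *not* drawn independently: they come from the generated
per-AE expenditure, exactly as the downstream analysis computes them, so
quintiles are endogenous. Rate-ratio injection is multiplicative because
the recovery model is log-linear; a product that would push any household's
probability above 1 raises a calibration error instead of capping, so the
stated truth is never silently distorted. For the linear gradient the
population concentration index has the closed form

$$C = \frac{b}{6\,(a + b/2)},$$

obtained by integrating $2\,\mathrm{cov}(y, r)/\mu$ for
$r \sim U(0, 1)$; the generator's truth record stores it, and the test
suite verifies it independently by brute-force simulation at $n = 10^5$.

What the generator does **not** emulate: care-seeking and cost-aversion
behaviour (skipped doses, foregone consultations), seasonality of
communicable illness, correlation between illness types, or reporting
error in consumption. Recovery tests on this generator therefore validate
the estimators, not the field realism of any particular survey.

## Numerical and design choices

* Threshold comparison is strict (`>`); shares are never capped at 1.
* Ranking ties: stable sort by (value, input order); tied blocks share the
  weighted mid-block rank. Quintile-boundary ties go to the lower quintile.
* The aggregated-versus-disaggregated OOP comparison is a two-sample
  Wilcoxon rank-sum as typically reported for these naturally paired
  estimates (fidelity to common practice over statistical preference);
  the z statistic uses the tie-corrected normal approximation, the p-value
  is exact for small tie-free samples. Aggregated estimates are generated
  as the disaggregated sum times lognormal noise with median 1, emulating
  the usual finding of little systematic difference.
* Poisson IRLS convergence: relative deviance change $< 10^{-8}$, at most
  100 iterations; non-convergence is an error, separation a marker.
* One master seed drives the pipeline; stage seeds derive deterministically
  from the stage name, so stages stay reproducible independently.
* Problem sizes in the validation suite: recovery checks use 200
  replicated surveys of 2 000 households (the design's natural size);
  bootstrap coverage is assessed at $B = 100$ over the same replicates;
  the delta-method type-I error at $n = 500$ over 500 null replicates.

## Known limitations

* The cost-attribution model is linear-additive OLS; two-part or
  gamma-GLM cost models are out of scope, as is any decomposition of the
  concentration index.
* No impoverishment (poverty-line crossing) analysis; catastrophe only.
* The percentile bootstrap at the default $B = 100$ undercovers slightly;
  raise `bootstrap_reps` for final inference.
* The data model assumes complete records; there is no imputation of
  missing expenditure components.
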