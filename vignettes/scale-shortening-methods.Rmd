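---
title: "Rasch-based shortening of polytomous rating scales: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasch-based shortening of polytomous rating scales: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`raschshort` implements a complete workflow for shortening a polytomous
rating scale — such as a multi-subscale burnout questionnaire rated on five
frequency categories — under the partial credit Rasch model, together with
the measurement diagnostics that justify each elimination and an
ordinal-to-interval conversion of the final instrument's scores. This
vignette lays out the model, the statistics, the numerical choices, and the
limits of what the included simulations demonstrate.

## The partial credit model

For item $i$ with maximum score $m_i$ and person location $\theta_v$
(logits), the probability of response $x \in \{0, \dots, m_i\}$ is

$$P(X_{vi} = x) = \frac{\exp\!\big(\sum_{k \le x} (\theta_v - \beta_{ik})\big)}
{\sum_{x'=0}^{m_i}\exp\!\big(\sum_{k \le x'} (\theta_v - \beta_{ik})\big)},$$

with the empty sum equal to zero. The uncentered thresholds $\beta_{ik}$ are
the points where adjacent categories are equally likely; the item location
is $\delta_i = \bar\beta_{i\cdot}$ and the centered thresholds
$\tau_{ik} = \beta_{ik} - \delta_i$ sum to zero within an item. Five
questionnaire categories ("never" … "always", coded 1–5) are analyzed as
scores 0–4.

### Estimation

Item thresholds are estimated by **conditional maximum likelihood** (CML,
`fit_pcm()`): the likelihood of the response patterns given the person
total scores, which removes the person parameters exactly and makes the
item estimates invariant to the person distribution — the defining Rasch
property, and the reason two samples with different burnout levels should
return the same item calibration. The conditional likelihood is evaluated
with polytomous elementary symmetric functions (the summation algorithm)
carried entirely in log space, so instruments as long as 23 five-category
items (or four testlets with up to 33 categories) cause no overflow.
Maximization is Newton–Raphson with step halving on the exact conditional
information matrix, a step-norm cap of 5 logits per iteration, convergence
at gradient $\infty$-norm $< 10^{-8}$, and at most 200 iterations. The null
direction of the conditional likelihood (a common shift of all thresholds)
is removed by a sum-to-zero constraint during iteration, and the reported
metric centers the item locations at zero, matching the convention that the
item mean is constrained to 0. Standard errors come from the inverse
conditional information, carried through the centering by the delta method.

Estimation requires every category of every item to be observed at least
once; a never-observed ("null") category is reported as an error naming the
item and category rather than silently dropped.

Person measurement (`person_estimates()`) uses the sufficiency of the raw
total: one maximum-likelihood estimate per total, solving
$\sum_i E_i(\theta) = r$. Extreme totals (0 and the maximum) have no finite
ML estimate; they are adjusted inward by `extreme_adjust` score units
(default 0.3) before solving. This one-constant rule is an explicit,
configurable stand-in for the unpublished extrapolation used by commercial
Rasch software; it produces finite, strictly ordered endpoint estimates,
which is all the downstream conversion table needs. Standard errors are
$1/\sqrt{\text{test information}}$.

## Fit diagnostics

Four item-fit indicators are computed at every step
(`summary_fit()` assembles them):

1. **Item fit residuals** (`item_fit_residuals()`). Standardized residuals
   $z_{vi} = (x_{vi} - E_{vi})/\sqrt{W_{vi}}$ are summed as
   $\sum_v z_{vi}^2$ and mapped to an approximate standard normal deviate by
   the Wilson–Hilferty cube-root transformation, screened against
   $\pm 2.5$. Negative values mean overfit (redundancy, Guttman-like
   response patterns); positive values mean underfit. The degrees of
   freedom are $n(I-1)/I$ per item and $I-1$ per person: each estimated
   person location absorbs one degree of freedom spread across the $I$
   items. (With df $= n$ the null distribution of the item statistic sits
   near $-1.3$ rather than 0, because person-estimate shrinkage makes
   $\sum_v z_{vi}^2$ systematically smaller than $n$; the corrected df give
   an empirical $\sum z^2/\mathrm{df}$ ratio of 1.02 under the null.) The
   exact transform used by RUMM-type software is unpublished; this is an
   approximation matching its mean-0/SD-1 convention, not a numerical
   replication.
2. **Item-trait interaction $\chi^2$** (`item_trait_chisq()`). Non-extreme
   persons are ranked by $\hat\theta$ and split into $G$ equal-count class
   intervals ($G = \min(10, \lfloor n/50 \rfloor)$ by default, ties broken
   by stable person order); per item,
   $\chi^2_i = \sum_g (\sum_{v \in g} (x_{vi}-E_{vi}))^2 / \sum_{v\in g} W_{vi}$
   on $G-1$ df. The total statistic sums over items. Per-item p-values are
   Bonferroni-adjusted within the item family at $\alpha = 0.01$.
3. **Threshold ordering** (`check_threshold_ordering()`): categories work
   as intended iff $\beta_{i1} < \dots < \beta_{im_i}$.
4. **Residual correlations** (`residual_correlations()`): local dependency
   is flagged for any item pair whose residual correlation exceeds the
   average off-diagonal correlation by more than 0.2. Under
   unidimensionality that average is $\approx -1/(I-1)$, so the critical
   value falls near $0.2 - 1/(I-1)$ — about 0.15 for 19 items, 0.13–0.12
   as the roster shrinks toward 13.

Reliability is the **person separation index**
$\mathrm{PSI} = (\widehat{\mathrm{Var}}(\hat\theta) - \overline{SE^2}) /
\widehat{\mathrm{Var}}(\hat\theta)$ over non-extreme persons, floored at 0
in reports (the raw value is kept).

### Smith's unidimensionality test

`smith_unidimensionality()` performs a principal component analysis of the
standardized-residual correlations, splits the items by the sign of their
first-component loadings (|loading| < 0.05 leaves an item out of both
sets — the near-zero rule), estimates every person on both subsets with
item parameters **anchored from the full fit** (so the two estimates share
one metric), and computes per-person
$t_v = (\hat\theta_v^A - \hat\theta_v^B)/\sqrt{SE_A^2 + SE_B^2}$, treating
the two errors as independent (the subsets are disjoint). Persons extreme
on either subset are excluded. The scale passes when the exact
Clopper–Pearson 95% lower bound of the percentage of $|t_v| > 1.96$ falls
below 5%.

### Differential item functioning

`dif_anova()` runs, per item and person factor, a two-way fixed-effects
ANOVA of the standardized residuals on factor, class interval, and their
interaction. The factor main effect is uniform DIF; the interaction is
non-uniform DIF. Because equal-count intervals crossed with covariates are
unbalanced, Type II sums of squares are used (via `car::Anova`).
Bonferroni adjustment spans the item $\times$ factor family at
$\alpha = 0.01$. Age enters dichotomized at the sample median, ties to the
lower group. Empty factor-by-interval cells are handled by merging adjacent
intervals (logged) or, optionally, by an error.

`resolve_artificial_dif()` distinguishes real from artificial DIF: the
flagged item with the highest uniform-DIF F is split into group-specific
virtual items by refitting the model within each group and aligning the
group metrics on the mean location of the unsplit items. Items whose flags
vanish after the split showed artificial DIF (their apparent DIF was
induced through the person estimates by the truly biased item); the split
item's group locations are compared by a normal-theory difference test.
When nothing is flagged the resolution returns its input unchanged.

## Testlets, latent structure, and score conversion

When residual correlations map onto the subscale structure, the items of
each subscale are summed into a **testlet** super-item
(`form_testlets()`) and the four-testlet instrument is re-analyzed; the
dependency is absorbed into the testlet's category structure. Summed-score
categories that never occur are collapsed to consecutive ranks (logged), or
reported as an error if collapsing is disabled.

`latent_structure()` quantifies how much the subscales measure one thing.
Each subscale is fitted as its own short PCM instrument; its reliability is
the PSI of that fit, and the observed correlations between the
per-subscale person estimates are disattenuated,
$r_{kl} = \mathrm{corr}(\hat\theta_k, \hat\theta_l)/\sqrt{\rho_k \rho_l}$,
capped at 1. (An earlier design measured persons on the joint testlet-fit
metric instead; the testlet metric's compression understates subscale
reliability badly at off-target person distributions, so the conventional
separate-fit disattenuation route is used.) With true variances
$t_k = \rho_k \mathrm{Var}(\hat\theta_k)$ and $\bar c$ the mean latent
correlation, the **explained common variance** is

$$\mathrm{ECV} = \frac{\bar c\, (\sum_k \sqrt{t_k})^2}
{\sum_k t_k + \sum_{k \ne l} r_{kl}\sqrt{t_k t_l}} \in [0, 1],$$

which is 1 when all latent correlations are 1 and tends to 0 under
independence. This is an operationalization chosen for those limit
properties; published variants differ in detail. Note the ratio amplifies
small-sample noise in $\bar c$ about fourfold with four subscales, which is
why the package's limit tests run at $n = 10{,}000$.

Score conversion (`conversion_table()`, `metric_from_logit()`,
`apply_conversion()`) maps every raw total $r$ to its raw mean on the 1–5
rating scale ($1 + 4r/R$, a 49-row grid for 12 five-category items), its
person logit, and a linear 1–5 **interval metric**
$M = 1 + 4(\hat\theta - \theta_{\min})/(\theta_{\max} - \theta_{\min})$
anchored at the extrapolated endpoint estimates of the analyzed instrument
(data-dependent anchors). Conversion of raw means is valid for complete
responses only: off-grid means are rejected, never imputed. Serialized
tables round to 2 decimals, half away from zero; full precision is kept in
memory.

## The shortening pipeline

`run_shortening()` iterates: analyze the current roster (CML fit, persons,
all four indicators, Smith's test, DIF for the configured factors), then
remove **one item from every subscale still above `min_items`** (default
3), chosen by `flag_elimination_candidates()`: items are scored by how many
indicators fire (|FR| > 2.5, significant $\chi^2$, any DIF flag, flagged
residual-correlation pair, subject-matter content category 3 or 4), with
ties broken by larger residual-correlation excess, then by location
redundancy (smaller minimum location distance to a retained item), then by
stable item order. Protected items — the configuration's encoding of
"theoretically important, keep" — are down-weighted. For a 23-item
instrument with subscale sizes 8/5/5/5 this yields the roster schedule
23 → 19 → 15 → 14 → 13 → 12: two steps remove one item per subscale, after
which only the largest subscale continues shedding one item per step.

When the top two candidates of a subscale tie exactly on a positive
indicator score (and on the correlation-excess tie-break), **both branches
are analyzed** one step ahead and the branch with the lower total $\chi^2$
wins (larger location spread on an exact tie). One branch evaluation is
performed per step, on the first tied subscale in stable order.

The pipeline is deterministic given data and configuration. It reproduces
the *procedure* of expert-guided shortening; the expert judgment itself
enters only as configuration (content flags, protected items), so on real
data the selected items depend on those inputs by design. Every removal
carries a machine-readable rationale naming the indicators that fired. A
final subscale-testlet analysis, latent-structure summary, and conversion
table are appended automatically; the conversion grid is built from the
testlet fit when no category collapsing occurred (testlet totals equal item
totals) and from the item-level fit otherwise.

## The synthetic-data generator

`sim_pcm()` draws from the fitted model itself — the null generator behind
every calibration test. `sim_bat_like()` emulates the response structure of
a 23-item, four-subscale burnout questionnaire (EX 8, MD 5, CI 5, EI 5;
five categories): person effect $\theta_{vs} = g_v + u_{vs}$ with a general
burnout factor $g_v \sim N(-1.04, 1.045^2)$ — the documented person
distribution of the emulated study population, whose negative mean
reproduces its suboptimal targeting (many respondents below the easiest
items) — plus subscale factors $u_{vs} \sim N(0, 0.5^2)$, a bifactor-style
kernel chosen over item chaining because it matches the testlet remedy and
makes the latent-correlation ground truth computable
($\mathrm{corr} = 1.045^2/(1.045^2 + 0.5^2) \approx 0.81$). Item locations
are staggered so exhaustion items sit lowest and emotional-impairment items
highest (the typical burnout item hierarchy), spanning $\pm 0.75$ logits;
generating thresholds are equally spaced at $\pm 0.9, \pm 0.3$. The
threshold span was set, before any testing, so that the rarest
item-category keeps a comfortable expected count (≳ 10 at $n = 800$) under
the stated person distribution — mirroring the emulated study, in which
every category of every item was observed and all thresholds were ordered.
Covariates form four exactly equal gender × country strata, age is drawn
around 41 and median-split. `inject_dif()` adds uniform (location shift) or
non-uniform (group-specific slope) DIF to the generating kernel;
`stratified_subsample()` draws fixed-size per-stratum subsamples without
replacement, e.g. 4 × 200 twice for cross-validation.

What the generator does **not** emulate: the skew and heaping of real
rating data beyond its first two moments, item-specific threshold shapes,
correlated covariates, or missingness (the package operates on complete
cases throughout, with `read_responses_csv()` dropping and counting
incomplete rows). Passing calibration tests on these simulations therefore
shows the statistics behave as designed under the model and the emulated
design — not that any particular real dataset fits the model.

## Numerical choices and problem sizes

* Elementary symmetric functions and all pattern weights in log space;
  leave-one-out and leave-two-out gamma vectors by prefix/suffix
  convolutions.
* Newton–Raphson: step cap 5, step halving to a minimum factor of
  $2^{-33}$, gradient tolerance $10^{-8}$, 200 iterations.
* Score-to-theta roots by `uniroot` on $[-30, 30]$ (extended upward if
  needed) at tolerance $10^{-10}$; expected-score monotonicity guarantees
  uniqueness.
* Ties in person ranking broken by stable order; Bonferroni families are
  items (fit $\chi^2$) and items × factors (DIF), each at 0.01.
* Test-suite problem sizes: $n = 800$ for calibration and power runs (10
  seeds where distributional claims are made, 5 where a binary detection
  count suffices), $n = 2000$ for parameter-recovery and
  threshold-ordering recovery, $n = 10{,}000$ for asymptotic ECV limits,
  brute-force oracles on ≤ 4 items × ≤ 100 persons.

## Known limitations

* CML here is summation-algorithm based; pairwise-conditional software
  (e.g. RUMM2030) will differ numerically though both are
  person-distribution-free. Numeric equality with published outputs of such
  software is not claimed anywhere.
* The extreme-score adjustment (0.3) and the item fit-residual df
  correction are documented approximations to unpublished conventions.
* The ECV formula is one defensible operationalization; treat reported ECV
  as comparable within this package, not across packages.
* Branch evaluation explores exactly two candidates on one subscale per
  step; a full combinatorial search over near-ties is out of scope.
* `resolve_artificial_dif()` assumes the group-specific refits are
  estimable; a split that empties a category advises category collapsing
  instead of proceeding.
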