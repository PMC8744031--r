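---
title: "Measuring lifespan inequality against a maximal-lifespan benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lifespan inequality against a maximal-lifespan benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeineq)
```

## The measurement problem

Length of life is a bounded variable: nobody has outlived 122.45 years.
As a population's life expectancy $e_0$ climbs toward that bound, the
age-at-death distribution has less and less room to spread out, so the
classical inequality indices — the absolute Gini (AID), the Gini
coefficient $G$, the standard deviation, $e^\dagger$ — decline partly
for mechanical reasons. `lifeineq` measures inequality *relative to the
most unequal distribution that the same mean and the same bound allow*,
so that comparisons between populations with very different longevity
levels are not contaminated by the shrinking support.

## The model

Work on the discrete age grid $x = 0, 1, \dots, A$ with an open terminal
interval. A life table's deaths column is normalized into shares $d_x$
($\sum_x d_x = 1$), and each interval contributes its mean age at death
$\bar{x} = x + a_x$, where $a_x$ is the average time lived in the
interval by those dying in it. Then

$$\mathrm{AID} = \tfrac12 \sum_x \sum_y d_x d_y\,|\bar x - \bar y|,
\qquad G = \mathrm{AID}/e_0 .$$

Given a maximal lifespan $\omega$, the most unequal distribution with
mean $e_0$ is two-point: a share $s_1 = 1 - e_0/\omega$ dies at exact
age 0 and the rest at exact age $\omega$. Writing $M(e_0,\omega)$ for
this benchmark, the normalized index of any base index $I$ is

$$I^*(A,\omega) = \frac{I(A)}{I\bigl(M(e_0(A),\omega)\bigr)} .$$

Evaluating the denominators in closed form:
$\mathrm{AID}_{\max} = e_0(\omega-e_0)/\omega$,
$G_{\max} = (\omega-e_0)/\omega$,
$\sigma_{\max} = \sqrt{e_0(\omega-e_0)}$,
$\mathrm{CV}_{\max} = \sqrt{(\omega-e_0)/e_0}$,
$e^\dagger_{\max} = e_0(\omega-e_0)/\omega$,
$H_{\max} = (\omega-e_0)/\omega$. Each closed form is unit-tested
against direct evaluation of the index on the benchmark distribution.
Two consequences matter in practice:

* $\mathrm{AID}^* \equiv G^*$ — normalization erases the
  absolute-versus-relative distinction (tested to $10^{-12}$);
* $G^*(A,\omega) = G(A)\,\omega/(\omega-e_0)$ decreases strictly in
  $\omega$ and converges to the classical Gini, which is therefore the
  unbounded-lifespan special case.

### Where maximality genuinely holds — and where it does not

That $M$ maximizes the variance is the Bhatia–Davis inequality
($\sigma^2 \le (\omega - e_0)e_0$, equality exactly at the two-point
distribution); the AID and Gini cases follow from majorization, and CV
from the variance. The package asserts these four maximality properties
on large random suites.

$e^\dagger$ is different. With the demographic convention that a death
at age $a$ loses the remaining expectancy $e(a)$ *of the same
population* (so $e(0) = e_0$, and deaths at $\omega$ lose nothing), the
benchmark value is $e^\dagger(M) = s_1 e_0 = e_0(\omega-e_0)/\omega$ —
but $M$ is **not** the maximizer. A near-geometric (memoryless) survival
curve has $e^\dagger \approx e_0$, which exceeds
$e_0(\omega-e_0)/\omega$ whenever deaths spread far enough; a frozen
counterexample lives in the test suite. The normalized
$e^{\dagger*}$ and $H^*$ are therefore reported as plain ratios against
the benchmark value and can exceed 1. Only the Gini family and the
moment indices carry the "share of maximal inequality" interpretation.

## Conventions and numerical choices

* **Interval placement.** Indices always consume the life table's own
  $\bar x = x + a_x$; bare weight vectors default to midpoints
  ($a_x = 0.5$) with an explicit point-mass option used by worked
  examples and by the benchmark itself. The benchmark puts exact point
  masses at 0 and $\omega$; the closed forms hold only under that
  convention, so the two conventions are never mixed silently.
* **$e^\dagger$ quadrature.** For a life table, the expectancy at the
  fractional death age $x + a_x$ interpolates the $e_x$ column linearly
  (clamped at the grid ends); an `integer` option reads $e_x$ at the
  interval's integer age instead. The two differ by well under half a
  year on smooth schedules.
* **AID evaluation.** The reference implementation is the literal
  $O(n^2)$ double sum; the default is the sorted cumulative-share form,
  $\mathrm{AID} = \sum_j d_j \bar x_j (F_j + F_{j-1} - 1)$, which agrees
  to $10^{-12}$ and is what panel-scale work uses.
* **$\omega$ policy.** Default $\omega = 122$, above every HMD table's
  top age $110 + a_{110}$; it can be overridden per call or supplied as
  a year-indexed record-lifespan series. Distributions carrying death
  mass above $\omega$ are rejected rather than truncated. $e_0 \ge
  \omega$ is a domain error ("no room for variability").
* **Crossing threshold.** For $G_A \ne G_B$ the curves
  $G\,\omega/(\omega-e_0)$ cross at
  $\omega^* = (G_A e_{0B} - G_B e_{0A})/(G_A - G_B)$, at most once above
  the larger $e_0$; verdicts are `partial` when $\omega^*$ exceeds the
  admissible floor (default 122), otherwise `complete` with the order
  read at the floor. Equal Ginis with different means are complete;
  exact ties are reported as ties, never silently ranked. The closed
  form is verified against bisection and grid scans.
* **Decomposition.** Changes in an index between two tables are
  attributed to ages with the continuous-change (Horiuchi) method over
  age-specific rates $m_x$: proportional (log-linear) paths, 20
  substeps by default, midpoint two-sided perturbations, closed-interval
  $a_x$ held at the first table's values, the open interval's $a_x$
  recomputed as $1/m_x$ at every evaluation. Rates with a zero endpoint
  fall back to a linear path and are flagged. The additivity residual is
  reported, typically $10^{-5}$ relative at 20 steps. The integration
  loop uses a stripped-down evaluator with the same arithmetic as the
  public life-table builder (agreement unit-tested).
* **Threshold age.** Reported as the first age of the terminal positive
  run of contributions (zeros skipped); absent, with a diagnostic, when
  contributions never switch from negative to positive. On a modern
  schedule ($e_0 \approx 79$) the Gini threshold sits near 78, so
  mortality improvements at 65–77 still *reduce* inequality —
  sign-pattern tests use improvements above 85 when they need an
  all-positive scenario.

## What the synthetic generator does and does not emulate

`generate_transition_panel()` drives a five-parameter Siler hazard
$m(x) = a_1 e^{-b_1 x} + a_2 + a_3 e^{b_3 x}$ log-linearly from a
pre-transition regime ($a_1 = 0.25$, $b_1 = 1.0$, $a_2 = 0.01$,
$a_3 = 8\cdot10^{-5}$, $b_3 = 0.09$; $e_0 \approx 35$) to a modern one
($a_1 = 0.0015$, $b_1 = 1.3$, $a_2 = 2\cdot10^{-4}$,
$a_3 = 2\cdot10^{-5}$, $b_3 = 0.10$; $e_0 \approx 79$), values chosen
as typical of the historical European transition. Populations differ by
fixed log-normal (10%) level offsets on $a_1, a_2, a_3$; infant deaths
use $a_0 = 0.3$, other closed intervals 0.5. A non-decreasing record
series rising from 107.26 to 122.45 accompanies the panel, and an
optional Poisson sampling layer draws death counts at a given exposure
(converging back to the deterministic table as exposure grows). One
seeded stream makes every panel bit-reproducible.

The generator reproduces the qualitative regime the analyses assume —
rising $e_0$, falling $G$, rectangularization, record lifespans growing
more slowly than $e_0$ — but not cohort effects, wars and epidemics,
migration, country-specific age patterns, or HMD data revisions. Green
tests on this panel therefore validate the *measurement machinery*, not
any empirical claim about a particular country.

## Problem sizes used by the test and acceptance suites

Maximality and unit-range: 10,000 random discrete distributions;
AID\* ≡ G\*: 1,000; large-$\omega$ limit: 200 at $\omega = 10^5 e_0$;
$\omega^*$ closed form vs bisection and single-crossing scans: 1,000
random pairs; Horiuchi additivity and antisymmetry: 100 random Siler
pairs for $G$ and $G^*$ at 20 substeps; panels of 2–4 populations over
25–60 years.

## Known limitations

* Period 1×1 tables only; no cohort or abridged (5-year) tables, no
  rate smoothing or graduation.
* $e^{\dagger*}$ and $H^*$ are benchmark ratios, not shares of a true
  maximum (see above); robustness analytics ($\omega^*$, rank
  consistency) are closed-form for the Gini family only, other indices
  would need grid scans.
* The decomposition holds closed-interval $a_x$ fixed along the path;
  when the two tables' $a_x$ differ materially (real HMD infant $a_0$
  shifts), the residual absorbs the difference.
* $\omega$ itself is treated as a free parameter throughout; the
  package estimates nothing about the true limit to human lifespan.
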