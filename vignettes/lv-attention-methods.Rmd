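---
title: "Methods: nonautonomous Lotka-Volterra inference for attention shares"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonautonomous Lotka-Volterra inference for attention shares}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvattention)
```

## The model and its assumptions

`lvattention` treats public attention as a market. At each week `t`, a
search act goes to one of `N` tracked topics or to an *outside search*
absorbing everything else. Topic shares follow a logit discrete-choice
model in latent utilities $f_i(t)$:

$$S_i(t) = \frac{e^{f_i(t)}}{1 + \sum_{j=1}^N e^{f_j(t)}}, \qquad
  S_0(t) = \frac{1}{1 + \sum_{j=1}^N e^{f_j(t)}}.$$

If every $f_i$ is of class $C^2$, these shares are the unique global
solution of the initial-value problem for the integrable nonautonomous
Lotka-Volterra system

$$\dot S_i = \underbrace{g_i(t)\,S_i(1-S_i)}_{\text{logistic growth}}
  - \underbrace{\sum_{j\ne i} g_j(t)\,S_j S_i}_{\text{competition}},
  \qquad g_i(t) = \dot f_i(t).$$

The package exploits this equivalence in both directions. The analysis
pipeline never integrates an ODE: it recovers utilities from shares
($f_i = \ln S_i - \ln S_0$, the exact inverse of the logit map), smooths
them, differentiates analytically, and reads the interactions off the
signs of the $g_i$. The numerical integrator (`integrate_forward()`, an
adaptive Dormand-Prince 5(4) scheme with tolerances $10^{-9}/10^{-12}$)
exists purely as an independent *test oracle*: the suite checks that
closed-form and integrated trajectories agree to $10^{-6}$ in sup norm
on random smooth systems, which validates both the closed form and the
right-hand-side implementation at once.

Key modelling assumptions, inherited from the share formulation:

* within a week, relative interest values are proportional to the
  fraction of all searches each topic received;
* the tracked topics jointly account for a constant fraction
  $\alpha$ of all searches (see *The coverage constant* below);
* utilities are smooth ($C^2$) so that interaction coefficients exist
  everywhere; all abrupt change is expressed through fast but smooth
  utility movement;
* one coefficient per topic: a topic cannot simultaneously be predator
  of one topic and prey of another at the same instant. This structural
  economy is inherent to the model class, not a fitted restriction.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `coverage` ($\alpha$) | 0.5 | share | outside share is $1-\alpha$; results provably invariant (below) |
| `order` (Fourier $n$) | automatic, cap 6 | - | bias/variance of the utility smoother |
| `tau_multiple` ($\tau$/span) | 1 | - | Fourier half-period; 1 = no periodicity assumed inside the window |
| `eps` | 10% of $\max_t\max_i \lvert g_i(t)\rvert$ | per week | zero-band for sign classification |
| `smooth_weeks` | 0 (off) | weeks | majority-vote label smoothing near crossings |
| `window` | 6 | weeks | changepoint detector window |
| `value_floor` | 0.5 | 0-100 scale | replaces zeros/"<1" cells; keeps log-odds finite |

### The coverage constant

Trends-style data only determines within-panel ratios. To build shares
with a positive outside good, the panel is renormalized per week and
scaled by a constant $\alpha \in (0,1)$. This constant is not
estimable from the data and does not need to be: it shifts every
recovered utility by the same additive constant
$\ln\alpha - \ln(1-\alpha)$, which the derivative removes. The suite
asserts numerically that coefficient curves under $\alpha = 0.3$ and
$\alpha = 0.7$ agree to $10^{-9}$ and give identical role labels. A
*time-varying* coverage would break this invariance and is deliberately
not implemented.

### Fourier order selection

The default order is the smallest $n \le 6$ whose pooled utility-scale
residual MSE is within a factor 2 of the cap-order MSE. Two deliberate
choices here:

* **relative, not absolute.** An absolute share-scale MSE threshold is
  not scale-invariant: it changes meaning with $\alpha$ and with the
  overall share level, and on regime-shift data it can be satisfied by
  an order too low to resolve the shift at all (an order-2 fit of the
  bundled preset already sits below `1e-3` on the share scale while
  missing the week-44 break entirely).
* **utility scale, not share scale.** Utility residuals are *exactly*
  invariant to $\alpha$ (the constant shift is absorbed by the
  intercept), so the selected order - and hence every downstream result -
  cannot depend on the arbitrary coverage constant.

The cap of 6 for ~52 weekly points (13 basis functions) guards against
interpolating observation noise; fits at the cap already resolve
week-scale structure. Exactly representable data short-circuits the rule:
residuals at machine zero select the generating order, which is what the
exact-recovery tests rely on.

### The zero-threshold `eps`

Role classification needs a band inside which a coefficient counts as
zero. The default is 10% of the *maximum* absolute coefficient over the
run: the strongest interaction observed sets the scale against which "no
interaction" is judged. A median-based threshold was considered and
rejected: in regime-shift data the median sits at the quiet-period noise
floor, the band collapses toward zero, and every noise wiggle becomes a
spurious sign - precisely in the quiet period where the scientifically
correct label is neutralism.

### Changepoint detection

`detect_intensification()` scans all candidate indices and maximizes the
ratio of trailing-window to leading-window mean intensity (ties to the
earliest index; 0/0 ratios count as 1). Two documented degeneracies: a
flat profile returns the earliest candidate, and a monotone ramp rising
from zero also resolves to the earliest candidate, because the ratio is
largest where the leading window hugs the near-zero start.

Inside `run_analysis()`, the detector runs on the *empirical* intensity -
centered differences of the recovered utility samples - rather than on
the fitted-coefficient intensity. A global Fourier basis necessarily
smears an abrupt regime shift across neighbouring weeks, which biases
the window-ratio detector two to three weeks early; the unsmoothed
series is noisier pointwise but localizes the break correctly. The
smooth fitted intensity remains the reported curve.

## What the synthetic generator emulates - and what it does not

`generate_trends()` produces weekly panels from known ground truth:
per-regime Fourier utilities blended over a 2-week $C^2$ ramp (so the
smoothness assumption holds *through* regime changes), shares via the
closed-form logit map, joint 0-100 normalization in which exactly one
cell of the noise-free panel equals 100 (the multi-topic Trends
convention), additive iid Gaussian observation noise on the 0-100 scale
clamped to $[0,100]$, and optional integer rounding. Determinism is a
contract: identical seeds give identical panels.

It does **not** emulate: the sampling design of the real service
(resampled extracts differ between download dates), deduplication of
repeated searches, cross-correlated or heteroscedastic sampling error,
or any real semantic coupling between topics. A green test therefore
establishes that the *estimator* recovers the *stated model's* truth
under iid observation noise - not that the model is a faithful
description of real search behaviour.

The bundled `pandemic_preset()` states one concrete world: 4 topics, 52
weeks, quiet utilities with small seasonal terms for 44 weeks, then a
regime in which topic 1 gains log-odds at +0.28/week while the others
lose 0.10, 0.08 and 0.12 per week (value-matched at the changepoint so
utilities stay continuous). These constants are the package's own
realization of the qualitative structure it is meant to exhibit - weak
early interactions, an intensity explosion after week 44, one predator,
mutualism among the rest - and were frozen after verifying they produce
that structure; they are not fitted to any dataset.

## Numerical choices

* **Least squares** via QR decomposition (`qr()`/`qr.coef`); rank
  deficiency raises an error naming the coefficient count, never a
  silent regularization.
* **Derivatives** are analytic throughout (the Fourier and polynomial
  families are closed under differentiation); a centered
  finite-difference oracle cross-checks them in the suite.
* **Degenerate inputs**: zeros and "<1" cells are floored at 0.5 (the
  midpoint of the censored interval) before the log-odds transform;
  the floor is configurable and its effect is confined to near-zero
  weeks.
* **Identifiability through the 0-100 panel.** The per-week panel
  renormalization adds a common time-varying term (a log-sum-exp of the
  utilities) to every recovered utility. This gauge term lies outside
  any finite Fourier span, so *individual* coefficients recovered
  through the full observation path carry a common-mode error, while
  *pairwise differences* $g_i - g_j$ are recovered exactly (the suite
  asserts $<10^{-6}$). Exact recovery of individual coefficients is
  tested from the generator's ground-truth shares, where the log-odds
  inversion is exact. In practice the common mode is small whenever no
  single topic dominates the panel's total movement; role labels on the
  bundled preset agree with truth at 94-96% of non-boundary points
  under noise.
* **Edge effects.** The derivative of a least-squares fit is poorly
  constrained at the first and last sample; role labels at the window
  edges should not be over-interpreted, and the package's own
  qualitative tests evaluate interior points.

## Known limitations

* Signs of $g_i$ describe co-movement within the stated share model;
  they are not causal claims about searchers.
* The one-coefficient-per-topic structure cannot express asymmetric
  pairwise mechanisms.
* The Fourier cap bounds how fast a change the smoother can represent;
  regime changes faster than ~2 weeks appear smeared in the fitted
  curves (the empirical intensity is provided for localization).
* Only the two smoother families named above are implemented - no
  splines or kernel smoothers.
* Areas are analyzed independently; there is no pooling across panels.
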