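---
title: "Correlation under measurement error: models, bias and correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation under measurement error: models, bias and correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attencor)
```

## The model

The error-free pair $(x_0, y_0)$ is bivariate normal with means
$\mu_{x_0}, \mu_{y_0}$, biological variances $\sigma_{x_0}^2,
\sigma_{y_0}^2$ and true correlation $\rho_0$. A measurement passes the
signal through a structural error equation; the most general form
implemented here is

$$x = x_0\,(1 + \varepsilon_{mu_x} + \varepsilon_{mc_x}) +
      \varepsilon_{au_x} + \varepsilon_{ac_x},$$

and likewise for $y$. All $\varepsilon$ terms are zero-mean normal,
independent of the signal and of each other, except that the correlated
pairs $(\varepsilon_{ac_x}, \varepsilon_{ac_y})$ and
$(\varepsilon_{mc_x}, \varepsilon_{mc_y})$ have correlations $\pi_{ac}$
and $\pi_{mc}$. The five `model_kind`s are nested restrictions:
`none` (all variances zero), `additive` and `multiplicative` (one branch
active), `realistic` (both, with perfectly (anti-)correlated shared
terms, $\pi = \pm 1$ and equal correlated variances), and `generalized`
(free $\pi \in [-1, 1]$, per-variable correlated variances). Internally
*everything* — simulator, expected correlation, correction — is computed
from the generalized form; the special models are exact reductions, which
the test suite verifies to $10^{-14}$.

Writing $\xi^2 = \sigma_{au}^2/\sigma_0^2$,
$\gamma = \sigma_{ac}/\sigma_0$, $\delta = \mu_0/\sigma_0$ per variable,
the population (large-sample) correlation of the measured pair is

$$\rho = A\left[\rho_0\,(1 + \pi_{mc}\sigma_{mc_x}\sigma_{mc_y})
  + \pi_{ac}\gamma_x\gamma_y
  + \delta_x\delta_y\,\pi_{mc}\sigma_{mc_x}\sigma_{mc_y}\right],$$

where the attenuation coefficient
$A = \sigma_{x_0}\sigma_{y_0}/\sqrt{\mathrm{var}(x)\,\mathrm{var}(y)}$
uses the model-implied measured variances
$\mathrm{var}(x) = \sigma_{x_0}^2 +
(\sigma_{x_0}^2+\mu_{x_0}^2)(\sigma_{mu_x}^2+\sigma_{mc_x}^2) +
\sigma_{au_x}^2 + \sigma_{ac_x}^2$. $A \in (0, 1]$, equals 1 exactly in
the error-free case, and decreases in every error variance. The
correction estimator is the algebraic inverse; when a corrected value
exceeds $\pm 1$ (possible, because disattenuation inflates sampling
noise) it is clipped, flagged, and the raw value kept for diagnostics.

### Assumptions worth keeping in mind

* Normal signal and errors. Under multiplicative error the *measured*
  variables are products of normals, hence not normal; the first two
  moments used by the formulas are exact regardless, but sampling
  distributions are heavier-tailed than normal theory suggests (this is
  why the equivalence tests use an influence-function standard error for
  $r$ rather than $(1-\rho^2)/\sqrt{n}$).
* No truncation: multiplicative and realistic draws can go negative for
  small $\mu_0$ — the Gaussian model implies it, and no censoring or
  detection-limit mechanism is modeled.
* Error-variance components are *inputs*. Estimating them from data is
  deliberately out of scope (only the pooled within-replicate variance
  for the purely additive uncorrelated case is provided,
  `estimate_additive_error_var()`, as the one estimator with a settled
  classical justification).

## Bias regimes and limiting surfaces

`classify_regime()` compares $\rho$ with $\rho_0$ *numerically* at
absolute tolerance $10^{-12}$: `unbiased`, `attenuated`
($|\rho| < |\rho_0|$), `inflated`, or `sign_flipped`. The printed
inequality tables accompanying these rules in the source material are
internally inconsistent (the $\rho_0 < 0$ branch repeats the
$\rho_0 > 0$ conditions, and the sign-flip condition is stated as
$|\rho_0| > \sqrt{\gamma_x\gamma_y}$ while the defining algebra gives a
flip for positively correlated error exactly when
$|\rho_0| < \gamma_x\gamma_y$). We therefore derive regimes from the
$\rho$ formula itself, and verified the sign-flip condition by Monte
Carlo; the algebra governs the behavior.

For the additive model with correlated error, the boundary between
attenuation and inflation is the limiting surface
$S = \frac{A}{1-A}\gamma_x\gamma_y$ (positively correlated error;
$\frac{A}{A-1}\gamma_x\gamma_y$ for negative). In the symmetric case
this simplifies to $S = \gamma^2/(\xi^2+\gamma^2)$, which is what
`limiting_surface()` returns; the regime classifier provably flips
across it, which the tests check on a grid.

## The random-number architecture

Each simulator derives one L'Ecuyer-CMRG substream per stochastic
component (signal, each uncorrelated error, each correlated pair) from
the root seed via `parallel::nextRNGStream()`, in a fixed canonical
order. Consequences: identical inputs give bit-identical output, and
switching one error component on or off never perturbs the draws of the
others (tested). Components with zero variance draw nothing. The global
RNG state of the session is saved and restored around every draw.

Error variances can be given absolutely or as fractions of biological
variance (`relative = TRUE`): uncorrelated additive components scale
with their own variable's variance, shared correlated additive
components with the *average* biological variance (matching the
"percent of the average variance" convention common in the field);
multiplicative variances are dimensionless already and are never
rescaled.

## What the synthetic data emulates — and what it does not

No real data set is consumed. `synth_covariance()` stands in for the
moments of a real metabolomics panel: means uniform on $(0, 23.4)$ (the
upper bound mirrors the maximum abundance reported for the data set the
original experiments drew on), variances uniform on $(0.5, 3.5)$ —
centered on 2, consistent with the reported "error variance 0.1 is
about 5% of the average variance" — and a random correlation matrix
$\mathrm{cov2cor}(WW^\top)$, $W$ a $p \times p$ standard normal factor
matrix, which is positive definite almost surely and mixes signs at
realistic magnitudes. The envelope experiment's variance prior bound
(`var_scale = 2`) follows the same inference, since the original value
(the average variance of the real panel) is not printed anywhere.

What a green test on these fixtures establishes: the formulas, their
inverses, and the experiment machinery are correct for exactly-normal
signals with known error components. What it does not establish:
robustness to non-normal biology, detection limits, unknown or
misspecified error variances — all outside this package's scope.

## The kinetic network experiment

Biological variability for the network experiment comes from an
irreversible enzyme-catalyzed reaction (substrate P1, complex P2,
product P3) with Michaelis–Menten kinetics, rate constants
$k_1 = 30, k_{-1} = 20, k_2 = 10$, total enzyme $E_T = 1$, initial
substrate $P_1(0) = 5$, each jittered $\pm 10\%$ uniformly per profile,
sampled at $t = 0.4$. The published system of equations contains a
$-k_{-1}P_1$ term that violates mass conservation and contradicts the
stated mechanism; the default integrates the mass-conserving S/ES/P
scheme ($P_1+P_2+P_3$ constant to solver tolerance), with
`as_printed = TRUE` available for the literal system. Both variants are
pinned in the tests against an independent high-accuracy integration.
Since no ODE solver package is available in the target environment, the
package carries a standard adaptive Dormand–Prince 5(4) integrator
(rtol $10^{-8}$, atol $10^{-10}$ by default).

A documented irreproducibility: with the mass-conserving kinetics the
error-free pairwise correlations at $t = 0.4$ are roughly
$(0.46, -0.34, 0.20)$, and the fixed correlated-error variance 0.05
lifts two pairs to $\approx 0.70$–$0.76$; sweeping uncorrelated error up
to 25% of the biological variance attenuates them only to
$\approx 0.65$–$0.71$, which never crosses the 0.6 network threshold.
No faithful reading of the stated configuration (literal vs conserving
equations, absolute vs variance-fraction correlated error) robustly
reproduces the published "edges disappear around 15% error" pattern; the
corresponding acceptance assertion is intentionally left failing rather
than tuned, and the unit tests demonstrate genuine edge loss on an
extended 0–100% sweep, where the attenuation is strong enough.

## Numerical choices

* Pearson $r$ is `stats::cor` (consistent numerator/denominator
  normalization; the mixed-normalization variant sometimes printed
  evaluates to the same quantity).
* Quantiles use linear interpolation (`type = 7`).
* Regime comparisons at $10^{-12}$ absolute; reduction and inverse
  identities asserted at $10^{-14}$/$10^{-12}$.
* Degenerate envelope draws ($\sigma_0^2 \le 10^{-8}\,$`var_scale`) are
  rejected, redrawn and counted.
* `correct_matrix()` forces a unit diagonal and symmetry; it does not
  re-project the corrected matrix onto the positive-definite cone
  (corrected matrices can be indefinite; that is a property of
  element-wise disattenuation, reported rather than hidden).
* Replicate resampling uses the same replicate indices for both
  variables by default (`paired = TRUE`), since in the emulated
  experiment both resonances are read from the same replicate spectrum;
  `paired = FALSE` draws them independently.

## Known limitations

* Estimation of error-variance components from data: out of scope.
* No sampling distributions or hypothesis tests for $r$ under the error
  models.
* The multivariate simulator supports only the shared-scalar,
  positively-correlated error structure (the structure the multivariate
  experiments require); the generalized per-variable structure is
  bivariate.
* Plotting is intentionally absent; all experiment outputs are plain
  tables.
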