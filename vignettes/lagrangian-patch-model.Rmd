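---
title: "A moment-closure model of drifting plankton patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A moment-closure model of drifting plankton patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(planktonpatch)
library(dplyr)
```

## The model

`planktonpatch` simulates a planktonic ecosystem living inside a Lagrangian
patch of surface ocean water — a fixed body of fluid followed in its
co-moving frame, so translation and rotation drop out and what remains is
deformation, dilution, and biology.

**Geometry.** The patch is an ellipse with half-width $W$ (minor axis) and
half-length $L$ (major axis), size $S = W + L$ and area $A = \pi W L$.
Horizontal strain $\gamma$ stretches $L$ and compresses $W$ while
conserving area; eddy diffusion $\kappa$ grows both axes and entrains
surrounding water:

$$\frac{dW^2}{dt} = 2\kappa - 2\gamma W^2, \qquad
  \frac{dL^2}{dt} = 2\kappa + 2\gamma L^2, \qquad
  \frac{dA}{dt} = \pi\kappa\,\frac{W^2 + L^2}{W L}.$$

$dA/dt$ is the *dilution rate*: the rate at which outside water is
incorporated. Strain never dilutes directly, but by elongating the patch it
raises the perimeter-to-area ratio and makes diffusion more efficient.
Because strain and diffusivity are scale-dependent in the ocean, both are
power laws of the patch size, anchored at the initial size $S_0$:
$\gamma = \gamma_0 (S/S_0)^{-2/3}$ and $\kappa = \kappa_0 (S/S_0)^{+1}$
(both exponents configurable). This is what lets the model reproduce the
observed decrease-then-increase of a real patch's width, which constant
forcing cannot do.

**Tracers.** The patch carries an inorganic resource (iron, $p_r$) and a
phytoplankton consumer ($p_b$, expressed in iron currency). Each field is
split by Reynolds decomposition into a spatial mean plus fluctuation, and
the model state tracks the means, the two spatial variances, and the
resource–biomass covariance. Three processes drive them:

* *Entrainment* (dilution): means relax toward the surrounding values at
  rate $(dA/dt)/A$; second moments do the same, **plus** a production term
  equal to the product of mean contrasts — entraining water of a different
  composition creates patchiness from nothing. This is the analytic
  reason dilution and heterogeneity are inseparable.
* *Internal mixing*: variances and covariance decay exponentially at
  $\kappa/S^2$, the diffusive homogenization rate at the patch scale. Means
  are untouched.
* *Biology*: Monod uptake $\nu p_r/(p_r + k)$, linear mortality $m$, and a
  remineralized fraction $\alpha$. The moment closure truncates the
  Reynolds expansion at second order (third central moments dropped), so
  the mean growth acquires two corrections: resource variance *lowers* it
  (Monod is concave) and positive resource–biomass covariance *raises* it
  (biomass sitting where resource is rich grows faster than the mean-field
  estimate). The latter is the engine of the heterogeneity-driven bloom
  enhancement.

In **well-mixed mode** all second moments are pinned at zero — the
classical homogeneous-parcel assumption — giving a paired null model for
every experiment.

The surrounding is *mean-field and constant*: resource at the coexistence
steady state $r^\* = mk/(\nu - m)$, biomass at its observed background,
second moments zero. With $\alpha = 0$ the surrounding resource equation is
not strictly stationary (export slowly removes iron), so constancy is a
boundary condition of the model, not a consequence of its dynamics.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $W_0 = L_0$ | 5 | km | circular patch, 10 km across |
| $h$ | 10 | m | patch thickness (carbon conversion only) |
| $\gamma_0$ | 0.12 | day$^{-1}$ | initial strain (ensembles: 0.01–0.6) |
| $\kappa_0$ | 0.1 | km$^2$ day$^{-1}$ | initial diffusivity (ensembles: 0.01–0.6) |
| $\nu$ | 1.05 | day$^{-1}$ | maximum growth rate |
| $k$ | 2 | µmol m$^{-3}$ | half-saturation constant |
| $m$ | 0.05 | day$^{-1}$ | linear mortality |
| $\alpha$ | 0 | — | remineralized fraction |
| Fe:C | $10^{-5}$ | — | iron-to-carbon molar ratio |
| patch / surrounding iron | 1.0 / 0.1 | µmol m$^{-3}$ | fertilization pulse over steady state |
| biomass (everywhere) | 0.0249 | µmol m$^{-3}$ | background consumer, iron currency |
| $\tau$ | 30 (42 SOIREE) | days | integration window |
| $dt$ | 0.01 | days | RK4 step (~14.4 min) |

These defaults are the study conditions of the fertilization experiments
the package reproduces; note the printed consistency $r^\* = 0.05 \cdot 2 /
(1.05 - 0.05) = 0.1$ µmol m$^{-3}$, the surrounding iron.

## Numerical choices

* **Integrator.** Fixed-step classical RK4 on the state
  $(W^2, L^2, \langle p_r\rangle, \langle p_b\rangle, \mathrm{var}_r,
  \mathrm{var}_b, \mathrm{cov}_{rb})$, with $\gamma$, $\kappa$ re-evaluated
  from $S$ at every stage. $W^2, L^2$ are the natural variables of the
  geometry ODEs; square roots are taken on output. The scheme is far below
  the dynamics' time scales at $dt = 0.01$ d (halving $dt$ moves the LBA by
  well under 0.1%) and keeps every run bit-reproducible. Ensembles use
  $dt = 0.02$ d, which is indistinguishable at the reported precision.
* **Positivity guards.** The continuous moment equations preserve
  positive-semidefiniteness and non-negative means; a discrete step need
  not. After each step variances are clipped at 0, the covariance is
  clamped to $|\mathrm{cov}| \le \sqrt{\mathrm{var}_r\,\mathrm{var}_b}$,
  and the means are clipped at 0. Clamps are counted and reported
  (`n_clamped`). The mean clip matters only deep in the post-bloom decay:
  the closure's additive covariance term can push the near-zero biomass
  mean through zero (in the 42-day SOIREE run it first fires around day
  37, three weeks after the peak, leaving peak and LBA diagnostics
  untouched).
* **Closure validity.** The truncation drops third central moments, so it
  is trustworthy while fluctuations are moderate relative to the means.
  Late in a bloom the biomass coefficient of variation exceeds 1 and the
  second-moment trajectories should be read qualitatively there.
* **Quadratic mortality.** The optional grazing-like variant substitutes
  $m p_b \to m' p_b^2$. The mean loss uses the exact identity
  $\langle p_b^2\rangle = \langle p_b\rangle^2 + \mathrm{var}_b$; the
  second-moment loss terms use the same second-order truncation as the
  growth terms ($4 m' b\,\mathrm{var}_b$, $2 m' b\,\mathrm{cov}$, and
  $2\alpha m' b\,\mathrm{cov}$ returned to the resource variance budget).
  Only the mean term has an exact oracle; the rest is a documented
  modelling choice.
* **Quadrature.** All trajectory integrals (LBA, dilution factor,
  heterogeneity contribution) use the trapezoidal rule on the simulation
  grid, matching the state accuracy at negligible cost.
* **Ensemble grid.** 30×30 log-spaced points over $[0.01, 0.6]$ on both
  axes by default (log spacing resolves the low-dilution structure);
  the examples below use 12×12 to stay light.

## A worked run: the SOIREE bloom

```{r soiree}
traj <- run_simulation(soiree_config())
glance(traj)
```

The fertilized patch blooms to roughly 16× the surrounding biomass around
day 14, then collapses as the iron pulse is consumed and diluted. The
covariance (see `autoplot(traj)`) is positive during growth — entrained
water is poor in both tracers, correlating them — and flips negative near
the peak, when resource depletion decouples them.

```{r soiree-plot, fig.height = 5}
autoplot(traj)
```

## Heterogeneity and dilution trade-offs

```{r ensemble, cache = FALSE}
ens <- run_ensemble(
  sim_config(tau = 30, dt = 0.02),
  gamma0 = log_spaced(0.01, 0.6, 12),
  kappa0 = log_spaced(0.01, 0.6, 12)
)
glance(ens)
```

Well-mixed patches always out-produce their surroundings (LBA > 0) but
gain nothing from dilution; resolving heterogeneity lets strongly diluted
patches reach several times the well-mixed LBA, with an interior optimum
in the LBA-versus-dilution curve:

```{r ensemble-plot, fig.height = 4}
autoplot(ens, type = "dilution")
```

The mechanism is isolated by `heterogeneity_contribution()`, the
time-integral of the second-moment terms of the mean-biomass equation: it
is negative or near zero on the low-dilution branch (variance penalty
wins) and turns positive where the LBA rises (covariance wins). The
two-box toy model (`growth_gap()`) gives the same threshold in closed
form: splitting a patch into sub-regions with deviations $\delta r,
\delta b$ enhances growth exactly when $(k + r)\,\delta b > b\,\delta r$.

## Design decisions

* The ellipse axes are a convention, not a state: $W$ is always the
  contracting axis, and inputs with $W > L$ are swapped on construction.
* "A 10 km wide circular patch" is read as $W_0 = L_0 = 5$ km, so the
  physical width $2W = 10$ km and the size $S = 10$ km hold
  simultaneously; the initial area is $\pi \cdot 25 \approx 78.5$ km².
* The SOIREE preset applies the same size-scaling laws as the ensembles,
  anchored at its $\gamma_0 = 0.12$, $\kappa_0 = 0.1$ — constant forcing
  cannot reproduce the observed width evolution.
* The internal-mixing decay rate is exactly $\kappa/S^2$, with no extra
  $O(1)$ prefactor. A `mixing_factor` knob exists purely as a diagnostic:
  inflating it by $10^4$ collapses the heterogeneous run onto the
  well-mixed one, a limit the test suite enforces.
* The LBA is converted to Mg C constant-by-constant (thickness × area ×
  mol conversion ÷ Fe:C × 12 g mol$^{-1}$), so ports in other languages
  can be compared bit-for-bit.

## What the model does and does not capture

The simulated conditions emulate a mesoscale fertilization experiment: one
pulse, one resource, one consumer, a mean-field constant surrounding, and
strain/diffusion as the only physics. Passing tests therefore demonstrate
the internal consistency of the moment-closed dynamics and its agreement
with independent oracles (pooled-sample entrainment, Monte-Carlo closure
sampling, adaptive-integrator cross-checks, the two-box closed form) — not
fidelity to any particular ocean state. Real patches feel vertical
exchange, light and temperature modulation, grazing with its own dynamics,
multi-nutrient limitation, and neighbours to trade water with; all are
outside this model's scope. Within-run second moments late in a bloom sit
at the edge of the closure's validity and are best read qualitatively.
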