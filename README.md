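# planktonpatch

Plankton blooms live inside moving patches of water that ocean currents
stretch, dilute and mix. Interpreting a bloom — natural or from deliberate
iron fertilization — therefore needs a *Lagrangian* model: follow the water
body, not a fixed point on the map. `planktonpatch` implements such a
model for an idealized iron–phytoplankton ecosystem, and, unusually for
Lagrangian models, tracks the *spatial heterogeneity* inside the patch
(variances and covariance of the tracer fields) rather than assuming the
patch is well mixed. It is aimed at biological oceanographers and
modellers studying bloom dynamics, dilution experiments, and patchiness.

## The model in brief

The patch is an ellipse (half-axes `W`, `L`, size `S = W + L`, area
`A = πWL`) evolving under size-dependent strain `γ(S) = γ₀(S/S₀)^(−2/3)`
and diffusion `κ(S) = κ₀(S/S₀)`:

    dW²/dt = 2κ − 2γW²,   dL²/dt = 2κ + 2γL²,
    dA/dt  = πκ (W² + L²)/(WL)      ← the dilution rate

Inside it, an iron resource `p_r` and a phytoplankton consumer `p_b`
(iron currency) interact through Monod uptake `ν p_r/(p_r + k)`, linear
mortality `m`, and remineralized fraction `α`. Every tracer field is
Reynolds-decomposed, and the model integrates closed equations for the
means, spatial variances and covariance under three processes:
entrainment of surrounding water (means relax at rate `(dA/dt)/A`; mean
contrasts *generate* second moments), internal mixing (second moments
decay at `κ/S²`), and moment-closed biology, in which resource variance
lowers mean growth while positive resource–biomass covariance raises it.
A paired *well-mixed mode* pins all second moments to zero.

The headline diagnostic is the Lagrangian biomass anomaly,

    LBA = (1/τ) ∫₀^τ A(t) (⟨p_b⟩ − ⟨s_b⟩) dt   [Mg C],

the time-averaged biomass the patch holds beyond an equal area of
surrounding water; `m(1−α)·LBA` is the mean export-rate anomaly.

## Worked example: the SOIREE bloom

The built-in preset reproduces the Southern Ocean iron-release experiment:
a 10 km circular patch, 10 m thick, `γ₀ = 0.12`/day, `κ₀ = 0.1` km²/day,
patch iron raised to 1 µmol/m³ over a 0.1 µmol/m³ surrounding, biomass
0.0249 µmol/m³ everywhere.

```r
library(planktonpatch)
traj <- run_simulation(soiree_config())
glance(traj)
#>   mode          peak_day peak_mean_b peak_ratio lba_MgC export_MgC_per_day
#> 1 heterogeneous     13.8       0.401       16.1    213.              10.6
#>   dilution_factor heterogeneity_contribution n_clamped
#> 1            3.67                     -0.221       481
```

The bloom peaks on day 13.8 at 16.1× the surrounding biomass — matching
the observed SOIREE peak near day 14 at ~15× — and the patch carries on
average 213 Mg C more than an equal area of surrounding water, implying a
mean export-rate anomaly of 10.6 Mg C/day. `autoplot(traj)` shows the
panel view: axes, means, variances, and the covariance turning negative
near the peak.

Ensembles contrast the two modes across the strain–diffusion plane:

```r
ens <- run_ensemble(sim_config(tau = 30, dt = 0.02),
                    gamma0 = log_spaced(0.01, 0.6, 12),
                    kappa0 = log_spaced(0.01, 0.6, 12))
glance(ens)
#>   n_members n_failed max_lba_well_mixed max_lba_heterogeneous max_excess_pct
#> 1       288        0               373.                  540.           362.
```

Well-mixed LBA is positive everywhere but decays with dilution;
heterogeneous patches peak at *intermediate* dilution and reach several
times the well-mixed LBA (`autoplot(ens, type = "dilution")`). The
two-box toy model explains the mechanism in closed form:

```sh
inst/exec/planktonpatch toy --r 1 --b 1 --dr 0.5 --db 0.5 --nu 1 --k 2
#> heterogeneous growth: 0.3714285714 umol/m^3/day
#> mean-field growth:    0.3333333333 umol/m^3/day
#> gap (Delta):          0.03809523810 umol/m^3/day
#> verdict: heterogeneity ENHANCES growth
```

A thin CLI (`inst/exec/planktonpatch`) exposes `simulate`, `soiree`,
`ensemble` and `toy` subcommands over flat YAML config files; see
`?read_sim_config` for the keys.

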