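# carrierflux

Simulation and model discrimination for carrier-mediated amino acid
transport into plasma membrane vesicles.

## The problem

System L amino acid transporters (LAT1/LAT2) are described as obligate
exchangers: one amino acid in, one out, 1:1. But radiotracer amino acids
enter vesicles that contain no added substrate (*zero-trans* uptake),
which a strictly obligate antiporter cannot do. Either the carrier's
empty form also translocates (a facilitated-transport component), or the
vesicles are not actually empty (endogenous amino acids drive exchange).
carrierflux is for transport physiologists and modelers who want to put
those hypotheses head to head against uptake time-course data.

## The model

A symmetric carrier binds substrate at either membrane face in rapid
equilibrium (dissociation constant *K* per substrate; labeled and
unlabeled pools of one species share a *K*):

    p_s = (c_s/K_s) / (1 + sum_j c_j/K_j)

The loaded carrier translocates at rate *D*, the empty carrier at *h·D*;
*h* (the relative mobility of the unbound carrier) is the discriminating
parameter: *h* = 0 is an obligate exchanger, *h* > 0 adds uniporter-like
transport. With the carrier distribution θ between the faces at quasi-
steady state, intravesicular concentrations evolve as

    dc_II/dt = V (θ_I p_I − θ_II p_II),      V ≡ D·T / V_in  (µM/min)

The package provides the flux law and stiff time-course integration
(`simulate_uptake`), a full mass-action oracle validating the reduction
(`full_ode_oracle`), the eight-condition cis/trans experimental matrix
with mixing/dilution arithmetic (`build_matrix`, `apply_mixing`,
`add_endogenous`), a synthetic uptake-data generator with replicate noise
(`generate_dataset`), and simultaneous bounded least-squares fitting of
the obligate (*h* = 0, plus a fitted endogenous intravesicular
concentration) and mixed (*h*, *V*, *K*) variants with R²-based model
discrimination (`fit_carrier`, `discriminate`).

## Worked example

Generate a noisy synthetic dataset whose ground truth has a mobile empty
carrier (h = 0.16), then let both model variants compete:

```r
library(carrierflux)

m  <- build_matrix()                       # the 8-condition design
ds <- generate_dataset(serine_params(h = 0.16), m,
                       noise = noise_model(cv = 0.10, floor = 0.3,
                                           n_replicates = 5, seed = 42))
head(ds, 3)
#>   condition_id time_min mean_uptake_pmol_per_mg        sem n
#> 1            1     0.25               0.2434596 0.08157174 5
#> 2            1     0.50               0.3879700 0.13827612 5
#> 3            1     1.00               0.4948248 0.18855294 5

discriminate(ds, m, multistart = 2)
#> Model discrimination: obligate exchange vs mixed transport
#>   mixed:    R^2 = 0.9885 (h = 0.1523, V = 94.82, K = 1185)
#>   obligate: R^2 = 0.9293 (V = 4563, K = 9.943e+04, endo = 222.5)
#>   delta R^2 = 0.05925 -> mixed-preferred
```

The mixed fit recovers the generating mobility (0.152 vs a true 0.16
under 10% noise) and wins on R²; the obligate variant can only chase the
zero-trans uptake by inflating its endogenous-substrate term, and still
fits worse. With the reference serine parameter set (V = 92 µM/min,
K = 1129 µM, h = 0.04) the simulated design shows the expected structure —
cis-inhibited initial rates (condition 1 > 2 > 5), trans-stimulation
(2 < 3 < 4), and an overshoot only under the outward gradients, the
steeper gradient peaking higher:

```r
simulate_conditions(serine_params(), m,
                    times = c(0, 10, 60, 180, 600, 3000))$summary
#>   condition_id initial_rate_uM_min      peak peak_time    final is_overshoot
#> 1            1          0.28128822  7.451250      3000 7.451250        FALSE
#> 4            4          0.34447965 19.788754       180 7.472179         TRUE
#> 5           4b          0.49440416 41.770825       180 7.495125         TRUE
#> 6            5          0.02425052  7.227169      3000 7.227169        FALSE
#> ...
```

`peak`/`final` are intravesicular tracer concentrations in µM
(multiply by 1.3 µl/mg for pmol/mg protein); all h > 0 conditions relax
to one common equilibrium (≈ 7.45 µM), the signature of the facilitated
component. See the vignette (`vignettes/carrier-exchange-model.Rmd`) for
the model derivation, parameter conventions and numerical choices.

A thin command-line front end lives at `inst/cli/carrierflux.R`
(subcommands `simulate`, `synth`, `fit`, `report`, `demo`), e.g.

```sh
Rscript inst/cli/carrierflux.R synth --seed 3 --out out/
Rscript inst/cli/carrierflux.R fit --data out/uptake.csv --variant both --out out/
```

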