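# chokinetics

Kinetic modelling of growth, glucose consumption and monoclonal antibody
(mAb) production in naive and recombinant CHO cell cultures.

CHO cells are the workhorse host for therapeutic protein production, yet
simple, fittable kinetic models of combined growth and antibody formation
for them are scarce. This package implements an unstructured model a
process engineer can estimate from routine daily samples and then use for
batch, fed-batch and temperature-shift what-ifs:

- **Growth** — Monod kinetics in the glucose concentration above a
  threshold `S_t` below which growth stops:
  `mu(S) = mu_max * (S - S_t) / (K_s + (S - S_t))` for `S > S_t`, else 0.
- **Substrate** — growth-linked consumption through a constant yield:
  `r_s = -r_x / Y_x/s`.
- **Product** — Luedeking–Piret mixed kinetics:
  `dP/dt = alpha * r_x + beta * X`, a growth-associated term plus a
  biomass-associated term.

Around that core the package provides the full estimation tool-chain
(log-linear specific growth rates on selected exponential windows,
Lineweaver–Burk fits with a fixed threshold, through-origin yield
regression, direct and integral Luedeking–Piret fits, temperature
recalibration), polynomial-smoothing rate machinery with specific rates
normalized by the integral of viable cells, fixed-step RK4 simulation of
batch and fed-batch bioreactors with feed-event dilution balances and
temperature-shift parameter switching, a registry of fitted parameter sets
for both cell lines at 33 and 37 °C, and a design-matched synthetic-data
generator used throughout the tests.

## Worked example

```r
library(chokinetics)

p <- get_default_parameters("r-CHO", 33)
p
#> Kinetic parameters (threshold-Monod + Luedeking-Piret)
#>   mu_max = 0.04 1/h, K_s = 0.664 g/L, S_t = 0.58 g/L
#>   Y_xs   = 2.59e+06 cells/mg
#>   alpha  = 7.65e-07 ug/cell, beta = 7.68e-08 ug/cell/h

# model growth rate across the experimental glucose levels (1/h)
round(monod_mu(c(1.2, 2.4, 3.6, 4.8), p), 4)
#> [1] 0.0193 0.0293 0.0328 0.0346

# a noisy triplicate batch experiment, and the Monod fit recovered from it
set <- generate_batch_dataset(experiment_design("r-CHO", 33),
                              fixture_parameters("r-CHO", 33),
                              noise_model(seed = 11))
est <- estimate_growth_parameters(set, S_t = p$S_t)
est$monod_fit
#> Fit result:
#>   mu_max = 0.038094
#>   K_s = 0.887371
#>   r^2 = 0.990145 on 4 points; valid = TRUE (r^2 > 0.97 rule applied)
```

The recovered `mu_max` (0.0381 1/h) sits within 5% of the generating value
0.040 under 5%-CV counting noise at daily sampling; `K_s` is the
noise-sensitive parameter of the reciprocal-scale fit, and its fitted value
is reported with the regression's r² so the published validity rule
(r² > 0.97) can gate downstream use.

Production constants round-trip exactly on noiseless profiles:

```r
prof <- lp_fixture_profile()                       # logistic rise, then decline
prof$P <- euler_integrate_product(prof, p)         # forward-Euler product curve
n <- nrow(prof)
fit_lp_direct(data.frame(r_p = diff(prof$P) / diff(prof$time),
                         r_x = prof$r_x[-n], X = prof$X[-n]))
#> Fit result:
#>   alpha = 7.65e-07
#>   beta = 7.68e-08
#>   r^2 = 1.000000 on 2400 points; valid = TRUE
```

## Analysis workflow

The numbered scripts under `analysis/` run the full study workflow on
generated data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_generate_data.R` | batch datasets for both lines, a low-glucose growth screen, a fed-batch run |
| `02_growth_kinetics.R` | threshold bracketing, per-level growth rates, Lineweaver–Burk fits |
| `03_yield_and_rates.R` | yield coefficients and phase-wise specific rates |
| `04_mab_production.R` | direct and integral Luedeking–Piret fits on noisy cultures |
| `05_fed_batch.R` | fed-batch vs batch comparison, temperature recalibration |

Run them in order from the repository root, e.g.
`Rscript analysis/01_generate_data.R`.

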