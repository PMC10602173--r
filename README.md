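# furrowsim

Viscous force-balance modelling of ventral furrow formation (VFF) in the
early *Drosophila* embryo.

During VFF — the first morphogenetic event of gastrulation — actomyosin
networks on the apical surfaces of ventral cells contract, constricting
those surfaces and folding the epithelium into a furrow along the
anterior-posterior axis. `furrowsim` is for quantitative developmental
biophysicists who want to simulate and interrogate this process: it maps a
spatiotemporal myosin tension profile to cell contraction rates, widths,
apical areas and the furrowed tissue cross-section, and provides the
stochastic myosin generators, ensemble statistics, parameter inference and
spectral analysis needed to study how cell-to-cell myosin fluctuations
disrupt — and pulsing rescues — tissue folding.

## The model

Apical constriction is resisted by viscous forces, not elastic ones. With
`w = -dv/dn` the contraction rate of the `n`th cell from the ventral
midline, the force balance

    mu dw/dn + lambda v = dT_myo/dn        =>
    d^2w/dn^2 - w/xi^2 = (1/mu) d^2T_myo/dn^2,    xi = sqrt(mu/lambda)

couples the internal viscosity `mu` (resisting width change) and the
external drag `lambda` per cell (friction against the vitelline membrane)
to the actomyosin tension `T_myo(n, t)`. Beyond the damping length
`xi ~ 2.5` cells, drag dominates and `lambda w ~ -d^2T_myo/dn^2`: tissue
contraction follows the *curvature* of the myosin patterning, which is why
the bell-shaped ventral-lateral envelope furrows the tissue while the flat
anterior-posterior direction does not, and why curvature-free envelopes
(top-hat, as in *Spn27A* RNAi) misfold. Cell-to-cell myosin fluctuations
of the measured ~45% exceed the critical deficit `(2 xi/h)^2 ~ 25-55%` and
disrupt furrowing when persistent (*C-GAP* RNAi, frozen fluctuations);
wild-type pulsing (~75 s correlation time) time-averages them away — a
low-pass filter.

Key functionality: `solve_contraction_rate()` / `closed_form_w()` (solver
plus analytic oracles), `simulate_furrow()` (quasi-static integration with
cell removal), `make_envelope()` / `sample_fluctuations()` /
`make_twist_profile()` / `preset_condition()` (condition generators),
`furrow_shape()` / `classify_failure()` (geometry), `ensemble_run()`,
`fit_xi_wstar()`, `pulsatile_spectrum()`, `solve_velocity_field_2d()`.
See the vignette `vignettes/furrow-mechanics.Rmd` for the full methods
account.

## Worked example

```r
library(furrowsim)
p <- vff_params()
p
#> Viscous force-balance parameters
#>   mu     = 36 pN s/nm   (internal viscosity)
#>   lambda = 5.76 pN s/nm   (external drag per cell)
#>   k      = 0 pN/um     (elastic constant)
#>   T*     = 1500 pN        (peak myosin tension)
#>   xi     = 2.5 cells     (damping length)
#>   w*     = 41.67 nm/s      (characteristic contraction rate)

# wild-type myosin envelope: parabola of half-width 8 cells, amplitude
# ramping linearly (T* is the 300-s value); integrate 500 s
env <- make_envelope("parabolic", h = 16, ramp_duration = 300, cap = FALSE,
                     times = seq(0, 500, 1))
sim <- simulate_furrow(env, p)
summary(sim)
#> Simulation of 81 cells to t = 500 s; 0 cell(s) removed
#>   midline apical area 23.9 um^2 (rest 39.9 um^2)
#>   final area quartiles (um^2):
#>    0%   25%   50%   75%  100%
#> 23.93 39.90 39.91 40.48 60.59

furrow_shape(sim)
#> Furrow shape: depth 31.1 um over 81 cells
```

The midline cells constrict from 39.9 to ~24 µm² while cells just outside
the active zone expand above rest (the 60.6 µm² maximum) — the expansion
zones required by the zero-sum property — and the assembled cross-section
dips 31 µm below the unfurrowed surface. A single cell carrying a frozen
45% myosin deficit instead *expands*, because 45% exceeds the critical
fluctuation:

```r
d <- single_deficit_expansion()
d$net_change_pct
#> [1] 31.2                      # ~30% above its resting area at 400 s

ensemble_run("wildtype", n_runs = 10, seed = 1)
#> Ensemble: 10 "wildtype" runs (master seed 1)
#>   failure rate 0 (reference depth 31.1 um)
#>   depth mean 34.3 um, sd 3.93 um
```

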