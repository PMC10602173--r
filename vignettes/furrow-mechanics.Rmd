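---
title: "Viscous force-balance mechanics of ventral furrow formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscous force-balance mechanics of ventral furrow formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(furrowsim)
```

## The model

During ventral furrow formation (VFF), the first morphogenetic event of
*Drosophila* gastrulation, actomyosin networks on the apical surfaces of
ventral cells contract, constricting those surfaces and folding the
epithelium into a furrow along the anterior-posterior axis. `furrowsim`
implements a quasi-static force balance for this process in which apical
constriction is resisted primarily by *viscous* forces, not elastic ones:

* an internal viscosity $\mu$ (pN s/nm) resists changes of apical cell
  width (network remodelling, anchoring drag);
* an external drag $\lambda v$ (per cell; $\lambda \equiv \tilde\lambda/2$,
  pN s/nm) resists translation of cells relative to the vitelline membrane;
* the driving stress is the actomyosin tension $T_{myo}(n,t)$ (pN), taken
  proportional to the amount of activated apical myosin in cell $n$.

With $w \equiv -\partial v/\partial n$ the contraction rate, the force
balance on cell $n$ along the ventral-lateral axis is

$$\mu\,\partial_n w + \lambda v - k\,\partial_n L = \partial_n T_{myo},$$

and since the measured elastic constant $k = 7$ pN/µm yields elastic
stresses $k\,\Delta L \sim 50$ pN, over 20-fold below the ~1.5 nN myosin
tensions (`elastic_myosin_ratio()`), the elastic term is dropped by
default. Differentiating gives the working equation

$$\partial_n^2 w - \frac{w}{\xi^2} = \frac{1}{\mu}\,\partial_n^2 T_{myo},
\qquad \xi = \sqrt{\mu/\lambda},$$

whose two reduced parameters are the damping length $\xi$ (cells) and the
characteristic contraction rate $w^* = T^*/\mu$ (nm/s), with $T^*$ the peak
tension. Beyond $\xi$, drag dominates and $\lambda w \approx
-\partial_n^2 T_{myo}$: **contraction follows the curvature of the myosin
profile**. Envelopes without interior curvature (top-hat, triangular)
contract cells only within $\sim\xi$ of their singular points;
`closed_form_w()` gives the exact solutions for the three hypothetical
shapes via the Green's function $G(n,m) = -(\xi/2)e^{-|n-m|/\xi}$. For the
parabolic profile the kernel applied to the distributional second
derivative yields interior coefficient $4w^*(\xi/h)^2$; the package's
closed form is verified in the tests against direct quadrature of that
kernel.

## Parameters and units

All internal computation uses pN, nm, s; widths and areas are reported in
µm and µm². Defaults (see `vff_params()`):

| quantity | default | meaning |
|---|---|---|
| $\mu$ | 36 pN s/nm | internal viscosity, $T^*/w^*$ with $w^* = 42$ nm/s |
| $\xi$ | 2.5 cells | damping length (area-profile fit) |
| $\lambda$ | $\mu/\xi^2 = 5.76$ pN s/nm | external drag per cell |
| $T^*$ | 1500 pN | peak myosin tension |
| $k$ | 0 (optional) | elastic constant, pN/µm |
| $b$ | 5.7 µm | anterior-posterior cell length |
| $L_{rest}$, $H$, $V$ | 7 µm, 39 µm, 1556.1 µm³ | rest width, height, volume |

$\lambda$ is derived from the identity $\lambda = T^*/(\xi^2 w^*)$; the
independently quoted value ~6 pN s/nm is consistent within its (large)
uncertainty. $V$ is fixed at $L_{rest}\,b\,H$ (within the quoted "~1500
µm³") so the rest state is exactly flat.

## Discretisation and numerical choices

Cells live on an integer grid $n \in [-N, N]$ with the midline **cell** at
$n = 0$ (default $N = 40$, ~80 cells as in the embryo at its widest
point). An odd, zero-centred grid represents symmetric profiles exactly;
mirror symmetry of solutions is tested to machine precision.

`solve_contraction_rate()` offers two discretisations. The default
*discrete cell form* solves for edge velocities $u_j$ between adjacent
cells from $T_{tot}(n{+}1) - T_{tot}(n) = \bar\lambda_j u_j$ with
$T_{tot} = T - \mu w$ and $w(n) = u_{left} - u_{right}$ (outer edges
clamped); eliminating $u$ reproduces, row for row, the *continuum form*
$\mu D^2 w - \lambda w = D^2 T$ with Dirichlet ends — so the two agree for
uniform drag, while only the discrete form is meaningful under spatially
varying drag (the Spn27A condition, where $\lambda$ is halved over the
detached cells $-6\ldots6$). Both are tridiagonal and solved by the Thomas
algorithm. A tension profile whose *gradient* at the domain ends exceeds
$10^{-3}$ of its maximum gradient triggers a domain-too-small error;
constant offsets are harmless because only differences enter.

Time integration (`simulate_furrow()`) is quasi-static: the overdamped
balance has no inertia, so $w$ responds instantaneously to each tension
slice and $L \leftarrow L - w\,dt$ with $dt = 1$ s by default (a warning
is issued above 1 s). When $k > 0$ the restoring term enters as an
effective tension $T + k(L - L_{rest})$ recomputed explicitly each step,
stable at $dt = 1$ s for the parameter ranges used. A cell reaching width
0.5 µm is removed — a strict zero is never reached in finite steps — and
its neighbours become mechanically adjacent; labels are never re-indexed
and dead cells are reported with width 0. With this scheme the zero-sum
identity $\sum_n w(n) = 0$ holds to round-off (telescoping edge
velocities): contraction anywhere is exactly balanced by expansion
elsewhere, which is why 2–3-cell-wide expansion zones flank the furrow.

## Synthetic myosin patterning

The generators emulate the study conditions, not microscope data:

* **Envelope** (`make_envelope()`): the wild-type stand-in is a parabola
  of full support 16 cells — i.e. half-width $h = 8$ cells, the symbol in
  the scaling arguments — matching the measured 10–15-cell-wide bell.
  (The scaling estimate "envelope contraction rate $\sim 2T/h^2\lambda$"
  is precisely the curvature of $T^*(1-(n/h)^2)$ at half-width $h$; with
  an 8-cell *support* the curvature would be four times larger and a 45%
  deficit could never overcome it, contradicting the single-deficit
  result below.) The amplitude ramps linearly with $T^*$ defined as the
  300-s value of an ongoing ramp (`cap = FALSE` in the presets), the
  convention under which $w^*$ was fitted; the `cap = TRUE` default of the
  plain constructor holds the plateau after the ramp instead. Top-hat
  (13-cell plateau, 2-cell shoulders; the Spn27A RNAi shape), triangular
  and Gaussian shapes are also provided.
* **Fluctuations** (`sample_fluctuations()`): per cell an independent
  stationary Ornstein–Uhlenbeck process with sd $\sigma = 0.45$ (the
  measured ~45% cell-to-cell variation) and correlation time $\tau = 75$ s
  (midpoint of the observed 60–90 s pulsing); the exact discretisation
  keeps the marginal law stationary at any step. `frozen` mode (C-GAP
  RNAi) draws once per cell and holds; `slow` uses $10\tau$. The law is
  Gaussian with the multiplier clamped at $1+\epsilon \ge 0$ — the
  magnitude and persistence are measured quantities, the distributional
  *shape* is not, and the choice matters (below).
* **Pulse trains** (`make_twist_profile()`): the twist RNAi condition —
  35-s pulses on a zero baseline for cells $-6\ldots7$, gaps uniform on
  [30, 330] s, amplitudes uniform on $[0, 2T^*]$, raised-cosine by default
  (smooth; rectangular available).

These emulate amplitude, width, ramp and fluctuation statistics; they do
not reproduce spatial correlations of real myosin, the exact experimental
envelope shape (published only graphically), or mechanochemical feedback
of contraction on myosin. Passing tests therefore validate the mechanics
given the stated statistics, not the upstream biology.

## Furrow geometry and failure classification

`cell_shape_from_area()` turns an apical area into a trapezoidal prism:
volume conservation at fixed height fixes the basal width
$L_{basal} = 2V/(bH) - L_{apical}$ and the wedge angle
$2\,\mathrm{atan}[(L_{basal}-L_{apical})/(2H)]$, the thin-wedge equivalent
of apical and basal surfaces lying on concentric arcs with areas in the
ratio of their radii. Chaining cells outward from the midline with
cumulative half-wedge rotations gives the cross-section
(`assemble_tissue_cross_section()`). The depth baseline is the undeformed
apical line through the far lateral cells, obtained by fitting a line
through the outermost vertices of both wings — necessary because
asymmetric (stochastic) profiles rigidly tilt a construction anchored at
the midline facet. Apical areas above $2V/(bH)\cdot b \approx 80$ µm²
cannot conserve volume (basal width would be negative); this is recorded
as a geometry error, and a backtracking apical polyline is flagged as
self-intersecting, not repaired.

`classify_failure()` marks a furrow failed when its depth falls below 0.5
of the fluctuation-free wild-type reference, when more than one local
minimum exceeds 0.2 of the reference depth (a fragmented surface), on any
geometry error, or on self-intersection. The two fractional thresholds are
artifact decisions calibrated once against the published ensemble rates
and then frozen; in practice the calibration space is flat under the
default study conditions — every non-degenerate run sits well above any
sensible depth threshold and strict secondary minima are rare — so the
failure statistics are governed almost entirely by the geometry-error
clause, i.e. by cells expanding past the volume-conservation bound.

### Sensitivity of failure rates to the fluctuation law

A cell with a persistent relative deficit $\epsilon$ expands at rate
$\sim\epsilon T^{env}/\mu$ against the envelope's curvature-driven
contraction $\sim 2T^{env}/h^2\lambda$; deficits beyond
$\epsilon_{crit} \sim (2\xi/h)^2 \approx 39\%$ (at $\xi = 2.5$, $h = 8$)
win. Under the clamped Gaussian law, $P(\epsilon < -0.8) \approx 3.8\%$
per cell, and such extreme deficits drive cells past the ~80 µm² geometry
bound by 500 s; with ~10 effective envelope cells this yields a frozen
(C-GAP) failure rate near 35% and a pulsatile (wild-type) rate near 2%
(time-averaged deficits occasionally persist). A lognormal law of the same
sd puts only $2\times10^{-4}$ of cells there and both rates collapse
toward zero. The published pair (0% wild-type, ~15% C-GAP) lies between
the two laws; since the distributional shape is not reported we keep the
Gaussian choice and report what it gives rather than tuning the tail. The
qualitative ordering — frozen $\gg$ pulsatile, both increasing in
$\sigma$ — is robust and is what the property tests assert.

## Why pulsing rescues furrowing: the low-pass filter

Because areas depend on the *time integral* of myosin, the effective
fluctuation a cell carries is its running time-average of
$\epsilon(t)$. For the OU process,

$$\mathrm{Var}\Big[\tfrac1t\textstyle\int_0^t\epsilon\,ds\Big]
 = \frac{2\sigma^2\tau}{t}\Big[1-\frac{\tau}{t}(1-e^{-t/\tau})\Big]
 \xrightarrow{t \gg \tau} \frac{2\sigma^2\tau}{t},$$

(`ou_timeavg_var()`): pulsing averages itself away, while frozen
fluctuations keep variance $\sigma^2$ at all window lengths. Spectrally,
time-averaging over $t$ cuts the fluctuation power above $1/t$;
`pulsatile_spectrum()` computes the one-sided periodogram of the
signal-minus-envelope (Lorentzian for OU input, corner $1/2\pi\tau$,
recovered by `fit_spectrum_corner()` via a log-binned fit that stops the
dense high-frequency tail from dominating), the cumulative power, and the
running-average variance.

## The single-deficit computation

`single_deficit_expansion()` places a frozen $\epsilon = -0.45$ on cell
$n = 1$ of the ramping wild-type envelope. Because $0.45 >
\epsilon_{crit} \approx 0.39$, the deficit does not merely stop the cell
contracting: by 400 s its apical area is ~31% *above* rest while its
neighbours constrict, producing a local furrow defect. The headline
number is the plain percent change of the cell's own area; the
deficit-attributable excess over the fluctuation-free reference (~56% of
the rest area at 400 s) is also returned. Both follow mechanically from
the superposition of the envelope response and the point-deficit response
$\delta w \approx 0.8\,\epsilon\,T^{env}/\mu$ (the 0.8 is the discrete
lattice Green's function at zero separation for $\xi = 2.5$).

## The twist condition and "zero mean contraction"

Pulse trains on a zero baseline produce cells that both contract and
expand with no collective contraction. Quantifying "no net contraction"
needs care in this model: the zero-sum identity makes the tissue-wide
mean area change *exactly* zero, while any finite observation window
excludes an exponentially small expansion tail that is perfectly
correlated with the window's pulse activity — so a per-seed windowed mean
is a small, systematic negative number at every window size, and a naive
t-statistic against seed scatter rejects zero no matter how wide the
window. The package therefore states the claim in three parts, which the
tests assert: the tissue-wide mean vanishes to numerical precision; every
realisation contains both contracting and expanding cells; and the
active-zone mean contraction is under a quarter of (measured, about 9% of)
the wild-type effect.

## Two-dimensional check

`solve_velocity_field_2d()` generalises the balance to
$\nabla\cdot[(\sigma_{myo} + \mu\nabla\cdot\mathbf v)\mathbf I] =
\lambda\mathbf v$ on a periodic lattice, solved mode-by-mode with the FFT.
Staggered forward/backward difference symbols make the $k_y = 0$ modes
coincide exactly with the 1D cell-level operator, the construction is
longitudinal (discrete curl zero), and the dissipation identity
$\lambda\sum|\mathbf v|^2 + \mu\sum w^2 = \sum\sigma w$ holds exactly.
Periodic boundaries are controlled by padding (default 128×128 for a
~16-cell envelope extruded 30 cells with raised-cosine tapers,
`extrude_stress()`). With curvature along one axis only, the directional
contraction along the flat axis is <1% of the curved axis at the centre
(`anisotropy_report()`): the anisotropic curvature of the myosin
patterning orients the furrow. Only instantaneous fields are computed in
2D; time integration stays 1D.

## Parameter inference

`fit_xi_wstar()` mirrors the two-stage experimental fit: $\xi$ from the
*shape* of the apical area profile (amplitude-free: for a fixed-shape
ramping envelope $\Delta A(n) \propto -w(n)$), via a grid search over
$\xi \in [0.5, 8]$ in steps of 0.05 plus golden-section refinement of the
normalised-profile least squares; then $w^*$ as a linear scale factor on
the contraction-rate profile. Noise-free self-consistency recovers the
generating $(\xi, w^*)$ to well under 2%; a flat profile raises a
no-identifiability error. The covariance proxy is a finite-difference
curvature estimate of the joint objective, reported as such.

## Problem sizes used by the tests

The test-suite and acceptance runs use the study-scale conditions: an
81-cell grid, 500 s at $dt = 1$ s, 50-realisation ensembles for the
wild-type and C-GAP statistics and 20 for twist; solver-oracle comparisons
refine the continuum equation to 0.05-cell spacing; Monte-Carlo checks of
the OU statistics use ~10 seeds of 81 cells × 2000 s. The full suite runs
in well under a minute on one core.

## Known limitations

* The fluctuation-law tail dominates ensemble failure rates (above);
  only magnitude and correlation time are constrained by measurement.
* The experimental envelope is available only graphically; the parabolic
  stand-in has the right width, amplitude and curvature scale but not the
  exact shape, and $T^*$-at-300-s is a convention, not a measurement of
  the late-time amplitude.
* The geometry model fixes cell height; strongly expanded cells hit the
  volume-conservation bound where a real cell would deform out of the
  modelled plane.
* No mechanochemical feedback, no adhesion remodelling, no 3D shell
  mechanics, no invagination beyond furrow formation.
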