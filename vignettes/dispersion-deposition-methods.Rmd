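---
title: "Methods: plume dispersion, deposition and exposure screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plume dispersion, deposition and exposure screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nanoplume` estimates steady-state airborne concentrations and ground
deposition of a depositing aerosol — engineered nanomaterials in particular —
released continuously from a single point source, and turns them into
screening-level exposure metrics: the maximum ground-level concentration and
its distance, the half-deposited distance $x_{50}$ separating the local from
the regional scale, two-compartment near-field/far-field concentrations, and
long-term soil accumulation with PEC/PNEC risk ratios. This vignette records
the model equations, the assumptions behind them, the tunable parameters and
the numerical choices, so that users know exactly what a result does and does
not mean.

## The plume hierarchy

All variants assume stationarity (constant wind $U$ along $x$, constant
emission $E$ in g/s at height $H$), flat terrain, and dispersion parameters
$\sigma_y(x)$, $\sigma_z(x)$ indexed by Pasquill stability class. Four nested
solutions are available through `plume_model(model = ...)`:

1. **classic** — the Gaussian plume with total ground reflection,

   $$C(x,y,z) = \frac{E}{2\pi U \sigma_y \sigma_z}
   e^{-y^2/2\sigma_y^2}\left[e^{-(z-H)^2/2\sigma_z^2} +
   e^{-(z+H)^2/2\sigma_z^2}\right],$$

   valid for a non-depositing gas. It conserves the emitted mass flux exactly.

2. **ermak** — the analytical depositing plume. Settling at $v_{set}$ tilts
   the plume and partial ground absorption at deposition velocity $v_{dep}$
   depletes it through a term proportional to
   $\sqrt{2\pi}\,(v_0\sigma_z/K_z)\,e^{\xi^2}\mathrm{erfc}(\xi)$, with
   $K_z = U\sigma_z^2/2x$, $v_0 = v_{dep} - v_{set}/2$ and
   $\xi = (z+H)/(\sqrt2\,\sigma_z) + v_0\sigma_z/(\sqrt2\,K_z)$. With
   $v_{set}=v_{dep}=0$ it reduces *exactly* to the classic solution (a unit
   test asserts machine-level agreement).

3. **rao** — the depositing plume inside a boundary layer of height
   $H_{pbl}$: image sources at effective heights $H_1 = H + 2jH_{pbl}$,
   summed over $j = -j_{max},\dots,j_{max}$. The implementation uses
   $|H_1|$ in every occurrence of the source height so that ground and lid
   reflections remain physically consistent under deposition; with
   $v_{set}=v_{dep}=0$ the series is the familiar reflecting
   (Yamartino-type) plume, and the tests check it against an independently
   coded image sum.

4. **rao_mass_balanced** (default) — the reflected depositing solution with
   an iterative mass-balance correction described below.

All concentrations are exactly linear in $E$, which the batch tools exploit
(an activity-rate maximum is the yearly-rate maximum scaled by the rate
ratio, and the tests verify the linearity).

## Dispersion parametrizations

Two coefficient sets are shipped as annotated CSV files under
`inst/extdata/`, selectable per run:

* **Klug**: $\sigma = R\,x^{r}$ with $x$ in metres;
* **Davidson**: $\sigma = a\,x^{\,b + c\ln x}$ with $x$ in kilometres
  (modified Pasquill–Gifford fits).

Public interfaces always take metres; the kilometre conversion is internal to
the Davidson scheme. Vertical dispersion is capped at 5000 m (configurable via
`dispersion_scheme(sigma_z_cap =)`), the usual fully-mixed ceiling, without
which the unstable-class fits grow without bound.

Two quirks of the Davidson fits required a documented decision. The exponent
$b + c\ln x$ makes $\sigma(x)$ turn over at $\ln x_{km} = -b/2c$: for $c<0$
(class f $\sigma_z$, turning at about 461 km) the raw fit would *shrink* with
distance; for $c>0$ (class a $\sigma_z$, turning near 16 m) it would *grow
towards the source*. Both lie outside the fitted range of the underlying
curves, so the curve is plateaued at its turning point, keeping $\sigma$
nondecreasing in $x$ everywhere on the supported domain (10 m–500 km). The
smallest supported evaluation distance is the grid minimum of 10 m; $x \le 0$
is rejected rather than extrapolated.

## Particle velocities

Settling follows Stokes–Cunningham,
$v_{set} = g\rho C_c d_p^2 / 18\eta$, with the Allen–Raabe slip correction
$C_c = 1 + Kn\,(1.257 + 0.4\,e^{-1.1/Kn})$, the mean free path scaled from
66.4 nm (293.15 K, 101325 Pa) with the Sutherland temperature correction, and
Sutherland's law for $\eta(T)$.

The dry deposition velocity is pluggable (`fixed_velocities()`,
`rannik_model()`, `lookup_velocities()`). The resistance mode implements

$$v_{dep} = v_{set} + \frac{1}{r_a + r_c},\qquad
r_a = \frac{\ln(z_{ref}/z_0)}{\kappa u_*},\qquad
r_c = \frac{1}{u_*\,\big(Sc^{-2/3} + (St/(1+St))^2 + \tfrac12 (d_p/A)^2\big)}$$

— Brownian diffusion, inertial impaction on needle-scale obstacles
(`impactor`, default 1 mm; $St = v_{set}u_*/g\,A_{imp}$) and interception on
fine canopy micro-elements (`collector`, default 5 µm). The defaults
($u_* = 0.45$ m/s, $z_0 = 1$ m, $z_{ref} = 10$ m) describe a rough forest
canopy: $u_*\approx\kappa U/\ln(z_{ref}/z_0)$ gives 0.43 m/s at the case
studies' 2.5 m/s wind. They were chosen once so that the $v_{dep}(d_p)$ curve
over 10–500 nm has the canonical shape for such surfaces — a minimum near
100 nm (0.066 cm/s), about 0.9 cm/s at 10 nm (the well-known factor ~10
between 10 nm and 100 nm particles) and 0.23 cm/s at 500 nm — and roughly
0.09 cm/s for the ~280 nm case-study agglomerates. Keeping impaction and
interception on separate obstacle scales matters: a single micrometre-scale
collector would give dense submicron particles several-fold too much
impaction and visibly over-deposit the case-study plumes. The exact
velocities the original facility studies experienced are unknown; this
submodel is the dominant source of uncertainty in the deposition-derived
outputs, which is why the package also accepts fixed velocities and
user-supplied lookup tables (two-column `dp_nm`, `vdep_m_s`, interpolated
linearly in $\log d_p$).

## Deposition bookkeeping and the mass-balance correction

The ground flux magnitude is $F(x,y) = v_{dep}\,C(x,y,z_{ref})$ with
$z_{ref} = 2$ m (configurable). The crosswind integral is analytic
($\sqrt{2\pi}\sigma_y$ times the centerline value); the downwind integral
accumulates over the geometric grid (default 10 m to 500 km at 50 points per
decade) using the *logarithmic mean* of the segment endpoint fluxes, which is
exact for exponential variation. A plain trapezoid systematically overshoots
the convex exponential decay of a depleting plume and, in nearly exhausted
plumes, pushes the deposited fraction above one — the log-mean rule is what
keeps the budget consistent to the end of the domain. Cumulative deposition
gives $f_{dep}(x) = R_{dep}(x)/E$; the suspended fraction $f_{susp}(x)$
integrates the horizontal flux $U\,C$ over $z \in [0, H_{pbl}]$ for the
reflected solutions (image sources fold all mass into the layer; the upper
limit is a documented interpretation of the formal $\infty$) and to
$H + 12\sigma_z$ for the unbounded ones.

The analytical reflected solution does not conserve mass — near the source it
overpredicts, a known bias of order 20%. The default model therefore rescales
the concentration field at each grid distance by iterating

$$C_{m+1}(x,\cdot) = \frac{C_m(x,\cdot)}{f_{dep}(x) + f_{susp}(x)}$$

until $|1 - f_{dep} - f_{susp}| < 1\%$ (iterated in practice to $10^{-6}$;
the fixed point is exact balance). The correction marches outward in $x$ so
the cumulative integral always uses already-balanced upstream fluxes; where
the plain iteration stalls (nearly exhausted plumes, $f_{susp}\to 0$) a
bracketed root solve finds the same fixed point. Iteration cap 100; failure
to converge raises a warning naming the worst distance, and the fitted object
records `worst_residual`.

The vertical integral for $f_{susp}$ uses composite Gauss–Legendre
quadrature with subinterval breakpoints at the plume peak ($z = H \pm
6\sigma_z$) and at both reflecting boundaries, 16 nodes per subinterval.
Near the source the integrand is a Gaussian spike of width
$\sigma_z \ll H_{pbl}$ that a global adaptive rule can miss silently; the
peak-resolving subdivision is deterministic, accurate to ~$10^{-8}$
relative for these integrands (validated against `stats::integrate` on split
domains in the tests), and fast enough for the 1782-combination sweeps.

$e^{\xi^2}\mathrm{erfc}(\xi)$ is evaluated as the scaled complementary error
function: the factors overflow/underflow separately long before the product
leaves $[0,1]$. An in-package `erfcx` uses `pnorm` up to $\xi = 25$ and the
asymptotic series beyond; tests pin it to `pracma::erfcx` in the moderate
range and to the classical two-sided bound elsewhere. Tiny negative
concentrations from cancellation in the image sum are clamped to zero with a
warning.

## x50, compartments, soil accumulation

$x_{50}$ solves $f_{dep}(x_{50}) = 0.5$ by interpolation linear in $\log x$
between the bracketing grid points (the profile is near power-law on the log
grid); when less than half the mass deposits within the domain the sentinel
`Inf` is returned and reports print "beyond domain". The two-compartment
layer treats the disc of radius $x_{50}$ (near field) and the annulus out to
$x_{tot}$ (far field, default 500 km) as uniformly mixed with steady state
set by emission and deposition alone: $C_N = E/2\pi x_{50}^2 v_{dep}$,
$C_F = E/2\pi(x_{tot}^2 - x_{50}^2)v_{dep}$. These are deliberately coarse —
about an order of magnitude below the dispersion profile at $x_{50}$ —
because uniform mixing dilutes the near-ground maximum; a test asserts the
bounded discrepancy rather than equality.

Yearly averages weight per-class profiles with a stability climatology
(default: a/b/c 4% each, d 37%, e/f 25.5% each, a Northern-Hemisphere
day/night average). Soil accumulation assumes every deposited gram stays in a
uniform topsoil layer ($H_{soil} = 0.05$ m, $\rho_{soil} = 1500$ kg/m³, 365-day
years, no decay or transformation — a worst case):
$PEC_{soil} = F\,a\,(365\cdot 24\cdot 3600)/H_{soil}\rho_{soil}$, evaluated on the plume
centerline (fixed prevailing wind direction, the screening worst case; no
wind-rose averaging). PNEC values (nano-TiO2 1000 µg/kg, CNT 176 µg/kg) live
in an editable CSV registry.

## Scenarios, sweeps, case studies

`scenario()`/`read_scenario()` accept the field's mixed units (µg/s, mg/min,
cm/s, nm, km, °C) with explicit suffixes and convert to SI at the parse
boundary; serialization is canonical-SI and round-trip idempotent. Two
measured nano-TiO2 releases ship as presets (`case_study()`): a paint factory
(stack 7.8 m, 260 nm, 940 kg/m³, yearly 29 µg/s, activity 0.14 mg/s) and a
spray-coating facility (exhaust 3 m, 280 nm, 2100 kg/m³, yearly 3.5 µg/s,
activity 0.33 mg/s), both at 2.5 m/s wind, 288.15 K, 1 km boundary layer,
Davidson scheme, all six classes.

`sweep_grid()` expands the two documented full-factorial designs (1296
nanomaterial and 486 generic-pollutant combinations; the three generic
settling velocities are paired index-wise with the three deposition
velocities — the factorial arithmetic requires pairing, and it also keeps
$v_{set} \le v_{dep}$). `run_sweep()` tabulates max concentration, its
distance, $x_{50}$ and the domain-total deposited fraction per combination;
results are order-independent and deterministic (no randomness anywhere in
the model; the fixture generator's seed exists only for optional noise toys).

## Numerical sizes and limitations

* Default grid 10 m–500 km, 50 points per decade (236 points); reported
  arg-max distances are grid points, so they carry one-grid-step (4.7%)
  granularity. The full 1782-combination sweep takes a few minutes on one
  core at this resolution.
* $j_{max} = 10$ reproduces the converged reflection series at ground level
  to better than 1% for kilometre-scale boundary layers. For the extreme
  combination of a 200 m layer with $\sigma_z$ at the 5 km cap the series is
  formally under-truncated; the mass-balance correction renormalises the
  column, so fractions stay consistent, but the uncorrected variants should
  be given a larger `j_max` in that regime.
* The Gaussian framework itself is a fair-weather, flat-terrain, single-source
  approximation: no aerosol dynamics (coagulation, condensation), no wet
  deposition or resuspension, no building wakes, poor fidelity at very low
  wind speeds. Stability-class dispersion curves differ between literature
  parametrizations by factors that matter: the shipped Klug and Davidson sets
  reproduce stable-class literature deposition distances well but give
  neutral-class $x_{50}$ values ~3x shorter than studies based on other
  (larger) neutral sigma curves. Deposition-derived outputs inherit the
  canopy submodel's parameter uncertainty; concentrations at the maximum are
  insensitive to it.

## A worked example

```{r, eval = FALSE}
library(nanoplume)
m <- plume_model(point_source(E = 29e-6, H = 7.8),
                 atmosphere(U = 2.5, T_K = 288.15, Hpbl = 1000,
                            stability = "d", scheme = "davidson"),
                 particle = particle(dp = 260, rho = 940))
summary(m)
report <- run_scenario(case_study("koivisto"))
print(report)
```

The tests rebuild every number quoted above (velocity curve values, limit
equivalences, budget closure, case-study reproductions) from code; nothing in
this document is asserted that the suite does not compute.
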