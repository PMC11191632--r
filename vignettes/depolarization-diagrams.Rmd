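---
title: "Circular-polarization depolarization diagrams: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular-polarization depolarization diagrams: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miepol)
```

## The physical model

`miepol` models what happens to right-circularly polarized (RCP) light
launched into a turbid slab of spherical scatterers, and asks one
question at many scales: *how much circular polarization survives?*
The answer, as a function of particle diameter $a$ and wavelength
$\lambda$, is the depolarization diagram, and its structure is what makes
wavelength-selective particle monitoring possible: cell nuclei, blood
corpuscles and protein-coated beads are all, to first order, spheres of
known size range.

### Single scattering

A homogeneous sphere acts on the Stokes vector
$S = (S_0, S_1, S_2, S_3)^T$ through the block-diagonal Mueller matrix

$$
\begin{pmatrix}
M_{11} & M_{12} & 0 & 0\\
M_{12} & M_{11} & 0 & 0\\
0 & 0 & M_{33} & M_{34}\\
0 & 0 & -M_{34} & M_{33}
\end{pmatrix},
$$

whose four independent elements come from the two complex Mie amplitudes
$M_1(\theta), M_2(\theta)$:
$M_{11} = \tfrac12(|M_2|^2{+}|M_1|^2)$,
$M_{12} = \tfrac12(|M_2|^2{-}|M_1|^2)$,
$M_{33} = \mathrm{Re}(M_2 M_1^*)$,
$M_{34} = \mathrm{Im}(M_2 M_1^*)$.
These satisfy $M_{11}^2 = M_{12}^2 + M_{33}^2 + M_{34}^2$ identically — a
property the test suite asserts everywhere to $10^{-9}$ — and force
$s_3(0^\circ) = +1$ (forward scattering preserves helicity) and
$s_3(180^\circ) = -1$ (backscatter is a helicity-flipping mirror).

The amplitudes are the standard partial-wave sums over the Mie
coefficients $a_n, b_n$ and angle functions $\pi_n, \tau_n$.  Everything
is controlled by two dimensionless numbers: the relative refractive index
$m = n_\mathrm{particle}/n_\mathrm{medium}$ and the size parameter
$x = \pi a\, n_\mathrm{medium}/\lambda$ (with $a$ the *diameter*).  The
diagram axis used throughout is the generalized size parameter
$X \equiv a/\lambda = x/(\pi n_\mathrm{medium})$, which absorbs the
medium index and makes iso-depolarization features exact rays
$a = X\lambda$ in the $(a, \lambda)$ plane.

The expected circular polarization emitted by one scattering event of
RCP light is the phase-function-weighted solid-angle average

$$
\langle S_3\rangle(m, X)
  = \frac{\int_0^\pi M_{33}(\theta)\sin\theta\,d\theta}
         {\int_0^\pi M_{11}(\theta)\sin\theta\,d\theta},
$$

because for circular input the scattering probability into $d\Omega$ is
$\propto M_{11}\sin\theta$ (the $M_{12}$ azimuthal term integrates to
zero) and the emitted degree of circular polarization at angle $\theta$
is $M_{33}/M_{11}$.  Alternative weightings (no $\sin\theta$; plain
angular averages of $M_{33}/M_{11}$) were implemented and rejected during
development: they displace the troughs to size parameters inconsistent
with the trough inventory the curve is known to have.

### Multiple scattering

The slab transport is a meridian-plane polarized Monte Carlo:
exponential free paths with $\mu_t = \mu_a + \mu_s$, polarized Mie
scattering at each event, implicit-capture absorption
(weight $\times\, \mu_s/\mu_t$ per event) and Russian roulette
(threshold $10^{-4}$, survival probability $0.1$).  Per event the pair
$(\theta, \varphi)$ is drawn from the exact bivariate density

$$
P(\theta, \varphi) \propto
 \left[M_{11} S_0 + M_{12}(S_1\cos 2\varphi + S_2\sin 2\varphi)\right]
 \sin\theta .
$$

Two implementation choices deserve explanation:

* **Sampling.**  The reference sampler (`rejection_sample_angles()`)
  rejects against a flat envelope at the global maximum of the density —
  transparent, but its acceptance rate collapses like the inverse of the
  forward peak (worse than $10^{-2}$ for $x \gtrsim 40$).  The transport
  kernel therefore factorizes the *same* density exactly: $\theta$ from
  its marginal $M_{11}\sin\theta$ via a tabulated inverse CDF, then
  $\varphi$ from its conditional by rejection with envelope
  $1 + |M_{12}/M_{11}|\sqrt{S_1^2+S_2^2} \le 2$ (acceptance $\ge 1/2$).
  The two samplers are checked against each other and against quadrature
  CDFs distributionally in the test suite.

* **Frames.**  Instead of re-rotating the Stokes vector into the global
  meridian plane after every event, each packet carries an orthonormal
  triad (direction, parallel axis, perpendicular axis).  Reference-plane
  rotations become plain vector arithmetic, the polar singularities of
  meridian bookkeeping disappear, and the density above is valid in
  whatever frame the Stokes vector is currently expressed.  The scored
  quantity $S_3/S_0$ is invariant under reference-plane rotations, so the
  detector-frame rotation applied to exit records (into the meridian
  plane through the surface normal) matters only for the reported
  $S_1, S_2$.

Transport is fully three-dimensional.  The slab is 12 mm wide and 6 mm
deep; the beam enters at the origin $1^\circ$ off the inward normal; the
reflection detector is the strip $x \in [1, 3]$ mm on the illuminated
face and the transmission detector $x \in [-1, 1]$ mm on the far face,
both limited to $|y| \le 1$ mm out of plane (mirroring the 2 mm window
widths; the extent is a config field, not a constant).  Boundaries are
refractive-index matched — no Fresnel reflection or refraction — recorded
as the config flag `fresnel: "off"`.  Photons crossing the lateral faces
are terminated as escaped.  All exit angles $\varphi \in [0^\circ,
90^\circ)$ are accepted and averaged with intensity weights; 10-degree
$\varphi$ bins are reported alongside for angle-resolved use.

### Baseline conditions

The fixed optical baseline is $\mu_a = 0.10$ mm$^{-1}$,
$\mu_s = 6.86$ mm$^{-1}$, $n_\mathrm{particle} = 1.59$ (polystyrene-like
organic matter), $n_\mathrm{medium} = 1.33$ (water), hence
$m \approx 1.195$.  The coefficients are deliberately independent of
wavelength and particle size: they fix the *number* of scattering
events, so that every feature of the diagrams is attributable to the
single-event polarization physics carried by $(m, x)$.  Real tissues
violate this (hemoglobin and water absorption, size-dependent $\mu_s$);
consequences are discussed under *Limitations*.

## Trough detection

The curve $\langle S_3\rangle(X)$ at $m = 1.195$ carries structure on two
scales: broad interference dips about one $X$-unit wide (near
$X \approx 5, 9, 12$, the dominant depolarization features) and very
narrow morphology-dependent resonance ripple (widths down to
$\lesssim 0.1$ in $X$).  A minimum is reported as *pronounced* when its
depth below the local upper envelope of the curve — a moving maximum over
$\pm 2.5$ in $X$ — exceeds a threshold, after a light moving-average
smoothing.  Envelope depth, not classic topographic prominence, is the
right measure here: the troughs at $X \approx 9$ and $12$ sit inside a
single wider depression, so the $12$-trough has almost no topographic
prominence yet is plainly a distinct feature of the curve.

Defaults and their reasons:

* `prominence = 0.015`: the dominant troughs have envelope depths
  $\approx 0.019{-}0.05$, saddle ripple $\lesssim 0.01$; the threshold
  sits in the gap.  No number is inherited from data external to the
  curve itself.
* `smooth_window = 0.3` in $X$, with a floor of **two grid steps**:
  structure narrower than two samples is aliased, not resolved, so a
  coarse Monte Carlo sweep (step 0.5) is automatically smoothed at its
  own Nyquist scale.  Without this, a narrow resonance dip near
  $X = 7.55$ aliases onto the $X = 7.5$ grid point of the MC sweep and
  masquerades as a major trough.
* `min_separation = 2.0`: distinct troughs of the curve are never closer
  than about two $X$-units; minima closer than that to a deeper one are
  ripple on the same feature and are pruned (deepest-first).
* The weak outer troughs near $X = 17, 19, 22, 26$ are shallow
  (envelope depth $0.008{-}0.02$) and narrow; they are resolved with
  `smooth_window = 0`, `prominence = 0.008`, `min_separation = 0`, the
  "sensitive" operating point used when an exhaustive trough inventory
  is wanted.

With the defaults the pronounced set on $X \in [1, 30]$ (step 0.05) is
$\{4.9,\ 8.7,\ 12.3\}$; the sensitive set additionally contains minima
within $0.5$ of each of $17, 19, 22, 26$.

## Diagrams, lines and recommendations

`build_diagram()` evaluates mean $S_3$ on a (diameter, wavelength)
lattice.  Single-scattering grids exploit that the value depends on
$(a, \lambda)$ only through $X$ (cells with equal $X$ are computed once;
asserted to $10^{-9}$ in the tests).  MC grids simulate every cell with
per-cell seed `seed + cell index`, so any sub-grid is reproducible in
isolation.  The default lattice steps (25 nm in $\lambda$, 0.25 um in
$a$) resolve the $X = 9$ vs $X = 12$ separation; full-resolution runs
scale through the config.

`extract_lines()` exploits the ray geometry directly: every cell maps to
$X = a/\lambda$, cells are pooled and median-binned on the finest row
resolution, and the 1-D trough detector runs on the pooled profile.
For single-scattering grids the pooling is exact (all rows sample one
curve); for MC grids it averages independent noise.  Reported line
endpoints are the exact ray values $a = X\lambda$ at the grid's
wavelength limits.

`recommend_wavelengths()` turns a diagram into measurement advice: a
wavelength (or band, for a size interval) qualifies for population A
when A sits on an active iso-$X$ line there while population B's
$X$-range stays at least `clearance = 1` away from every active line.
Active lines are $\{9, 12, 22\}$ in reflection and $\{9, 12\}$ in
transmission, where the $X{=}22$ line is narrow and weak; the broad
shallow $X \approx 5$ region (transmission) and the weak 19/26 side
bands (reflection) are advisory — never recommended, and overlapping
them only flags the recommendation (`advisory_overlap`) instead of
rejecting it, which is what licenses the classic blood-monitoring bands.
Band edges follow the diagonal-rectangle construction
$\lambda = 1000\,a_{\min}/X$ to $1000\,a_{\max}/X$ (nm, 10-nm rounding).
Wavelengths above 1100 nm carry a water-absorption warning; absorption
spectra themselves are out of scope.  For a single size crossing the
$X = 9$ line at $a = 11$ um the analytic ray gives 1220 nm; published
readings of diagram troughs quote values up to $\sim$20 nm away, which
is within the width of the trough itself — when an MC diagram is
supplied the empirical trough wavelength is reported alongside.

## Numerical choices

* Mie coefficients: logarithmic-derivative downward recurrence for
  $D_n(mx)$ seeded 15 orders above the Wiscombe truncation
  $n_\mathrm{max} = \lceil x + 4.05x^{1/3} + 2\rceil$; $\psi_n, \chi_n$
  upward.  Validated term-by-term against a non-recursive evaluation
  built on half-integer Bessel functions, and against the Rayleigh
  closed form.  $m = 1$ returns a zero series with a warning rather than
  0/0.
* Riccati-Bessel: $j_n$ by Miller's downward recurrence (normalized by
  $j_0$), $y_n$ upward; $\xi_n = x(j_n + i y_n)$, the convention under
  which $\xi_n - \psi_n = i x y_n$ and $|a_n| \le 1$ for real $m$.
* Angular quadrature: fringe-resolving grid with step
  $\min(0.1^\circ, 180^\circ/20x)$ including both endpoints exactly;
  composite Simpson; refinement by step-halving until successive
  estimates agree to $10^{-6}$ (a warning carries the grid diagnostic if
  the budget is exhausted).
* Kernel numerics: Mueller elements linearly interpolated in the phase
  table; direction triad re-orthonormalized every event; degree of
  polarization clamped to 1 against interpolation noise; runaway paths
  cut at $10^6$ events.  Weight bookkeeping closes exactly:
  $N = \text{exits} + \text{absorbed} + \text{roulette kills} -
  \text{roulette gains}$ (roulette necessarily *raises* a survivor's
  weight by $1/p$, so monotone weight decay holds only between roulette
  events).
* Determinism: one R-level RNG stream per run, seeded from the config;
  sweep and diagram cells use `seed + index`.  Identical configs give
  bit-identical outputs.

## Problem sizes used in the shipped checks

The package's own verification runs at desk scale, chosen so the full
suite completes in a few minutes: the single-scattering curve on
$X \in [1, 30]$ at step 0.05; the MC trough sweep on $X \in [6, 14]$ at
step 0.5 with $2 \times 10^4$ photons per point; the
transmission-vs-reflection comparison on $X \in [10, 30]$ at step 1 with
$4 \times 10^4$ photons; diagrams and refractive maps as small lattices.
At these budgets the MC standard error per point is about $0.015{-}0.02$
in $S_3$, an order of magnitude below the trough depths being located.

## What the simulations do and do not show

The model is monodisperse, spherical, index-matched at the boundaries,
and its optical coefficients are wavelength-independent.  Passing tests
therefore demonstrate the internal consistency of the Mie/Mueller
algebra, the transport sampling, and the size-parameter structure of
depolarization — not quantitative agreement with any real tissue.  Known
gaps to reality:

* **Polydispersity** smooths the narrow resonance ripple and shallow
  outer troughs; the dominant $X = 9, 12, 22$ features survive size
  dispersion, the fine structure does not.
* **Spectral absorption** (hemoglobin, water) reweights wavelengths;
  here it surfaces only as the $>1100$ nm warning flag.
* **Birefringence** of connective tissue adds a depolarization channel
  absent from the model.
* **Fresnel boundaries** would re-inject internally reflected light;
  the `fresnel` flag records that this is off.
* At small $X$ ($\lesssim 9$) transmitted light traverses $\sim$40 mean
  free paths of nearly isotropic scattering and depolarizes *more* than
  reflected light in this model; the often-quoted transmission advantage
  for circular polarization is a property of the forward-scattering
  regime ($X \gtrsim 10$), and the tests state it there.
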