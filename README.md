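# miepol

Mie polarimetry and polarized Monte Carlo depolarization diagrams for
size-selective monitoring of biological particles with circularly
polarized light (CPL).

## The problem

When circularly polarized light scatters in a turbid medium — tissue,
blood, a bead suspension — how much of its circular polarization
survives depends sharply on the ratio of particle diameter to
wavelength, the *generalized size parameter* `X = a/λ`
(`= x/(π·n_medium)` with `x = π·a·n_medium/λ` the Mie size parameter).
At specific values of `X` a single scattering event depolarizes CPL
unusually strongly, and multiple scattering amplifies those dips into
deep troughs.  Plotted over the (diameter, wavelength) plane the troughs
are exact rays `a = X·λ` — *iso-X depolarization lines* — and they are
the working surface for choosing measurement wavelengths that respond to
one particle population but not another: normal (~6 µm) versus enlarged
cancerous (~11 µm) cell nuclei in reflection geometry, or red (6–8 µm)
versus white (12–15 µm) blood cells in transmission.

`miepol` implements the full chain:

* **Mie core** — Riccati–Bessel functions, Mie coefficients `a_n, b_n`,
  angle functions `π_n, τ_n`, amplitudes `M1, M2`, and the
  block-diagonal sphere Mueller elements `M11, M12, M33, M34`
  (satisfying `M11² = M12² + M33² + M34²` exactly — tested to 1e-9).
* **Single scattering** — angular intensity / `s3(θ)` profiles, the
  expected emitted circular polarization
  `⟨S3⟩ = ∫M33 sinθ dθ / ∫M11 sinθ dθ`, and pronounced-trough detection.
* **Polarized Monte Carlo** — meridian-plane photon transport through a
  12 × 6 mm slab (`μa = 0.10 /mm`, `μs = 6.86 /mm`, indices 1.59/1.33),
  RCP pencil beam 1° off normal, reflection (x ∈ [1,3] mm) and
  transmission (x ∈ [−1,1] mm) strip detectors, implicit capture +
  Russian roulette, passage-probability maps.  The kernel is compiled
  (Rcpp) and simulates ~10⁵ photons/s on one core.
* **Diagrams** — `⟨S3⟩(X)` sweeps, MC resultant-S3 sweeps,
  (diameter × wavelength) depolarization diagrams for either geometry,
  the (X × m) refractive-index map, and iso-X line extraction.
* **Applications** — wavelength recommendations for discriminating two
  particle sizes or size intervals, with water-absorption warnings.

## Worked example

```r
library(miepol)

optical_context(1000, 9)        # 9 µm particle at 1000 nm
#> <optical_context> lambda = 1000 nm, a = 9 um, n_p = 1.59, n_m = 1.33
#>   m = 1.19549   x = 37.6049   X = a/lambda = 9

# single-scattering depolarization troughs over X = a/lambda
cv <- sweep_expected_s3(1.195, seq(1, 30, 0.05))
find_depolarization_minima(cv)
#>      X    s3 prominence
#> 1  4.9 0.971     0.0189
#> 2  8.7 0.954     0.0236
#> 3 12.3 0.960     0.0195
```

The three pronounced troughs sit near `X ≈ 5, 9, 12`: a 9 µm particle
at 1000 nm (X = 9) emits, per scattering event, markedly less circular
polarization (`⟨S3⟩ ≈ 0.95`) than its neighbours.  Multiple scattering
compounds this into a deep dip:

```r
res <- simulate_slab(default_config(photons = 20000L, seed = 42L,
                                    medium = list(diameter_um = 9)))
res
#> <mc_result> 20000 photons, seed 42
#>   reflection   mean S3 = 0.1617 (se 0.017), n = 904, <events> = 35.38
#>   transmission mean S3 = 0.09116 (se 0.031), n = 261, <events> = 78.51
```

After ~35 scattering events the detected reflection-side circular
polarization has fallen to 0.16 (off-trough values at neighbouring X are
~0.45).  Wavelength selection for the cancer-screening size pair reads
straight off the line geometry:

```r
recommend_wavelengths(6, 11, "reflection", c(600, 1300))
#>   selective_for diameter_um X_line lambda_nm band_lo_nm band_hi_nm contrast
#> 1             A           6      9       670        670        670   0.0135
#> 2             B          11     12       920        920        920   0.0203
#> 3             B          11      9      1220       1220       1220   0.0398
#>   water_warning advisory_overlap
#> 1         FALSE            FALSE
#> 2         FALSE            FALSE
#> 3          TRUE            FALSE
```

670 nm depolarizes only the 6 µm population (it sits on the X = 9 line),
920 nm only the 11 µm population (X = 12 line); the 1220 nm crossing is
reported but flagged — water absorbs strongly there.  `contrast` is the
analytic single-scattering `|⟨S3⟩_A − ⟨S3⟩_B|` at that wavelength.

A shell entry point wraps the same functions
(`inst/cli/miepol.R`): subcommands `mie`, `single`, `xsweep`, `mc`,
`diagram`, `optimize`, `fixtures`, YAML configs, CSV/JSON outputs.

See `vignettes/depolarization-diagrams.Rmd` for the model, the sampling
scheme, the trough-detection design and known limitations.

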