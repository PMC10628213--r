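---
title: "Slab-model XRR analysis of protein-membrane association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slab-model XRR analysis of protein-membrane association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrrfit)
```

## The measurement and the model

Specular X-ray reflectivity probes the laterally averaged electron-density
profile normal to a planar interface. The incidence angle is converted to
momentum transfer $q_z = 4\pi\sin(\alpha_i)/\lambda$; at 22 keV
($\lambda = 0.56$ Å) the beam penetrates a bulk aqueous phase, so a
solid-supported membrane can be measured at the solid/liquid interface.
Below the critical edge $q_c = \sqrt{16\pi\,\Delta\mathrm{sld}}$ the
interface reflects totally; above it, reflectivity falls roughly as
$q^{-4}$, modulated by Kiessig fringes whose period encodes layer
thicknesses and whose contrast encodes density steps and interfacial
widths.

`xrrfit` parameterizes the interface as homogeneous slabs between two
semi-infinite media. Each slab has thickness $d$ (Å), electron density
$\rho$ (e⁻·Å⁻³) and an rms roughness $\sigma$ (Å) attached to the
interface on its beam side; the backing interface carries its own
roughness. Electron density converts to X-ray scattering length density
as $\mathrm{sld} = \rho\,r_e$ with $r_e = 2.818\times10^{-5}$ Å.

Two exact formalisms are implemented: the Abeles transfer matrix (compiled
kernel, the production path) and the Parratt recursion (pure R, the
cross-check). They are algebraically equivalent, and the test suite holds
them to within $10^{-8}$ relative on random stacks. Roughness uses the
Névot–Croce damping $\exp(-2 k_i k_{i+1} \sigma^2)$ of each interfacial
Fresnel coefficient.

Assumptions worth stating explicitly:

* **No absorption.** At 22 keV the imaginary part of the optical index for
  Si, SiO₂, water and organics is roughly three orders of magnitude below
  the real part, so the optical profile is real. The kernel exploits this
  (purely real or purely imaginary $k_z$ per layer). A consequence is that
  $R = 1$ exactly below the critical edge.
* **Corrected data.** The forward model assumes footprint-corrected,
  incident-beam-normalized, background-subtracted curves; a constant
  residual background (free in [0, 1e-8] by default) and an intensity
  scale absorb what the corrections leave behind.
* **No resolution smearing by default.** A constant-$dq/q$ Gaussian
  smearing hook exists (`reflectivitySmeared`) but is off, since beamline
  resolution functions for this class of measurement are narrow and rarely
  reported; leaving it on without knowledge of the true width would bias
  fitted roughnesses.

## Fitting

The cost defaults to the unweighted mean squared residual of
$\log_{10} R$: reflectivity spans about six decades, and without reliable
per-point counting statistics a log-space residual weights all decades
evenly. When error bars exist, `cost = "chi2_weighted"` uses them.

Minimization is differential evolution (rand/1/bin), a genetic-type
stochastic global search: population 15 per free parameter, mutation
weight $F = 0.7$, crossover $CR = 0.9$, up to 1000 generations, stopping
early when the relative spread of population costs falls below $10^{-8}$.
The starting stack is injected as one population member, so the achieved
cost never exceeds the cost of the initial guess, and the best member is
refined by a bounded quasi-Newton polish (as stochastic reflectometry
fitters conventionally do). All randomness flows from one integer seed;
identical seed and configuration give bit-identical results.

Constraints follow refinement practice for supported membranes on
silicon: the densities of silicon (0.692), silicon oxide (0.660) and
buffer (0.335 e⁻·Å⁻³) are fixed, and the oxide thickness is bounded to
12–25 Å. `presetFitParameters()` applies these conventions to any
template whose oxide slab is named `sio2`; everything else is free within
±25% of the template by default.

The intensity scale is a free parameter in [0.95, 1.05] by default rather
than pinned at 1. Beam normalization is rarely accurate beyond a few
percent, and pinning the scale is actively harmful under multiplicative
noise: the expectation of $\log_{10}(1+\epsilon)$ is negative, so noisy
curves sit uniformly $\sim\sigma^2/(2\ln 10)$ low in log space, and with
no scale to absorb that offset it leaks into the nearly degenerate
thickness–roughness–density valley of thin-slab stacks, biasing fitted
thicknesses by several percent. With the scale free, the same fits
recover thicknesses to ~1–2% median error at 2% noise.

Per-parameter uncertainties come from a residual bootstrap
(`parameterUncertainty`): residuals of the best fit are resampled in the
cost's own space, synthetic curves are rebuilt around the best-fit model,
and the free parameters are refit by bounded local optimization from the
global optimum. The spread of the refits is the reported 1σ. This is a
choice, not the only defensible one; a full evolutionary refit per
resample adds cost without changing the spread materially, and covariance-
based errors are unreliable for bounded, correlated parameters.

Model order (how many slabs the data support) is decided by a parsimony
rule, `compareModels`: the larger model is accepted only when it improves
the cost by more than 10% (relative, configurable). This mirrors the
qualitative practice of adding a slab only when it visibly improves the
fit; ties go to fewer slabs.

## The synthetic-data generator

No beamline curves are distributed with the package, so every stage is
exercised on synthetic data. `makePreset()` carries the slab stacks of the
study's membrane scenarios — DOPC and DOPC/DOPS monolayers in air, the
corresponding Hsp70-incubated bilayers in buffer (the DOPC/DOPS case with
its additional 22.6 Å / 0.372 e⁻·Å⁻³ protein layer), and a degenerate
single-slab disrupted bilayer. Published parameters are used exactly;
three quantities the tables do not print were fixed once as conventional
values and are not tuned: SiO₂ thickness 18 Å (midpoint of the stated
12–25 Å window), substrate interface roughnesses 3 Å (typical polished
silicon), and, for the disrupted scenario, a single diffuse slab of
40 Å / 0.30 e⁻·Å⁻³ / σ = 10 Å.

`simulateCurve()` evaluates the exact model on a default grid of 200
log-spaced points in $q \in [0.01, 0.7]$ Å⁻¹ and perturbs it with either
multiplicative Gaussian noise of fixed relative width (default 2%) or
Poisson counting noise at a given incident count rate, both seeded and
unbiased. What the generator does *not* emulate: footprint and geometry
effects at low $q$, resolution smearing, long-term drift, parasitic
background, or any lateral inhomogeneity (islands, coexisting phases) —
real curves carry all of these. Passing the recovery tests therefore
demonstrates the estimator chain is correct and well-conditioned under the
stated noise model, not that every beamline dataset of this kind is
fittable to the same accuracy.

## Numerical choices and degenerate inputs

* Units are fixed internally: Å, e⁻·Å⁻³, Å⁻¹; degrees appear only at the
  I/O boundary (`qzFromAngle`, the `angle_R` file dialect).
* $\sigma = 0$ interfaces are exact steps both in the optical model and in
  the reconstructed profile; the $\sigma \to 0$ profile limit reproduces
  the discrete stack exactly.
* A roughness exceeding twice the thickness of the thinner adjacent slab
  smears an interface over more than the layer itself; such stacks are
  legal but constructed with a warning.
* Zero-thickness slabs are legal in the kernels. Between sharp interfaces
  they are exact no-ops; under Névot–Croce damping a zero-thickness slab
  of distinct density is *not* a no-op (it splits one damped interface
  into two with different damping products), which is physically
  consistent and covered by the tests.
* Model reflectivities are floored at $10^{-30}$ inside the log-cost to
  keep the objective finite; non-positive data points are masked with a
  warning.
* The recovery study (`runRecover`) simulates at 2% relative noise and
  refits with bounds centered on the generating values (±25%), starting
  from the bounds midpoint, 20 replicates by default, 400 generations per
  fit — problem sizes chosen to characterize estimator accuracy at
  realistic noise within a practical runtime.

## Known limitations

* The log-cost surface at 2% multiplicative noise is nearly degenerate
  along correlated directions (thickness–roughness–density trade-offs
  between adjacent thin slabs): basins several percent apart in individual
  thicknesses can differ by less than the noise floor in cost. Recovery
  from a far-away random start can therefore settle in a neighbouring
  basin even when the search converges. Meaningful absolute-accuracy
  claims require either informative starting stacks (as in practice, where
  monolayer fits seed bilayer fits), error bars that sharpen the
  likelihood, or multi-contrast data.
* Absorption, magnetic/polarized scattering, off-specular scattering and
  free-form (spline) profile inversion are out of scope.
* The bundled residue volume table (Zamyatnin 1972 consensus volumes) and
  the curated HSPA1A sequence reproduce the published protein volume and
  density to well within the 2% the construct ambiguity warrants; a
  different volume table shifts the volume by a comparable margin.
* The ±-style uncertainties of the original tables were produced by an
  unstated method; the bootstrap here is not asserted to be equivalent.
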