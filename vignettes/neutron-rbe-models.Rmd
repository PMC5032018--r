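---
title: "Modelling the energy dependence of neutron RBE: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the energy dependence of neutron RBE: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutronRBE)
```

## The problem

Neutrons deposit dose through a mixed field of secondary charged particles
whose composition changes with neutron energy and with depth in tissue:
below roughly 0.1–1 MeV the dose is dominated by electrons set in motion by
the 2.22 MeV photons from radiative neutron capture on hydrogen (with a
small proton component from nitrogen capture, which releases 626 keV shared
by the proton and the carbon recoil); in the elastic regime recoil protons
take over, since hydrogen can absorb the full neutron energy in a single
collision (`maxEnergyTransfer()`); and above the reaction thresholds
(~1 MeV for nitrogen, ~5 MeV for oxygen, ~10 MeV for carbon) heavy recoils
and alpha particles add a slow, densely ionizing component. The relative
biological effectiveness (RBE) of neutrons versus a photon reference
therefore depends on energy, peaking near 1 MeV where slow recoil protons
dominate, with a secondary region of enhanced effectiveness near 20 MeV
driven by heavy recoils.

This package models that energy dependence two ways and lets both run
end-to-end on synthetic inputs with known ground truth.

## The two RBE models

**Phenomenological (y\*).** The stochastic energy deposition in a 1 μm
site (the scale of chromosome domains) is described by the lineal-energy
frequency density f(y) and its dose counterpart d(y) = y f(y)/ȳ_F. The
dose-mean lineal energy ȳ_D = ∫y² f dy / ∫y f dy condenses d(y) into one
number per field or per species. Because effectiveness for survival-type
endpoints drops again at very high lineal energy (overkill: single tracks
deposit more energy than a cell needs to be inactivated), the dose-mean is
saturation-corrected,

y\* = y₀² ∫ (1 − e^{−y²/y₀²}) f(y) dy / ∫ y f(y) dy,

with y₀ between 100 and 200 keV/μm (the weight of components above y₀ is
suppressed; y\* → ȳ_D as y₀ → ∞ and is monotone in y₀). The RBE model is
the ratio of neutron y\* to the photon-reference y\* at the same y₀.

**Mechanistic (DSB clusters).** Complex DNA damage is scored from break
positions: DNA fragments shorter than 30 bp, and DSB clusters, i.e. at
least two double-strand breaks within less than 25 bp (both thresholds
strict, matching the endpoint definitions). Damage yields per Gy per cell
as a function of LET follow a power law Y = a·L^n for light ions; for heavy
ions the cluster yield turns over before the maximal LET, captured by one
extra clustering parameter, Y = A·L^N·e^{−B·L}, which nests the power law
at B = 0 and has a single interior maximum at L = N/B. The coupling
operator identifies each species' dose-mean lineal energy with the LET at
which its damage curve is read (dose averaging makes the two estimators
compatible), weights the species yield by its dose fraction, and sums:

Y_n(E) = Σ_s w_s(E) · Y_s(ȳ_D,s(E)).

Deuterons are evaluated on the proton curve (equal damage versus LET), and
electrons on the proton curve at their low, almost constant lineal energy,
clamped to the curve's low-LET end when below its fitted span (clamping is
flagged in the output). The RBE model is Y_n over the photon-reference
cluster yield; linearity in dose is assumed for the cluster endpoint, since
two independent tracks essentially never cooperate within 25 bp.

Dose-fraction uncertainties propagate through the coupling as independent
(σ² = Σ (Y_s σ_{w_s})²); lineal-energy uncertainties are not propagated by
default but can be, through a numerical curve slope
(`couple(..., propagateYD = TRUE)`).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `y0` | 150 (100–200 supported) | keV/μm | saturation parameter; larger values re-weight high-LET components upward, raising RBE at and above the 20 MeV region |
| `siteDiameter` | 1 | μm | metadata on spectra; no chord resampling is performed |
| cluster distance | 25 | bp | strict threshold defining DSB clusters |
| fragment length | 30 | bp | strict threshold defining short fragments |
| `linkage` | `"chain"` | — | transitive chaining of consecutive breaks; `"pairwise"` bounds the cluster span instead (the endpoint definition does not specify which; both are implemented behind one argument) |
| `energyGrid` | 49 log nodes, 10⁻⁵–10³ | MeV | the neutron-energy grid radiation-protection factors are quoted on |
| `captureCrossover` | 0.7 / 1.5 / 3.0 | MeV | outer / intermediate / inner energy where electron dose dominance yields to protons |
| `thresholds` | N 1, O 5, C 10, α 2 | MeV | reaction-channel openings |
| `moderationStrength` | 0.10 / 0.45 / 0.75 | — | asymptotic moderated (capture-like) dose share per region |
| `seed` | 34033 | — | seed for the sampled generators (damage noise, break patterns) |

## What the synthetic generator emulates — and what it does not

`generateCompositionTable()` is an emulator of the mechanisms that shape
the secondary field, not a transport code. It reproduces, by construction:
constant composition toward thermal energies (no-threshold capture on H and
N with a constant cross-section ratio — the table is frozen below
10⁻⁴ MeV); the electron→proton crossover, placed at lower energy for the
surface region where neutrons arrive unmoderated; uniform elastic recoil
spectra on [0, E_max] from isotropic centre-of-mass scattering; smooth
threshold-gated α and heavy-recoil channels (zero at threshold, saturating
over ~half a decade); a high-energy electron component standing in for
electromagnetic cascades; and depth-dependent moderation as a mixture with
the capture-limit composition. Per-species lineal energies come from an
embedded stopping-power model: a coarse proton anchor table (approximate
ICRU-style water/tissue values) interpolated with a monotone log-log
spline, scaled to heavier ions by Barkas effective charge at equal
velocity; ranges follow by quadrature of 1/S. A recoil born at energy T is
assigned the energy it deposits over one mean chord (2/3 μm) of the site —
stoppers deposit everything, fast crossers deposit at their local stopping
power — and the species' dose-mean lineal energy is the second moment of
that quantity over the recoil spectrum. A pure analytic Bethe expression
was rejected for the low-energy region (it turns unphysical below
~0.3 MeV/u), so the anchor table *is* the primary representation; its
accuracy (a few per cent) only affects where lineal energies sit, not any
dosimetry.

The generator's free constants (crossovers, channel amplitudes and ramp
scales, the electron cascade term, moderation strengths) were calibrated
once, against the qualitative regime structure described above — proton
dominance at 0.5 MeV in the surface region, an effectiveness maximum at
1 MeV shifting deeper-region maxima to higher energies, a secondary
maximum near 20 MeV that is strongly muted for the cluster endpoint — and
then frozen; they are not fit to any quantitative dataset. Consequently,
passing tests demonstrate that the *pipeline* reproduces the mechanistic
structure, not that the generator predicts real transport output: absolute
dose fractions, absolute damage yields and absolute RBE levels carry no
quantitative meaning here. The same applies to the photon reference
(`syntheticReferenceField()`): a log-normal low-LET spectrum with dose-mean
5 keV/μm and a cluster yield read off the proton curve at that lineal
energy, a synthetic stand-in for the 220 kV X-ray machine spectrum it is
labelled after. RBE *shapes* and *peak positions* are the meaningful
outputs.

The default damage-curve truth parameters place the heavy-ion cluster
maxima at N/B ≈ 500–650 keV/μm, inside each curve's fitted LET span, with
light-ion power laws and per-Gy-per-cell magnitudes of order 10 at
proton-recoil lineal energies; fragment curves are pure power laws for all
species, which is what makes the 20 MeV fragment peak prominent while the
cluster peak is damped.

## Numerical choices

* Continuous spectra live on log grids and integrate by trapezoid;
  discrete line spectra are summed exactly, so worked examples carry no
  quadrature error. Constructors renormalize densities whose integral is
  within 1% of unity and reject larger deviations (a guard against unit
  mistakes); `1 − e^{−x}` uses `expm1` so the large-y₀ limit is exact to
  rounding.
* Mixing resamples component dose distributions onto a common log grid
  (default 1024 points), renormalizing each component after resampling so
  the mixture identity ȳ_D,mix = Σ w_s ȳ_D,s holds to quadrature
  precision.
* Both damage-curve forms are linear in log-yield space, so the "weighted
  nonlinear least squares in log space" is an exact weighted linear fit
  (`lm`), with inverse-variance weights from relative yield errors and the
  covariance mapped back from the log-amplitude scale by the delta method.
  On noiseless data the truth is recovered to numerical precision.
* Composition interpolation is linear in log₁₀E for dose fractions
  (renormalized afterwards) and log-log for lineal energies; a channel
  absent at the lower bracketing node contributes exactly zero there, so
  thresholds are never extrapolated across.
* Break scoring chains consecutive breaks (transitive linkage) by default;
  cluster counts, multiplicities, isolated breaks and short fragments are
  all derived from per-chromosome sorted positions, and an O(n²)
  all-pairs oracle in the test suite checks exact equivalence on hundreds
  of random patterns.
* The ICRP Publication 103 w_R function is transcribed as published; its
  three branches agree at 1 and 50 MeV only to about 0.01 (the
  regulation's own rounding), which is the tolerance the tests assert. The
  U.S. NRC quality-factor table is interpolated log-linearly in energy and
  clamped outside its range. Both are exposed "for qualitative comparison"
  only, as weighting factors are defined for radiation protection, not
  risk assessment.

## Problem sizes

The default pipeline runs the full 49-node energy grid with 256-point
species spectra and 1024-point mixing grids in about one second; the test
suite (including 500-pattern oracle comparisons and 200-replicate
parameter-recovery simulations) completes in under a minute on one CPU.
These sizes were chosen as the smallest that keep quadrature error well
below the asserted tolerances.

## Known limitations

* No transport, no track-structure physics, no radiation chemistry: every
  physical input is an emulator with documented shape assumptions.
* The ȳ_D → LET identification is exact (no smearing), as in the coupling
  scheme it implements; the electron clamp value is configurable only
  through the proton curve's fitted span.
* Depth dependence is a two-component moderation mixture; only the
  direction of the depth shift (deeper regions peak at higher nominal
  energies) is asserted, not its magnitude.
* Species with atomic number above 8 are excluded; compositions carry
  their dose share only as a logged residual (≤ 5%).
* The Bragg-edge ambiguity (two particle energies sharing one LET) is
  deliberately not modelled; the analytic damage curves absorb it, which
  is accurate for the cluster endpoint and a known approximation for
  fragments.

```{r example}
tab <- generateCompositionTable(fieldGeneratorConfig())
ys <- ystarCurve(tab, y0 = 150)
attr(ys, "maxima")          # low-energy effectiveness peak (MeV)

dmg <- neutronDamageCurve(tab, defaultDamageCurves("dsb_clusters"),
                          "dsb_clusters")
attr(dmg, "maxima")         # the two damage maxima (MeV)

ref <- syntheticReferenceField()
rbe <- rbeCurveCluster(dmg, ref)
head(rbeValues(rbe))
```
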