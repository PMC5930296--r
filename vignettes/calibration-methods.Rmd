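---
title: "Gamma-camera calibration factors for quantitative SPECT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-camera calibration factors for quantitative SPECT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative SPECT turns a reconstructed count map into an activity map by
multiplying with a camera calibration factor

$$\mathrm{CF} = \frac{C}{A\,t} \quad [\mathrm{cps/MBq}],$$

where $C$ is the number of counts the camera records from a source of
activity $A$ in time $t$. The CF is a property of the camera, collimator,
radionuclide and energy-window protocol — not of the imaged object — yet
the phantom geometry used to *measure* it changes the answer. This package
implements, at desk scale, a simulation study of that effect for the
therapy radionuclides I-131, Lu-177 and Re-188, comparing four standard
calibration geometries:

* **A** — planar scan of a 1-mL point-like source in air (`CF_PWSC`:
  photopeak counts corrected for scatter with the triple-energy-window
  method);
* **B** — SPECT of a 100-mL hot sphere centered in a cold 20-cm water
  cylinder;
* **C** — the same sphere in a warm background at a 6:1
  activity-concentration ratio;
* **D** — the cylinder uniformly filled.

Tomographic CFs use the total counts of an OSEM reconstruction with
attenuation correction (AC) and TEW scatter in the update denominator,
divided by $A \, n_p t_p$ (or, for simulations, by $n_p N_\mathrm{tot}$
decays). The central finding the package reproduces: **B overestimates the
planar CF by more than 10%**, while C and D agree with it to a few percent.
The mechanism is a spatial bias of the TEW estimator — it underestimates
true photopeak scatter over the source and overestimates it over the
background — amplified by attenuation correction, which weights the central
(source) region most.

## The Monte Carlo acquisition model

The synthetic-data generator stands in for a full general-purpose Monte
Carlo detector simulation. It transports photons analytically through the phantom
(exponential free paths from packaged cross-section tables, photoelectric
absorption, Klein–Nishina Compton scattering with exact kinematics;
coherent scattering off) and scores detection by **forced detection**: at
every emission or scatter vertex the expected detection weight toward each
of the two heads is accumulated —

directional density (isotropic, or the KN angular pdf at the vertex) ×
phantom exit attenuation × collimator geometric sensitivity
$g = K^2 (d/l_e)^2 \bigl(d/(d+t)\bigr)^2$ × crystal response — and the
analog history then continues. This is what makes desk-scale budgets
(about $10^{-3}$ of the reference decay numbers, minutes on one CPU)
feasible where brute-force sampling through a $\sim 10^{-4}$ collimator
acceptance would not be. An analog mode (binary acceptance within the
collimator cone, normalized to the same $g$) is retained purely as an
unbiasedness check of the weighted estimator.

The camera response comprises:

* **Geometric collimation and septal penetration.** Penetration is an
  effective model: transmission $\exp(-\mu_\mathrm{Pb}(E)\,l\,t_s/(d+t_s))$
  through the mean septal path, applied over a solid angle
  `kappa_penetration` times the geometric acceptance. It matters above
  ~300 keV (the 364-keV line of I-131; 478/633 keV of Re-188).
* **Crystal.** A 0.95-cm NaI(Tl) slab. Interactions split into
  photoelectric (full deposit) and Compton; a Compton-scattered photon is
  reabsorbed with probability $1-\exp(-\mu_\mathrm{NaI}(E')\,t)$ (full
  deposit, i.e. a photopeak event) or escapes (partial deposit). The
  second-order term is essential: without it the 364-keV photofraction
  would equal the photoelectric fraction (~0.32) and the camera's count
  budget would fall far below the reference study's (>15,000 photopeak
  counts at the stated decay numbers).
* **Backscatter compartment.** Photons crossing the crystal uninteracted
  may Compton-backscatter in an effective water-equivalent slab
  (`backscatter_slab_cm = 5`) and redeposit, with a return factor
  `kappa_backscatter = 1` (slab directly behind the crystal, near-$2\pi$
  return). This reproduces the high-energy backscatter continuum that
  dominates point-source spectra for Re-188 (478 keV backscatters to
  166 keV — inside the 140–171 keV photopeak window) and I-131. These two
  parameters and `kappa_penetration` are the acknowledged calibration
  surface of the simplified camera model: the validated vendor-specific
  geometry they replace is not reproducible here, so they were set to
  physically plausible values such that the cold-background criterion is
  driven by the mechanism, not starved by a too-clean camera.
* **Energy response.** Gaussian blur with
  $\mathrm{FWHM}(E) = 9.9\%\,\sqrt{140/E}\cdot E$. Window counts are
  accumulated semi-analytically (Gaussian window fractions per deposit),
  which removes almost all classification noise from the expectation maps.

Every detected weight is tagged `primary`, `phantom_scatter`,
`camera_scatter` or `septal_penetration`. "Primary" means: no scatter in
the phantom, through the collimator aperture, full-energy deposit. A
full-energy deposit via Compton-then-reabsorption in the crystal counts as
primary — it is experimentally indistinguishable from a photopeak event
and the photon never scattered in the phantom; partial deposits and
backscatter-compartment returns are camera scatter.

## Replicated tomographic projections

All phantoms are cylindrically symmetric, so — following the reference
protocol — one high-statistics projection is simulated and replicated over
90 angles with independent Poisson noise. Two scales are deliberately
decoupled:

* `mc_decays` — Monte Carlo histories (desk-scale default $10^{-3}$ of the
  reference budget). The forced-detection expectation error at this scale
  is ≲0.3% and is *common to all angles* (a bias-like term, not noise).
* `n_decays` — the decay budget the Poisson draws represent (default: the
  full reference budget). Projection counts then match the reference
  statistics (roughly $10^4$–$10^5$ photopeak counts per projection).

Running the *count level* at $10^{-3}$ instead would leave ~10 counts per
projection, where OSEM's positivity constraint biases total counts by tens
of percent — a property of low-count EM reconstruction, not of the
calibration methods under study. The planar reference CF is computed from
the expectation maps directly (`use_expected = TRUE`), since it is an
expectation and sampling it would only add noise to every ratio.

## Reconstruction

A rotation-based attenuated parallel-beam projector (bilinear gather
rotation per slice, attenuation accumulated along the projection axis with
a half-voxel self-attenuation convention) and its exact matrix transpose
drive the OSEM update

$$x \leftarrow \frac{x}{P_s^T 1}\, P_s^T\!\left[\frac{y}{P_s x + s}\right],$$

with interleaved angle subsets and the TEW estimate $s$ strictly in the
denominator — scatter is never subtracted from the data, so negative
counts cannot arise. Defaults: 6 iterations × 10 subsets (Lu-177, Re-188),
35 × 6 (I-131), 12 subsets for the 96-projection quebec protocol; grid
64³ at 9.58 mm (the full-resolution 128³ at 4.79 mm is a configuration
option, ~8× slower). The TEW estimator is the trapezoid
$S = (C_L/W_L + C_U/W_U)\,W_P/2$ with widths always recomputed from the
window bounds.

Numerical conventions worth knowing:

* `osem()` images are in per-projection count units (its projector sums
  image counts once per angle); `reconstruct()` rescales to whole-scan
  units (× $n_p$) so that total image counts are comparable to the total
  acquired counts, the convention under which tomographic and planar CFs
  are directly comparable.
* The forced-detection exit attenuation uses the *voxelized* water columns
  of the same attenuation map the reconstructor uses, while transport
  sampling stays analytic. The alternative (fully analytic detection
  attenuation) leaves a ~3–5% discretization mismatch between data and
  system model at 9.58-mm voxels — larger than the 1–3% primary-photon
  consistency band the study relies on, and the reference study itself
  attributes its residual to exactly this voxelized-vs-analytic mismatch.
* Denominator guard $\varepsilon = 10^{-12}$; uniform positive
  initialization; gather-rotation conserves counts to interpolation
  accuracy (~0.1%) and its adjoint has a zero-mean local texture that the
  EM ratio structure cancels.

## What the generator does and does not emulate

Emulated: line emissions above 1% intensity with exact Table-style
energies; phantom Compton/photoelectric transport; window-resolved
projections with primary/scatter truth tags; collimator sensitivity,
penetration and camera backscatter at the spectrum-shape level; replicated
Poisson tomography. Not emulated: beta particles and bremsstrahlung,
coherent scattering, characteristic X-rays, pile-up and dead time,
depth-dependent collimator blur (CF uses total counts, which blur
preserves), the validated vendor camera geometry. Absolute CFs are
therefore *not* comparable to published absolute values — only relative
comparisons between calibration methods are claimed, and a green test
establishes exactly those relative statements under this stated world.

## Choices made where the design was open

* **Config A source material**: air (a true point source). The planar
  reference protocol minimizes source self-attenuation; a 1-mL water
  sphere would shift the reference CF by ~2%, comparable to the
  consistency criterion itself.
* **Config C decay split**: geometry enforces an exact 6:1 concentration
  ratio; the study driver feeds the published per-compartment decay budget
  (whose implied ratio is ~5.5) as explicit weights. The config-C CF
  divides by total activity, so the split barely matters.
* **Dual-head planar handling**: CF per head, then averaged.
* **Decay during acquisition**: ignored (≤0.1% for half-lives ≥17 h at
  ≤40 s per projection).
* **Attenuation-map energy**: the isotope's photopeak line (364/208/155
  keV); boundary voxels carry 2×-subsampled occupancy fractions, keeping
  voxelized volumes and central line integrals within 2% and 1% of the
  analytic values.
* **Source ROI** for the scatter-bias diagnostic: 1.5× the projected
  sphere radius; the bias-sign result is verified for 1.2–2×.
* **Cross sections**: plain-text tables (30–1000 keV), Klein–Nishina
  incoherent part from the closed form, photoelectric power laws anchored
  at standard reference values, log-log interpolation; water at 364 keV
  gives 0.110 cm⁻¹.

## Known limitations

The camera model is deliberately effective rather than geometric; its
backscatter and penetration scale factors were chosen once (see above) and
absolute sensitivities are ~2× below summed-head conventions. Low-count
reconstructions (≲100 counts/projection) show the usual positive-bias
breakdown of EM and are outside the validated regime. The quebec dialect
is wired for windows and subsets but no 96-projection reference dataset is
reproduced. Only the single-sphere simulation phantoms are implemented;
the multi-insert experimental phantoms (58–560 mL) are out of scope.
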