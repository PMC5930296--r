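# spectcal

Gamma-camera **calibration factors** (CF) for quantitative SPECT of the
therapy radionuclides **I-131, Lu-177 and Re-188** — a desk-scale
simulation study of how the calibration geometry changes the answer.

Quantitative SPECT converts a reconstructed count map into an activity map
via

```
CF = C / (A * t)        [cps/MBq]
```

(counts `C` recorded from activity `A` in time `t`; for simulated data,
`A*t` is replaced by the number of decays). Clinics determine CF either
from a **planar scan of a point source in air** (photopeak counts,
scatter-corrected with the triple-energy-window method, TEW) or from a
**tomographic scan of an extended phantom** (total counts of an OSEM
reconstruction with attenuation correction and TEW scatter in the update
denominator). This package simulates both, end to end, for four standard
phantoms:

| config | geometry | CF method |
|---|---|---|
| A | 1-mL point source in air (planar) | `CF_PWSC` |
| B | 100-mL hot sphere in a cold 20-cm water cylinder | `CF_R^B` |
| C | same sphere in a warm background, 6:1 concentration | `CF_R^C` |
| D | uniformly hot 6-L cylinder | `CF_R^D` |

and reproduces the study's relative findings: **the cold-background
configuration B overestimates the planar CF by >10%** (worst for Re-188,
whose 478/633-keV emissions backscatter into the 155-keV photopeak
window), while the distributed-activity configurations C and D agree with
the planar CF to a few percent and with each other to ~1%. The mechanism —
TEW underestimating true photopeak scatter over the source while
overestimating it over the background, amplified by attenuation
correction — is exposed by per-component truth tags in the simulator.

The package contains:

* a **forced-detection Monte Carlo** of a dual-head camera (Klein–Nishina
  transport, parallel-hole collimator with septal penetration, NaI crystal
  with partial deposits, backscatter compartment, Gaussian energy
  response), written in C++ (Rcpp);
* **TEW** scatter estimation and a rotation-based attenuated projector with
  its exact adjoint driving **OSEM** (scatter in the denominator, never
  subtracted);
* CF computation for every method of the study, a study driver, ROI-based
  scatter-bias diagnostics, spectra reports, config/CLI plumbing and
  acquisition persistence (JSON sidecar + raw arrays, minimal Interfile
  export).

## Worked example

```r
library(spectcal)

## planar point-source calibration (config A), Re-188
phA  <- make_configuration("A", "Re188")
acqA <- simulate_planar(phA, n_decays = 3.5e6, seed = 1)
cf_planar(acqA)                     # TEW-corrected photopeak CF
cf_planar(acqA, use_primary = TRUE) # truth (primary photons only)

## hot sphere in cold background (config B): simulate, reconstruct, calibrate
phB  <- make_configuration("B", "Re188")
acqB <- simulate_spect(phB, n_decays = 2e9, mc_decays = 2e6, seed = 1)
rec  <- reconstruct(acqB, phB)      # OSEM + AC + TEW-in-denominator
cf_tomographic(rec, n_projections = 90, n_decays = 2e9,
               method = "CF_Rsim^B", isotope = "Re188", configuration = "B")
```

prints (seed 1):

```
<calibration_result> CF_PWSC    Re188 config A: 17.36 +/- 2.2 cps/MBq
<calibration_result> CF_PPsim   Re188 config A: 17.85 +/- 2.3 cps/MBq
<calibration_result> CF_Rsim^B  Re188 config B: 19.56 +/- 0.01 cps/MBq
```

The tomographic CF from the cold-background phantom (19.6 cps/MBq) exceeds
the planar TEW CF (17.4 cps/MBq) by ~13% — the study's central effect; the
primary-photon CF shows the planar reference itself is accurate to ~3%.
The mechanism:

```r
roi <- source_roi(phB, acqB$meta$camera)
roi_scatter_bias(acqB, roi)$ratio                            # 0.773 (< 1)
roi_scatter_bias(acqB, region_spec("background_roi",
                 radius_px = roi$radius_px))$ratio           # 1.566 (> 1)
```

TEW under-corrects scatter where attenuation correction amplifies hardest
(the phantom center) and over-corrects the periphery, so reconstructed
totals come out high.

The full 3-isotope × 4-configuration grid:

```r
res <- run_calibration_study(seed = 1)        # ~8 min, 1 CPU
compare_cf(res, reference_method = "CF_PWSC")
```

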