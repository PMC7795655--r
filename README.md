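# paflux

Fluence-compensated oxygen-saturation (sO₂) imaging for dual-wavelength
LED-array photoacoustic (PA) systems.

LED-based PA scanners estimate blood oxygenation by imaging at two
near-infrared wavelengths that straddle the ~800 nm hemoglobin isosbestic
point (here 750 and 850 nm) and unmixing the two amplitude images into
deoxy-/oxy-hemoglobin (HbR/HbO₂) concentrations. The catch is light fluence:
the LED units are wide, tilted toward the imaging plane, fire the two
wavelengths from different rows with a 2:1 pulse-energy ratio, and their
illumination decays and recolors with depth. Ignoring that makes sO₂
estimates drift with depth. This package implements the full correction
chain for an AcousticX-style probe:

1. **US segmentation** — a co-registered B-mode image is turned into a
   binary tissue mask (median filter → threshold → Sobel boundary →
   hole filling → largest component).
2. **Medium construction** — the mask is edge-replicated and extruded into
   a 3-D labeled voxel volume with per-wavelength optical properties
   (bundled presets for a soft-tissue phantom, mouse thigh, human forearm;
   water background).
3. **Monte-Carlo fluence** — a compiled voxel photon-transport core
   (Henyey–Greenstein scattering, implicit capture, Russian roulette,
   track-length fluence estimator, per-photon seeded RNG) simulates the
   probe's 240 LED elements per wavelength and returns the imaging-plane
   fluence map Φ(r, λ).
4. **Compensation** — PA images are divided by pulse energy and Φ, with a
   configurable fluence floor and amplitude display gate.
5. **Linear unmixing** — the per-pixel 2×2 system

   ```
   A x = b,   A = [ ε_HbR(750)  ε_HbO2(750) ]     x = (c_HbR, c_HbO2)
                  [ ε_HbR(850)  ε_HbO2(850) ],    b = (p/EΦ at 750, 850)
   ```

   is solved exactly (the least-squares solution `(AᵀA)⁻¹Aᵀb` for the
   square case) and `sO₂ = 100 · c_HbO2 / (c_HbO2 + c_HbR)`.

A synthetic-phantom module generates the validation scenes end-to-end —
blood-filled 0.5 mm tubes at depth in homogeneous or two-slab (water over
tissue) media, speckled B-mode images with known boundaries, and forward PA
frames from the initial-pressure model `p = Γ µa E Φ` with calibrated noise
— so every claim in the test suite is checked against known ground truth
without instrument data.

## Worked example

Simulate a tube phantom (96% saturated blood at 5/10/15 mm in an
intralipid-style medium), then run the five-step pipeline on its synthetic
US/PA frames — segmentation and fluence simulation use fresh seeds, so
nothing is recycled from the generator:

```r
library(paflux)

spec  <- make_tube_phantom(depths = c(5, 10, 15), so2 = 96)
frame <- synthetic_frame(spec, n_photons = 7e5, seed = 20,
                         noise_sigma = 0, envelope = FALSE)

cfg <- pipeline_config(threshold = 0.25 * mean(frame$us),
                       n_photons = 6e5, seed = 40,
                       lateral_symmetry = TRUE, average_slices = 5,
                       amplitude_gate_k = NULL)
res <- run_pipeline(frame$us, frame$pa[["750"]][[1]],
                    frame$pa[["850"]][[1]], cfg)

for (i in 1:3) {
  t <- spec$tubes[i, ]
  r <- roi_mean_so2(res$so2, c(t$x - .15, t$x + .15, t$z - .15, t$z + .15))
  cat(sprintf("tube at %2.0f mm: sO2 = %5.1f %%\n", t$z, r$mean))
}
```

```
tube at  5 mm: sO2 =  94.7 %
tube at 10 mm: sO2 =  96.6 %
tube at 15 mm: sO2 =  94.1 %
```

All three tubes come back near the 96% truth (residuals are Monte-Carlo
ratio noise). The uncompensated map from the same run
(`res$so2_uncompensated`) instead reads high-to-low with depth — 86.6,
81.3, 80.6% over the same ROIs — because the 850 nm rows sit nearest the
transducer and illuminate shallower — exactly the depth bias that fluence
compensation removes. `compare_compensation()` tabulates both maps over
ROIs and reports the depth trend.

Fluence behavior itself is summarized by the 1/e decay depth of the
laterally averaged profile below the usable-region start (9.2 mm):

```r
src <- build_led_sources(probe_config())
med <- homogeneous_medium(grid3d(c(372, 176, 200), spacing = 0.148),
                          list(`750` = optical_properties(0.101, 10.5, 0.9)))
f   <- simulate_fluence(med, src, 750, 1e6, seed = 101)
f2  <- symmetrize_fluence(extract_imaging_plane(f, c(272, 200),
                                                average_slices = 3))
one_over_e_depth(f2, roi_start_depth = 9.2)
#> [1] 6.527345
```

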