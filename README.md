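# trssx

Analysis toolkit for time-resolved serial synchrotron crystallography
(TR-SSX) experiments on photoactive retinal proteins — the kind of study in
which microcrystals of a photosensor such as sensory rhodopsin II are
extruded in a lipidic-cubic-phase (LCP) microjet, photoexcited by a
millisecond blue-light flash, and probed by X-ray diffraction while
flash-photolysis spectroscopy tracks the photocycle intermediates in
parallel.

The package is written for structural biologists who have (or simulate)
three kinds of data:

* time-resolved difference absorption spectra (wavelength × delay matrices),
* reflection amplitude sets for "light" and "dark" states plus model phases,
* refined atomic models of resting and photoactivated states,

and who want the standard analyses connecting them: SVD-based kinetic
decomposition, photoexcitation budgets, isomorphous difference maps,
per-residue projections, bootstrap error bars, and Cα displacement
profiles. Synthetic-data generators with exact ground truth make every step
testable without beamline data.

## The model at the core

Difference spectra are decomposed under the sequential photocycle scheme
M → O → ground with rate constants k₁ and k₂ and occupancies

    c_M(t) = e^(−k₁ t)
    c_O(t) = k₁/(k₂ − k₁) · (e^(−k₁ t) − e^(−k₂ t))      (k₁ t e^(−k₁ t) if k₁ = k₂)

`fit_photocycle()` truncates the data matrix to its two leading singular
components and, for each trial (k₁, k₂) on a log-spaced grid, solves the two
basis spectra by linear least squares inside that rank-2 subspace (variable
projection), keeping the rate pair with the smallest residual and polishing
it by local search. From the fitted model it reports the M/O crossover time
(c_M = c_O) and the half-decay time of the total photoexcited population
(c_M + c_O = 1/2).

Difference maps follow the isomorphous convention
FT[(F_obs(light) − F_obs(dark)) · exp(i·Φ_dark)], normalised by the map rms
σ. Other modules implement the photon/jet budget closed forms
(F = ½P·t/(π r²_FWHM), σ_abs = 1000·ln10·ε/N_A, v_jet = Q/(π r²_jet), …),
the Wickstrand-style 1D projection of difference density onto the sequence,
bootstrap resampling of redundant amplitude observations, and Kabsch
superposition / per-residue Cα displacement of paired models.

## Worked example

```r
library(trssx)

# synthetic flash-photolysis series under the study conditions:
# tau1 ~ 81 ms, tau2 ~ 220 ms, 30 delays over 0-500 ms, SNR 20
truth <- solve_rates_from_times(63, 240)
g <- make_spectral_series(k1 = truth$k1, k2 = truth$k2,
                          delays = seq(0, 500, length.out = 30),
                          snr = 20, seed = 42)
fit <- fit_photocycle(g$series)
print(fit)
```

```
Sequential photocycle decomposition (SVD rank-2 variable projection)
  rates:      k1 = 0.012189 /ms (tau1 = 82.04 ms), k2 = 0.0046264 /ms (tau2 = 216.2 ms)
  M/O crossover:     63.83 ms
  M+O half-decay:    239.1 ms
  residual RMS:      0.000461 Delta OD
  SVD rank gap s3/s2: 0.0291
```

The fitted lifetimes (82 / 216 ms) recover the generating ones (81 / 219 ms)
to a few percent at this noise level; the crossover (63.8 ms) is the time at
which the M and O populations are equal, and the half-decay (239 ms) the
time at which half the initially photoexcited molecules have returned to the
resting state.

```r
photon_budget()[c("fluence_mj_cm2", "velocity_um_per_s",
                  "translation_per_flash_um", "column_height_um")]
# $fluence_mj_cm2            147.1299   mJ/cm^2 within the laser FWHM
# $velocity_um_per_s         754.5123   downward LCP jet speed
# $translation_per_flash_um  188.6281   sample travel between 4 Hz flashes
# $column_height_um           90.5415   photoactivated column height (120 ms)
```

A difference-map round trip on a toy crystal:

```r
toy  <- toy_crystal(c(16, 14, 12, 90, 90, 90),
                    data.frame(chain = "A", resid = 1:2, atom = c("CA", "O"),
                               fx = c(0.2, 0.6), fy = c(0.3, 0.7),
                               fz = c(0.4, 0.2), width = c(1.2, 1),
                               weight = c(12, 8)), d_min = 1.5)
dark  <- structure_factors_direct(toy)
light <- structure_factors_direct(perturb_crystal(toy, "delete_atom", atom = 2))
map   <- compute_difference_map(light$reflections, dark$reflections,
                                dark$phases, scale_mode = "none")
peak_search(map, 3, crystal_sites(toy))   # strongest feature: negative, at the
                                          # deleted atom, in sigma units
```

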