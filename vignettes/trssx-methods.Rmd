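---
title: "Methods: kinetic decomposition and difference-density analysis for TR-SSX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic decomposition and difference-density analysis for TR-SSX}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trssx)
```

This vignette documents the models behind `trssx`, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not demonstrate about real data.

## The sequential photocycle model

Flash photolysis of a blue-light photosensor such as sensory rhodopsin II
populates, on the millisecond timescale relevant to serial-crystallography
delays, two spectrally distinct intermediates: M (blue-shifted, deprotonated
Schiff base) and O (red-shifted, late intermediate). `trssx` models their
populations as the irreversible chain M → O → ground:

$$c_M(t) = e^{-k_1 t}, \qquad
  c_O(t) = \frac{k_1}{k_2-k_1}\left(e^{-k_1 t} - e^{-k_2 t}\right),$$

with the analytic limit $c_O = k\,t\,e^{-kt}$ when $k_1 = k_2$ (applied for
$|k_1-k_2| < 10^{-9}k_1$, so the near-degenerate case never divides by a
vanishing difference). Assumptions: unit photoexcited population entirely in
M at $t = 0$ (formation of M from the earlier J/K/L intermediates is
complete within tens of microseconds, far below the millisecond delays
modelled); no back-reactions; no branching. Earlier intermediates are
deliberately out of scope: the decomposition uses exactly two components.

Two derived observables summarise a fit: the **crossover time** (smallest
$t>0$ with $c_M = c_O$) and the **half-decay time** ($c_M + c_O = 1/2$).
Both are located by a sign-change scan on a log grid over
$(0,\,100\max(1/k_1, 1/k_2))$ followed by root polishing to $10^{-6}$ ms;
`NA` is the documented "no crossing" / "conserved total" sentinel (the
latter arises when $k_2 = 0$). `solve_rates_from_times()` inverts the pair
of observables to rates by nested root finding, using the bound that the
fastest possible half-decay at fixed $k_1$ is $\ln 2/k_1$.

## Fitting: truncated SVD + variable projection

`fit_photocycle()` assumes the data matrix $D$ (wavelength × delay, ΔOD) is
a rank-2 bilinear product plus noise, $D \approx S\,C(k_1,k_2)^T$. The fit:

1. truncates $D$ to its two leading singular vectors (Eckart–Young);
2. for each $(k_1, k_2)$ on a log-spaced grid (default 40 × 40 over
   $10^{-4}$–$1$ ms$^{-1}$, a range spanning microsecond-formed to
   second-lived intermediates), solves the basis spectra by linear least
   squares within the rank-2 left subspace (variable projection — the
   linear parameters are eliminated exactly for every trial of the
   nonlinear ones);
3. polishes the best grid pair by Nelder–Mead on log rates.

Because the fit imposes no sign or shape constraints on the basis spectra,
the span of $\{c_M, c_O\}$ equals the span of
$\{e^{-k_1 t}, e^{-k_2 t}\}$, which is symmetric under $k_1 \leftrightarrow
k_2$: the residual alone cannot tell which exponential belongs to M. The
package resolves this classical exponential-analysis ambiguity by the
convention $k_1 \ge k_2$ — M decays into O at least as fast as O returns to
ground, which holds for the system studied ($\tau_1 \approx 81$ ms
$< \tau_2 \approx 220$ ms) — with `slow_first = TRUE` for systems ordered
the other way. The half-decay time is invariant under the exchange; the
crossover is not, which is why the convention must be explicit.

Unconstrained amplitudes are a deliberate choice (non-negativity of
occupancies is guaranteed by the model parametrisation itself, and sign
constraints on difference basis spectra would be wrong — they are
differences). Non-identifiable input (second singular value below
$10^{-6}$ of the first, i.e. effectively rank 1) is an error, not a
degenerate fit.

**Normalisation.** Reported traces are the analytic occupancies with
$c_M(0) = 1$: the total photoexcited population is 1 when extrapolated back
to $t = 0$. All signal amplitude is carried by the basis spectra (ΔOD per
unit initial photoexcited population); the factor applied to the traces to
reach this normalisation is stored in `scale` (identically 1 for the
analytic parametrisation — the field exists so that re-scaled traces remain
traceable). Absolute photoexcited fractions are not recoverable from
difference spectra alone.

**Repeat averaging.** Spectroscopy protocols repeat each measurement many
times (45 in the emulated setup). `average_repeats()` rejects a repeat when
the RMS deviation of its matrix from the element-wise median matrix exceeds
`rejection_k` (default 3) times the median of all repeats' RMS deviations —
a median-based rule chosen because the underlying protocols state only that
outliers were rejected; the median reference keeps the criterion robust to
the outliers being tested for.

**Beam-overlap correction.** In an LCP microjet the photoactivated column
translates downward out of the X-ray beam, so late time bins under-sample
the photoactivated population. `occupancy_beam_correction()` provides a
linear-overlap geometry, $\max(0, 1 - vt/(H + h_\mathrm{beam}))$: the
literature states that such a correction is applied but not its functional
form, so the package implements the simplest geometric model and documents
it as such. It is plumbing around the decomposition, not part of the fit.

## Photon and jet budget

Closed forms with SI-definition constants ($N_A = 6.02214076\times10^{23}$,
$h = 6.62607015\times10^{-34}$ J s, $c = 2.99792458\times10^8$ m/s):

* fluence averaged within the FWHM: $F = \tfrac12 P t / (\pi r_{\mathrm{FWHM}}^2)$
  — exactly half a Gaussian beam's power falls inside the FWHM circle, and
  this convention reproduces the instrument's worked value (147 mJ/cm² for
  2.6 mW, 5 ms, 75 µm);
* absorption cross-section $\sigma = 1000 \ln(10)\,\varepsilon/N_A$;
* photons per chromophore $F\sigma/h\nu$. With $\varepsilon = 48\,000$
  M⁻¹cm⁻¹ at 488 nm this evaluates to ≈66, whereas ≈49 is the surface
  value quoted alongside these inputs in the literature for this setup; the
  plain formula does not reproduce it (an implicit wavelength-dependent
  absorbance correction relative to the 498 nm peak may be involved). The
  package reports the formula value and does not guess a correction
  factor; the depth-average chain below therefore takes the quoted surface
  value as an explicit input rather than recomputing it.
* depth-average transmission over a uniform path,
  $(1-10^{-\mathrm{OD}})/(\mathrm{OD}\ln 10)$ — 0.7525 at OD 0.26, turning
  a surface value of 49 into ≈37 through a 20 µm crystal;
* jet kinematics $v = Q/(\pi r_\mathrm{jet}^2)$, translation per flash
  $v/f_\mathrm{rep}$, column height $v\,t_\mathrm{loss}$ (default
  $t_\mathrm{loss} = 120$ ms, the observed residence time of photoactivated
  crystals in the beam).

## Isomorphous difference maps

`compute_difference_map()` implements
$\mathrm{FT}[(F_o^\mathrm{light} - F_o^\mathrm{dark})\,e^{i\Phi_\mathrm{dark}}]$:
common indices only, optional symmetric resolution cutoff, least-squares
amplitude scaling (global, or per resolution shell for B-factor-like
discrepancies; the upstream merging pipeline's scaling scheme is not
specified, so both are options), Friedel completion, inverse FFT, and σ
(map rms) annotation. Numerical conventions:

* all computation in P1 — symmetry expansion belongs to upstream tools;
* plain ΔF coefficients, no weighting, matching the stated formula;
* F(000) excluded, so maps are zero-mean;
* grid spacing $d_\mathrm{min}/3$; extrema are reported on grid points,
  without interpolation;
* minimum-image distances wrap fractional differences to $[-\tfrac12,
  \tfrac12)$ before orthogonalisation — exact for the orthorhombic toy
  cells generated here, approximate for strongly oblique cells.

`peak_search()` finds 26-neighbour local extrema above the threshold
(default convention ±3σ), merging same-sign extrema within 1.5 Å (opposite
signs are never merged: paired positive/negative lobes are the signature of
atomic motion and must survive). `feature_at_site()` reports the signed
ball-extremum at a named position, the convention in which feature heights
at atoms are quoted.

One property of the map formula worth knowing when interpreting the toy
tests: with dark-model phases, only the ΔF component in phase with the dark
structure factors is recovered; the orthogonal component is scattered
through the cell as background. On a sparse toy crystal this background
reaches 1–2σ anywhere in the cell, because σ itself is dominated by the one
real feature. In protein-scale maps the same scattered background is what σ
mostly measures, which is why ±3σ contours are meaningful there.

## 1D sequence projection

`project_to_sequence()` assigns every above-threshold grid point within
`cutoff_A` of a model atom to the residue of its nearest atom (ties by
lowest atom serial) and accumulates $|\rho|$ separately by sign. Defaults:
threshold 3σ (matching the contouring convention) and cutoff 2 Å; the
published projection procedure does not print its parameters, so both are
exposed. Summing $|\rho|$ (integration) rather than recording per-residue
extrema is the package's documented convention — conservation
(assigned + dropped = total above threshold) is then exact and testable.
Profiles correlate via Pearson's r on concatenated (positive, negative)
vectors; zero-variance input returns `NA`. Built-in tables provide the
photosensor's helix boundaries and the four canonical regions used for
time-course averaging (helix C 71–81, D/E 118–124, F + F/G loop 143–171,
helix G 197–213).

## Bootstrap error estimation

`bootstrap_feature_errors()` resamples the individual amplitude
observations within each Miller index with replacement (the resampling unit
in the emulated procedure is not stated in print; per-image resampling is
upstream of this package's inputs, so the individual observation is the
natural unit here), merges by unweighted mean, recomputes the difference
map, and evaluates each site; the per-site standard deviation over
replicates (default 100, as in the emulated procedure) is the error bar.
Observations are sorted within each index before resampling, making the
estimate invariant to file ordering; all resampling flows from one explicit
seed. `coordinate_separation_errors()` pairs model ensembles by replicate
index, computes per-residue Cα separations per pair, and reports their mean
and standard deviation over replicates.

## Displacement analysis

Kabsch superposition (proper rotation enforced via the SVD determinant
correction) over Cα atoms matched strictly by chain + residue id; unmatched
residues are counted, not fatal — deposited models routinely differ in
modelled range. Near-collinear Cα sets trigger a warning because the
rotation is then ill-determined. `per_residue_displacement()` defaults to
**no** superposition, the right choice when the two "models" are conformers
of one partial-occupancy refinement sharing a crystal frame; superposition
should be switched on when comparing separately refined entries. Both modes
are provided because published helix-displacement figures do not state
which was used. Region means are arithmetic means over inclusive residue
ranges (e.g. helix F of the photosensor, residues 144–175, and its
proton-pump counterpart, 155–186).

## Synthetic data: what it emulates and what it does not

`make_spectral_series()` builds difference basis spectra as (intermediate
Gaussian band − ground-state Gaussian band) with the ground bleach at
498 nm, M at 390 nm and O at 530 nm — the first is the measured ground-state
peak, the latter two are physically plausible defaults for a blue-shifted M
and red-shifted O, configurable and not measured values. Band sd 28 nm,
ΔOD scale 0.05, 30 delays over 0–500 ms, and default rates solved from the
observed 63 ms crossover / 240 ms half-decay ($\tau_1 \approx 81$,
$\tau_2 \approx 220$ ms). SNR is defined as rms(clean signal)/noise sd.
The generator returns its ground truth, so recovery tests compare against
known rates and spectra. It does **not** emulate baseline drift, scattering
backgrounds, wavelength-dependent noise, sample inhomogeneity, or the
slowdown seen once microcrystals form — passing recovery tests show the
estimator is correct under the model, not that real samples obey the model.

`toy_crystal()` uses one isotropic Gaussian per atom so that structure
factors have an exact closed form by direct summation and every map
operation has an independent oracle (direct summation vs FFT agree to
$10^{-6}$; Parseval's identity holds to the same level). Tabulated
scattering factors, anisotropy, solvent and symmetry are deliberately
absent — the toys validate the transform machinery, not crystallographic
realism.

## Problem sizes and determinism

Test and acceptance runs use deliberately small problems — 186 × 30
spectral matrices, toy cells of 10–16 Å with a few thousand reflections,
15³–32³ grids, 20 Monte-Carlo seeds for timing recovery, 60-replicate
bootstraps in tests (100 is the analysis default) — sizes at which every
oracle (dense scans, brute-force sums, exhaustive searches) is itself
cheap and exact. Every stochastic routine takes an explicit seed and is
bit-reproducible given one.

## Known limitations

* Reflection data are read from whitespace text (`h k l F [sigF]`); binary
  MTZ/CCP4 formats are not parsed — conversion is a one-liner in any
  crystallographic toolchain and keeping the package text-only keeps it
  dependency-light.
* P1 only; symmetry-expanded input is accepted but never generated.
* The isomorphous approximation's scattered background (above) means toy
  σ-units are not comparable to protein-map σ-units.
* The beam-overlap correction is a geometric stand-in for an unpublished
  functional form and should be recalibrated against measured loss curves
  where available.
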