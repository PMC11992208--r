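## Physical constants (SI definitions)
.N_AVOGADRO <- 6.02214076e23
.PLANCK_J_S <- 6.62607015e-34
.LIGHTSPEED_M_S <- 2.99792458e8

## unit conversions used across the budget
.UM2_PER_CM2 <- 1e8        # cm^2 -> um^2
.UM3_PER_UL <- 1e9         # ul  -> um^3

#' Mean laser fluence within the FWHM focal spot
#'
#' For a Gaussian beam exactly half the total power falls inside the FWHM
#' circle, so the fluence averaged across the FWHM is
#' `0.5 P t_pulse / (pi (FWHM/2)^2)`.
#'
#' @param power_mw laser power at the sample, mW.
#' @param pulse_ms pulse duration, ms.
#' @param fwhm_um FWHM diameter of the focal spot, um.
#' @return fluence in mJ/cm^2.
#' @export
mean_fluence_within_fwhm <- function(power_mw, pulse_ms, fwhm_um) {
  stopifnot(power_mw >= 0, pulse_ms > 0, fwhm_um > 0)
  area_cm2 <- pi * (fwhm_um / 2)^2 / .UM2_PER_CM2
  0.5 * power_mw * (pulse_ms / 1000) / area_cm2
}

#' Absorption cross-section from a molar extinction coefficient
#'
#' `sigma = 1000 ln(10) eps / N_A` in cm^2 per molecule.
#'
#' @param extinction molar (decadic) extinction coefficient, 1/(M cm).
#' @return cross-section in cm^2.
#' @export
absorption_cross_section <- function(extinction) {
  stopifnot(extinction >= 0)
  1000 * log(10) * extinction / .N_AVOGADRO
}

#' Photons absorbed per chromophore at the illuminated surface
#'
#' The dimensionless product F sigma / (h nu) of fluence, absorption
#' cross-section and photon energy.
#'
#' @param fluence_mj_cm2 pulse fluence, mJ/cm^2.
#' @param cross_section_cm2 absorption cross-section, cm^2.
#' @param wavelength_nm photon wavelength, nm.
#' @return dimensionless photons-per-chromophore.
#' @export
photons_per_chromophore <- function(fluence_mj_cm2, cross_section_cm2,
                                    wavelength_nm) {
  stopifnot(fluence_mj_cm2 >= 0, cross_section_cm2 >= 0, wavelength_nm > 0)
  photon_energy_j <- .PLANCK_J_S * .LIGHTSPEED_M_S / (wavelength_nm * 1e-9)
  (fluence_mj_cm2 / 1000) * cross_section_cm2 / photon_energy_j
}

#' Depth-averaged attenuation factor through a crystal of given optical density
#'
#' Mean transmission over a uniform path through total optical density `od`:
#' `(1 - 10^-od) / (od ln 10)`; 1 at od = 0.
#'
#' @param od optical density along the full path (dimensionless, >= 0).
#' @return factor in (0, 1].
#' @export
depth_average_factor <- function(od) {
  stopifnot(all(od >= 0))
  ifelse(od == 0, 1, (1 - 10^(-od)) / (od * log(10)))
}

#' Kinematics of the LCP injector microjet
#'
#' Downward jet velocity from volumetric flow and jet diameter, the sample
#' translation between successive laser flashes, and the height of the
#' photoactivated column swept past the X-ray beam within `t_loss_ms`.
#'
#' @param flow_ul_per_min LCP volumetric flow rate, ul/min.
#' @param jet_diameter_um jet diameter, um.
#' @param repetition_hz laser flash repetition rate, Hz.
#' @param t_loss_ms time after which photoactivated crystals have left the
#'   beam, ms (default 120).
#' @return list with `velocity_um_per_s`, `translation_per_flash_um`,
#'   `column_height_um`.
#' @export
jet_kinematics <- function(flow_ul_per_min, jet_diameter_um, repetition_hz,
                           t_loss_ms = 120) {
  stopifnot(flow_ul_per_min > 0, jet_diameter_um > 0, repetition_hz > 0,
            t_loss_ms > 0)
  q_um3_s <- flow_ul_per_min * .UM3_PER_UL / 60
  v <- q_um3_s / (pi * (jet_diameter_um / 2)^2)
  list(velocity_um_per_s = v,
       translation_per_flash_um = v / repetition_hz,
       column_height_um = v * t_loss_ms / 1000)
}

#' Full photoexcitation and jet-geometry budget
#'
#' Combines the laser, crystal-optics and jet calculations into one report.
#' Defaults are the blue-laser / LCP-microjet configuration of the
#' photophobic-sensor experiment: 2.6 mW at 488 nm in a 75 um FWHM spot,
#' 5 ms pulses at 4 Hz, extinction 48000 1/(M cm), OD 0.26 over a 20 um
#' crystal, 0.2 ul/min through a 75 um jet.
#'
#' @param power_mw,wavelength_nm,fwhm_um,pulse_ms laser parameters.
#' @param extinction,od,path_um crystal optical parameters.
#' @param flow_ul_per_min,jet_diameter_um,repetition_hz,t_loss_ms jet
#'   parameters.
#' @return list of all derived quantities (fluence, cross-section, surface
#'   and depth-averaged photons per chromophore, depth-average factor, jet
#'   kinematics).
#' @export
photon_budget <- function(power_mw = 2.6, wavelength_nm = 488, fwhm_um = 75,
                          pulse_ms = 5, extinction = 48000, od = 0.26,
                          path_um = 20, flow_ul_per_min = 0.2,
                          jet_diameter_um = 75, repetition_hz = 4,
                          t_loss_ms = 120) {
  fl <- mean_fluence_within_fwhm(power_mw, pulse_ms, fwhm_um)
  xs <- absorption_cross_section(extinction)
  surf <- photons_per_chromophore(fl, xs, wavelength_nm)
  dav <- depth_average_factor(od)
  jet <- jet_kinematics(flow_ul_per_min, jet_diameter_um, repetition_hz,
                        t_loss_ms)
  c(list(fluence_mj_cm2 = fl,
         cross_section_cm2 = xs,
         photons_per_chromophore_surface = surf,
         depth_average_factor = dav,
         photons_per_chromophore_volume = surf * dav),
    jet)
}
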