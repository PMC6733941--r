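#' Parameters of the forward solubilization model
#'
#' Describes the expected single-vesicle response to detergent injection: a
#' stable FRET efficiency `E0` at near-constant total intensity before the
#' injection at `t0`, then an exponential FRET drop to `E_plateau` with
#' half-life `t_E` (vesicle swelling), overlapped with an exponential loss of a
#' fraction `f_loss` of the total intensity with half-life `t_L` (lysis).
#' Half-lives are true half-lives: the generator uses base-2 exponentials
#' `2^(-t/t_half)` directly.
#'
#' Defaults are the observed single-vesicle values for 200 nm PC:PS vesicles
#' with 20% cholesterol at 0.16 mM TX-100: `E0 = 0.46`, `E_plateau = 0.22`,
#' ~50% total-intensity loss, swelling on the ~5 s scale and lysis on the
#' ~40 s scale, 50 ms integration time, injection at 90 s.
#'
#' @param E0 Initial FRET efficiency (dimensionless, in (0, 1)).
#' @param E_plateau Post-swelling FRET efficiency; must satisfy
#'   `0 < E_plateau < E0 < 1`.
#' @param t_E Swelling half-life (s).
#' @param t_L Lysis half-life (s).
#' @param f_loss Fraction of total intensity lost at completion (0-1).
#' @param I_tot0 Pre-injection total intensity (counts/frame).
#' @param t0 Injection time (s).
#' @param frame_dt Integration time per frame (s).
#' @param duration Trace length (s).
#' @param background Mean background per channel (counts/frame).
#' @param bleach_rate Optional photobleaching rate (1/s); 0 disables.
#' @return An object of class `solub_params`.
#' @export
solub_params <- function(E0 = 0.46, E_plateau = 0.22, t_E = 5, t_L = 40,
                         f_loss = 0.5, I_tot0 = 200, t0 = 90,
                         frame_dt = 0.05, duration = 500,
                         background = 0, bleach_rate = 0) {
  if (!(E_plateau > 0 && E_plateau < E0 && E0 < 1)) {
    stop_invalid("need 0 < E_plateau < E0 < 1 (got E0 = %g, E_plateau = %g)",
                 E0, E_plateau)
  }
  check_positive(t_E, "t_E")
  check_positive(t_L, "t_L")
  if (f_loss < 0 || f_loss > 1) stop_invalid("`f_loss` must lie in [0, 1]")
  check_positive(I_tot0, "I_tot0")
  check_nonneg(t0, "t0")
  check_positive(frame_dt, "frame_dt")
  check_positive(duration, "duration")
  check_nonneg(background, "background")
  check_nonneg(bleach_rate, "bleach_rate")
  structure(
    list(E0 = E0, E_plateau = E_plateau, t_E = t_E, t_L = t_L,
         f_loss = f_loss, I_tot0 = I_tot0, t0 = t0, frame_dt = frame_dt,
         duration = duration, background = background,
         bleach_rate = bleach_rate),
    class = "solub_params"
  )
}

#' Parameters of the Brownian-dynamics FCS simulation
#'
#' Fluorescent particles diffuse in a periodic box and are detected through a
#' 3D Gaussian focal volume with radial 1/e^2 radius `omega_xy` and structure
#' parameter `Omega` (axial/radial ratio). The particle number in the box is
#' chosen so the mean occupancy of the effective focal volume
#' `V = pi^(3/2) * Omega * omega_xy^3` equals `mean_N`. Optional triplet
#' blinking is a two-state telegraph process with equilibrium dark fraction
#' `A_T / (1 + A_T)` and correlation time `tau_T`.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param mean_N Mean particle number in the focal volume.
#' @param omega_xy Radial 1/e^2 radius of the focus (m). Default 0.27 um,
#'   the Rhodamine 123 calibration value.
#' @param Omega Structure parameter (axial/radial ratio, > 1). Default 4.84,
#'   back-solved from the calibrated focal volume of 0.53 um^3.
#' @param brightness Mean counts per particle per second at focus center.
#' @param A_T Triplet amplitude (0 disables blinking).
#' @param tau_T Triplet correlation time (s).
#' @param duration Trace length (s).
#' @param bin_dt Count bin width (s); should be well below the diffusion
#'   time `omega_xy^2/(4 D)`.
#' @param box_factor Simulation box half-width in units of `omega_xy`
#'   (and of `omega_z` axially).
#' @return An object of class `fcs_sim_params`.
#' @export
fcs_sim_params <- function(D, mean_N = 2, omega_xy = 0.27e-6, Omega = 4.84,
                           brightness = 3e4, A_T = 0, tau_T = 1e-6,
                           duration = 100, bin_dt = 4e-4, box_factor = 8) {
  check_positive(D, "D")
  check_positive(mean_N, "mean_N")
  check_positive(omega_xy, "omega_xy")
  check_positive(Omega, "Omega")
  if (Omega <= 1) stop_invalid("`Omega` must exceed 1")
  check_positive(brightness, "brightness")
  check_nonneg(A_T, "A_T")
  check_positive(tau_T, "tau_T")
  check_positive(duration, "duration")
  check_positive(bin_dt, "bin_dt")
  check_positive(box_factor, "box_factor")
  structure(
    list(D = D, mean_N = mean_N, omega_xy = omega_xy, Omega = Omega,
         brightness = brightness, A_T = A_T, tau_T = tau_T,
         duration = duration, bin_dt = bin_dt, box_factor = box_factor),
    class = "fcs_sim_params"
  )
}

#' Parameters of the synthetic QCM-D solubilization trace
#'
#' A vesicle layer sits at a stable frequency shift `-f_vesicle` relative to
#' the bare sensor. After injection the trace approaches
#' `-f_vesicle * (1 + gain_frac)` (detergent-uptake mass gain) over a gain
#' phase, then relaxes towards `-f_vesicle * (1 + gain_frac) * (1 - loss_frac)`
#' (lysis mass loss). Phase ramps are truncated exponentials normalized to
#' complete exactly at their phase boundary, so noiseless traces round-trip
#' through [detect_mass_phases()] to machine precision. Default gain/loss
#' fractions are the observed ~5% gain and ~63% loss.
#'
#' @param f_vesicle Frequency-shift magnitude of the vesicle layer (Hz, at the
#'   chosen overtone). 0 gives a vesicle-free control trace.
#' @param gain_frac Relative mass gain in the uptake phase.
#' @param loss_frac Relative mass loss in the lysis phase (0-1), referenced to
#'   the peak mass.
#' @param tau_gain,tau_loss Phase time constants (s).
#' @param overtone Odd harmonic number (7 in the reference experiment).
#' @param noise_sd Gaussian frequency noise (Hz).
#' @param dissipation_scale Dissipation change per Hz of frequency deviation
#'   (in the 1e-6 dissipation convention).
#' @param injection_time Injection time (s).
#' @param gain_duration Length of the gain phase (s); default `8 * tau_gain`.
#' @param hold_duration Plateau between mass gain and mass loss (s), the
#'   window where intact vesicles change conformation without mass loss.
#' @param duration Total trace length (s).
#' @param dt Sampling interval (s).
#' @return An object of class `qcmd_sim_params`.
#' @export
qcmd_sim_params <- function(f_vesicle = 28, gain_frac = 0.05, loss_frac = 0.63,
                            tau_gain = 5, tau_loss = 20, overtone = 7,
                            noise_sd = 0, dissipation_scale = 0.05,
                            injection_time = 120,
                            gain_duration = 8 * tau_gain,
                            hold_duration = 20,
                            duration = 600, dt = 1) {
  check_nonneg(f_vesicle, "f_vesicle")
  check_nonneg(gain_frac, "gain_frac")
  if (loss_frac < 0 || loss_frac > 1) stop_invalid("`loss_frac` must lie in [0, 1]")
  check_positive(tau_gain, "tau_gain")
  check_positive(tau_loss, "tau_loss")
  if (overtone %% 2 != 1 || overtone < 1) {
    stop_invalid("`overtone` must be an odd integer >= 1")
  }
  check_nonneg(noise_sd, "noise_sd")
  check_nonneg(dissipation_scale, "dissipation_scale")
  check_positive(injection_time, "injection_time")
  check_positive(gain_duration, "gain_duration")
  check_nonneg(hold_duration, "hold_duration")
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  if (injection_time + gain_duration + hold_duration >= duration) {
    stop_invalid("`duration` must extend beyond the gain and hold phases")
  }
  structure(
    list(f_vesicle = f_vesicle, gain_frac = gain_frac, loss_frac = loss_frac,
         tau_gain = tau_gain, tau_loss = tau_loss, overtone = overtone,
         noise_sd = noise_sd, dissipation_scale = dissipation_scale,
         injection_time = injection_time, gain_duration = gain_duration,
         hold_duration = hold_duration, duration = duration, dt = dt),
    class = "qcmd_sim_params"
  )
}

#' Hill-model parameter set
#'
#' Parameters of the dose-response model
#' `E(c) = A + (B - A) * c^n / (k^n + c^n)`, where `A` and `B` are the FRET
#' efficiencies at the start and end of the titration, `k` the half-maximal
#' concentration constant (mM) and `n` the Hill coefficient. Defaults are the
#' reference TX-100 titration fit (A = 0.43, B = 0.12, k = 0.39 mM, n = 2.0).
#'
#' @param A FRET efficiency at zero detergent.
#' @param B FRET efficiency at saturating detergent.
#' @param k Half-maximal concentration constant (mM).
#' @param n Hill coefficient.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(A = 0.43, B = 0.12, k = 0.39, n = 2.0) {
  if (A < 0 || A > 1 || B < 0 || B > 1) stop_invalid("`A`, `B` must lie in [0, 1]")
  check_positive(k, "k")
  check_positive(n, "n")
  structure(list(A = A, B = B, k = k, n = n), class = "hill_params")
}
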