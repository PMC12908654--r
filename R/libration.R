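#' Rigid water geometry
#'
#' @param r_oh_A O-H bond length, Angstrom (default 0.9572).
#' @param hoh_deg H-O-H angle, degrees (default 104.52).
#' @param mass_o,mass_h Masses, amu.
#' @return A `cw_water_geometry`.
#' @export
water_geometry <- function(r_oh_A = tip3p$r_oh_A, hoh_deg = tip3p$hoh_deg,
                           mass_o = tip3p$mass_o, mass_h = tip3p$mass_h) {
  if (r_oh_A <= 0) stop("r_oh must be > 0")
  if (hoh_deg <= 0 || hoh_deg > 180) stop("H-O-H angle must be in (0, 180]")
  structure(list(r_oh_A = r_oh_A, hoh_deg = hoh_deg,
                 mass_o = mass_o, mass_h = mass_h),
            class = "cw_water_geometry")
}

# Site coordinates (Angstrom) in the molecular frame, centre of mass at the
# origin: molecule in the xz-plane, bisector along +z (O below, H above).
water_sites <- function(geom) {
  half <- geom$hoh_deg / 2 * pi / 180
  o <- c(0, 0, 0)
  h1 <- geom$r_oh_A * c(sin(half), 0, cos(half))
  h2 <- geom$r_oh_A * c(-sin(half), 0, cos(half))
  m <- c(geom$mass_o, geom$mass_h, geom$mass_h)
  xyz <- rbind(o, h1, h2)
  com <- colSums(xyz * m) / sum(m)
  sweep(xyz, 2, com)
}

#' Principal moments of inertia of rigid water, by librational mode
#'
#' Computes the moment of inertia about each principal axis through the
#' centre of mass and assigns the three librational modes by their
#' rotation axes: *rock* about the normal to the molecular plane (in-plane
#' oscillation), *twist* about the H-O-H bisector (hydrogens move out of
#' plane in opposite directions), *wag* about the in-plane axis
#' perpendicular to the bisector (both hydrogens move out of plane
#' together). For a planar body the moments obey the perpendicular-axis
#' identity `I_rock = I_twist + I_wag`. A collinear geometry (angle 180)
#' makes the in-line moment zero; it is flagged with a warning.
#'
#' @param geom A `cw_water_geometry`.
#' @return A `cw_mode_inertia` data.frame: `mode`, `inertia_amuA2`,
#'   ordered rock, twist, wag (decreasing inertia for bent geometries).
#' @export
principal_inertias <- function(geom) {
  stopifnot(inherits(geom, "cw_water_geometry"))
  xyz <- water_sites(geom)
  m <- c(geom$mass_o, geom$mass_h, geom$mass_h)
  # molecule lies in xz: rock axis = y (plane normal), twist = z (bisector),
  # wag = x (in-plane, perpendicular to bisector); these are principal axes
  # by symmetry
  I_about <- function(axis) {
    d2 <- rowSums(xyz^2) - (xyz %*% axis)^2
    sum(m * d2)
  }
  out <- data.frame(
    mode = c("rock", "twist", "wag"),
    inertia_amuA2 = c(I_about(c(0, 1, 0)), I_about(c(0, 0, 1)),
                      I_about(c(1, 0, 0))),
    stringsAsFactors = FALSE)
  if (any(out$inertia_amuA2 < 1e-12))
    warning("collinear geometry: a principal moment is zero")
  class(out) <- c("cw_mode_inertia", "data.frame")
  out
}

#' Harmonic librational frequency from binding energy and inertia
#'
#' Inverts the harmonic-oscillator relation `E_b = (1/2) I (2 pi f)^2`:
#' `f = (1/2pi) sqrt(2 E_b / I)`, with `E_b` given per mole of molecules
#' (kcal/mol, converted to joules per molecule via Avogadro's number) and
#' `I` in amu Angstrom^2 (converted to kg m^2). Strictly increasing in
#' `E_b` and decreasing in `I`.
#'
#' @param E_b_kcal Binding (orientational well) energy, kcal/mol (> 0).
#' @param I_amuA2 Moment of inertia, amu Angstrom^2 (> 0).
#' @return Frequency in THz.
#' @export
harmonic_frequency <- function(E_b_kcal, I_amuA2) {
  if (any(E_b_kcal <= 0) || any(I_amuA2 <= 0))
    stop("E_b and I must be > 0")
  E_J <- E_b_kcal * cw_constants$kcal_to_kj * 1e3 / cw_constants$avogadro
  I_kg <- I_amuA2 * cw_constants$amu_A2_to_kg_m2
  sqrt(2 * E_J / I_kg) / (2 * pi) / 1e12
}

#' Librational mode table (inertia and harmonic frequency per mode)
#'
#' @param E_b_kcal Binding energy, kcal/mol (default 19).
#' @param geom A `cw_water_geometry` (default rigid TIP3P).
#' @return A `cw_mode_table` data.frame: `mode`, `inertia_amuA2`,
#'   `frequency_THz`, with the binding energy as attribute `E_b_kcal`.
#' @export
librational_table <- function(E_b_kcal = 19, geom = water_geometry()) {
  ino <- principal_inertias(geom)
  out <- data.frame(mode = ino$mode, inertia_amuA2 = ino$inertia_amuA2,
                    frequency_THz = harmonic_frequency(E_b_kcal,
                                                       ino$inertia_amuA2))
  attr(out, "E_b_kcal") <- E_b_kcal
  class(out) <- c("cw_mode_table", "data.frame")
  out
}

#' @export
print.cw_mode_table <- function(x, ...) {
  cat(sprintf("Librational modes of rigid water (E_b = %g kcal/mol)\n",
              attr(x, "E_b_kcal")))
  df <- data.frame(mode = x$mode,
                   `I (amu A^2)` = sprintf("%.4f", x$inertia_amuA2),
                   `f (THz)` = sprintf("%.1f", x$frequency_THz),
                   check.names = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Parameters of the 1-D driven damped librational rotor
#'
#' A deliberately minimal caricature of one librational mode: a single
#' angular coordinate with moment of inertia `I`, harmonic restoring
#' stiffness `k = 2 E_b` (so that the well depth at 1 rad amplitude equals
#' `E_b`, matching the harmonic mode model), viscous damping `gamma`, and
#' a torque `mu_c E0 cos(2 pi f t)` from the oscillating field. Internal
#' units: amu nm^2 / ps / kJ mol^-1 (1 kJ/mol = 1 amu nm^2 ps^-2), so the
#' natural frequency `sqrt(k/I)/2pi` comes out directly in THz.
#'
#' @param inertia_amuA2 Moment of inertia, amu Angstrom^2.
#' @param E_b_kcal Binding energy, kcal/mol.
#' @param damping Damping rate gamma, ps^-1. Default gives quality factor
#'   ~10 at the rock-mode natural frequency so the resonance is visible in
#'   tens of ps.
#' @param coupling Effective dipole coupling, kJ/mol per (V/nm).
#' @param field A `cw_field` (its amplitude scales the torque).
#' @return A `cw_rotor`.
#' @export
rotor_params <- function(inertia_amuA2 = 1.7709, E_b_kcal = 19,
                         damping = NULL, coupling = 1,
                         field = field_spec(amplitude_E0 = 0.4)) {
  I_nm <- inertia_amuA2 / 100  # amu A^2 -> amu nm^2
  k <- 2 * E_b_kcal * cw_constants$kcal_to_kj  # kJ/mol/rad^2
  omega0 <- sqrt(k / I_nm)     # rad/ps
  if (is.null(damping)) damping <- omega0 / 10
  if (damping < 0 || coupling < 0) stop("damping and coupling must be >= 0")
  structure(list(inertia_amuA2 = inertia_amuA2, I_nm = I_nm, k = k,
                 omega0 = omega0, f0_THz = omega0 / (2 * pi),
                 damping = damping, coupling = coupling, field = field),
            class = "cw_rotor")
}

#' @export
print.cw_rotor <- function(x, ...) {
  cat(sprintf("<cw_rotor> I = %.4f amu A^2, f0 = %.2f THz, gamma = %.3g ps^-1, Q = %.2f\n",
              x$inertia_amuA2, x$f0_THz, x$damping, x$omega0 / x$damping))
  invisible(x)
}

#' Simulate the driven damped rotor at one drive frequency
#'
#' Integrates `I theta'' = -k theta - I gamma theta' + M0 cos(2 pi f t)`
#' (with `M0 = coupling * E0`) from rest, discards the damping transient,
#' and reports the steady-state angular amplitude as `sqrt(2)` times the
#' RMS of the retained window (exact for a sinusoid). The time step must
#' resolve the drive with at least 20 steps per period.
#'
#' @param params A `cw_rotor`.
#' @param drive_frequency Drive frequency, THz.
#' @param duration Total simulated time, ps; should exceed several damping
#'   times (default `60 / gamma`).
#' @param dt Integration output step, ps (default resolves the faster of
#'   drive and natural frequency with 40 steps/period).
#' @return List with `amplitude_deg`, `time` (ps), `theta_deg`, and the
#'   closed-form linear-response amplitude `analytic_deg`.
#' @export
simulate_driven_rotor <- function(params, drive_frequency, duration = NULL,
                                  dt = NULL) {
  stopifnot(inherits(params, "cw_rotor"))
  om <- 2 * pi * drive_frequency
  fmax <- max(drive_frequency, params$f0_THz)
  if (is.null(dt)) dt <- 1 / (40 * fmax)
  if (drive_frequency > 0 && dt > 1 / (20 * drive_frequency))
    stop("dt under-resolves the drive: need >= 20 steps per period")
  if (is.null(duration)) duration <- 60 / params$damping
  M0 <- params$coupling * params$field$amplitude_E0
  I <- params$I_nm; k <- params$k; g <- params$damping
  deriv <- function(t, y, p) {
    list(c(y[2], (M0 * cos(om * t) - k * y[1]) / I - g * y[2]))
  }
  times <- seq(0, duration, by = dt)
  sol <- deSolve::ode(c(0, 0), times, deriv, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  keep <- sol[, 1] >= duration * 0.6
  th <- sol[keep, 2]
  amp <- sqrt(2 * mean(th^2)) * 180 / pi
  den <- sqrt((params$omega0^2 - om^2)^2 + (g * om)^2)
  analytic <- (M0 / I) / den * 180 / pi
  list(amplitude_deg = amp, time = sol[, 1], theta_deg = sol[, 2] * 180 / pi,
       analytic_deg = analytic)
}

#' Frequency sweep of the driven rotor
#'
#' @param params A `cw_rotor`.
#' @param frequencies Drive frequencies, THz (>= 3 values).
#' @param ... Passed to [simulate_driven_rotor()].
#' @return A `cw_sweep`: data.frame `freq_THz`, `amplitude_deg`,
#'   `analytic_deg`, with attribute `peak_THz` (drive frequency of maximal
#'   simulated amplitude, at the grid resolution).
#' @export
frequency_sweep <- function(params, frequencies, ...) {
  if (length(frequencies) < 1) stop("need at least one frequency")
  res <- lapply(sort(frequencies), function(f) {
    s <- simulate_driven_rotor(params, f, ...)
    data.frame(freq_THz = f, amplitude_deg = s$amplitude_deg,
               analytic_deg = s$analytic_deg)
  })
  out <- do.call(rbind, res)
  class(out) <- c("cw_sweep", "data.frame")
  attr(out, "peak_THz") <- out$freq_THz[which.max(out$amplitude_deg)]
  out
}

#' @export
print.cw_sweep <- function(x, ...) {
  cat(sprintf("<cw_sweep> %d frequencies, peak at %g THz\n",
              nrow(x), attr(x, "peak_THz")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}
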