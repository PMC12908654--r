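#' Physical constants and unit conventions
#'
#' Internal units are nm / ps / amu / elementary charge / kJ mol^-1
#' throughout. Readers convert on ingest (PDB and XYZ are Angstrom-based,
#' GRO is nm-based). The constants below are the fixed conversion factors
#' used everywhere in the package.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kcal_to_kj}{1 kcal in kJ (4.184).}
#'   \item{avogadro}{Avogadro constant, mol^-1.}
#'   \item{amu_A2_to_kg_m2}{1 amu Angstrom^2 in kg m^2.}
#'   \item{coulomb_kj_nm_e2}{Electric conversion factor
#'     \eqn{1/(4\pi\epsilon_0)} in kJ mol^-1 nm e^-2 (138.935458), so that
#'     two unit charges 1 nm apart interact with 138.935458 kJ/mol.}
#'   \item{A_per_nm}{Angstrom per nm (10).}
#' }
#' @export
cw_constants <- list(
  kcal_to_kj       = 4.184,
  avogadro         = 6.02214076e23,
  amu_A2_to_kg_m2  = 1.66053906660e-47,
  coulomb_kj_nm_e2 = 138.935458,
  A_per_nm         = 10
)

#' Rigid three-site (TIP3P) water geometry constants
#'
#' O-H bond length 0.9572 Angstrom, H-O-H angle 104.52 degrees, masses
#' 15.9994 / 1.008 amu and charges -0.834 / +0.417 e. These are the standard
#' rigid three-site water-model values used by the synthetic generators and
#' the librational-mode model.
#'
#' @seealso [water_geometry()]
#' @export
tip3p <- list(
  r_oh_A    = 0.9572,
  hoh_deg   = 104.52,
  mass_o    = 15.9994,
  mass_h    = 1.008,
  q_o       = -0.834,
  q_h       = 0.417,
  # CHARMM-family TIP3P oxygen LJ parameters (kJ/mol, nm); hydrogens 0/0
  eps_o     = 0.6364,
  sigma_o   = 0.31506
)
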