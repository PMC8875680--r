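# Material property containers and table I/O.

#' Mechanical/structural description of one aerogel material
#'
#' @param name text label.
#' @param Y Young's modulus, Pa (> 0).
#' @param rho bulk density, kg/m^3 (> 0).
#' @param phi mean pore diameter, m (> 0).
#' @param Y_err,phi_err measurement errors (Pa, m); optional.
#' @param porosity volume porosity in `[0, 1]`; optional.
#' @param scatter_xsec per-pore scattering cross-section, m^2; optional.
#' @return object of class `material_properties`.
#' @export
material_properties <- function(name, Y, rho, phi, Y_err = NA_real_,
                                phi_err = NA_real_, porosity = NA_real_,
                                scatter_xsec = NA_real_) {
  if (!is_scalar_num(Y) || Y <= 0)   abort_invalid("Y must be a positive scalar")
  if (!is_scalar_num(rho) || rho <= 0) abort_invalid("rho must be a positive scalar")
  if (!is_scalar_num(phi) || phi <= 0) abort_invalid("phi must be a positive scalar")
  if (!is.na(porosity) && (porosity < 0 || porosity > 1))
    abort_invalid("porosity must lie in [0, 1]")
  structure(list(name = as.character(name), Y = Y, Y_err = Y_err, rho = rho,
                 phi = phi, phi_err = phi_err, porosity = porosity,
                 scatter_xsec = scatter_xsec),
            class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("<material_properties> %s\n", x$name))
  cat(sprintf("  Y = %.4g Pa, rho = %.4g kg/m^3, phi = %.4g m\n",
              x$Y, x$rho, x$phi))
  if (!is.na(x$porosity)) cat(sprintf("  porosity = %.3f\n", x$porosity))
  invisible(x)
}

material_cols <- c("name", "Y_MPa", "Y_err_MPa", "rho_kg_m3",
                   "phi_um", "phi_err_um", "porosity")

#' Read a material property table
#'
#' CSV with header `name,Y_MPa,Y_err_MPa,rho_kg_m3,phi_um,phi_err_um,porosity`.
#'
#' @param path CSV file path.
#' @return data.frame with the columns above.
#' @export
read_material_table <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("material table not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(material_cols, names(tab))
  if (length(missing))
    abort_format(sprintf("material table is missing columns: %s",
                         paste(missing, collapse = ", ")))
  if (any(!is.finite(tab$Y_MPa)) || any(tab$Y_MPa <= 0) ||
      any(!is.finite(tab$rho_kg_m3)) || any(tab$rho_kg_m3 <= 0) ||
      any(!is.finite(tab$phi_um)) || any(tab$phi_um <= 0))
    abort_invalid("Y_MPa, rho_kg_m3 and phi_um must be positive")
  tab
}

#' Derive acoustic properties for a material table
#'
#' Adds speed of sound `v_m_s`, acoustic impedance `Z_Mrayl` and the tissue
#' impedance mismatch `mismatch_pct` (against `tissue_Z_Mrayl`, default
#' 1.6 Mrayl for soft tissue) to a material table. Impedance is computed in
#' rayl and reported in Mrayl.
#'
#' @param materials data.frame as returned by [read_material_table()].
#' @param tissue_Z_Mrayl reference tissue impedance, Mrayl.
#' @return the input data.frame with `v_m_s`, `Z_Mrayl`, `mismatch_pct` added.
#' @export
acoustic_property_table <- function(materials, tissue_Z_Mrayl = 1.6) {
  if (!is.data.frame(materials) || !all(c("Y_MPa", "rho_kg_m3") %in% names(materials)))
    abort_invalid("materials must be a data.frame with Y_MPa and rho_kg_m3")
  Y <- materials$Y_MPa * 1e6
  rho <- materials$rho_kg_m3
  v <- sound_speed(Y, rho)
  Z <- acoustic_impedance(Y, rho)
  materials$v_m_s <- v
  materials$Z_Mrayl <- Z / 1e6
  materials$mismatch_pct <- impedance_mismatch(tissue_Z_Mrayl * 1e6, Z)
  materials
}

#' Write an acoustic property table to CSV
#'
#' @param tab data.frame (normally from [acoustic_property_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_acoustic_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Bundled mechanical properties of eight reference aerogel formulations
#'
#' Young's modulus, bulk density and mean pore diameter for eight aerogel
#' types spanning 0.32-11.4 MPa and 0.04-5 um pore diameters: crosslinked
#' silica (plain and phosphor-doped), shape-memory polyurethane (two
#' formulations), carbon (acid- and base-catalyzed resorcinol-formaldehyde)
#' and crosslinked calcium alginate (two formulations).
#'
#' @return data.frame in the [read_material_table()] layout.
#' @export
aerogel_materials <- function() {
  read_material_table(system.file("extdata", "aerogel_materials.csv",
                                  package = "echogel", mustWork = TRUE))
}

#' Bundled reported acoustic measurements for the reference aerogels
#'
#' Sound speed, acoustic impedance and tissue impedance mismatch as
#' reported in the original ultrasound characterization of the eight
#' reference aerogels. Kept separate from [aerogel_materials()] because
#' the reported v/Z are measurement-derived and are not exactly
#' reproduced by `sqrt(Y/rho)` on the reported Y and rho (see the package
#' vignette); use these values when the reported numbers themselves are
#' the input.
#'
#' @return data.frame with columns `name`, `v_m_s`, `Z_Mrayl`, `mismatch_pct`.
#' @export
aerogel_reported_acoustics <- function() {
  utils::read.csv(system.file("extdata", "aerogel_reported_acoustics.csv",
                              package = "echogel", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Bundled reference attenuation coefficients at 8.5 MHz
#'
#' Mean attenuation (dB/cm) with standard errors for the eight reference
#' aerogels in three placements: aqueous bath (Aq), submuscular (SM) and
#' subcutaneous (SC), measured at a scan frequency of 8.5 MHz. These values
#' parameterize the default synthetic scenarios of [run_pipeline()]; they
#' are scenario inputs, not reproduction targets.
#'
#' @return data.frame with columns `name`, `alpha_Aq_db_cm`, `sem_Aq`,
#'   `alpha_SM_db_cm`, `sem_SM`, `alpha_SC_db_cm`, `sem_SC`.
#' @export
aerogel_attenuation_8p5MHz <- function() {
  utils::read.csv(system.file("extdata", "aerogel_attenuation_8p5MHz.csv",
                              package = "echogel", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
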