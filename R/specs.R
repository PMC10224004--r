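#' Solute specification
#'
#' Minimal description of a solute needed for concentration-scale
#' conversions: its name and molar mass.
#'
#' @param name Solute name.
#' @param molar_mass Molar mass in g/mol.
#' @return An object of class `solute_spec`.
#' @examples
#' solute_spec("iproniazid", 179.22)
#' @export
solute_spec <- function(name, molar_mass) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive_scalar(molar_mass, "molar_mass")
  structure(list(name = name, molar_mass = molar_mass), class = "solute_spec")
}

#' Solvent specification
#'
#' Name, molar mass and pure-solvent density used when converting molar
#' solubility to mole fraction. The density is held temperature-independent
#' over the narrow fitting interval; `density_reference_T` records the
#' temperature at which the tabulated value applies.
#'
#' @param name Solvent name.
#' @param molar_mass Molar mass in g/mol.
#' @param density Pure-solvent density in g/cm^3.
#' @param density_reference_T Temperature (K) of the density value.
#' @return An object of class `solvent_spec`.
#' @examples
#' solvent_spec("1-octanol", 130.23, 0.8262)
#' @export
solvent_spec <- function(name, molar_mass, density, density_reference_T = 298.2) {
  stopifnot(is.character(name), length(name) == 1L)
  check_positive_scalar(molar_mass, "molar_mass")
  check_positive_scalar(density, "density")
  check_positive_scalar(density_reference_T, "density_reference_T")
  structure(
    list(
      name = name, molar_mass = molar_mass, density = density,
      density_reference_T = density_reference_T
    ),
    class = "solvent_spec"
  )
}

#' Default solvent and solute specifications
#'
#' Literature pure-solvent densities at 298 K (1-octanol 0.8262 g/cm^3,
#' n-hexane 0.6548 g/cm^3) and molar masses for the three
#' pyridinecarboxamide compounds studied with them (iproniazid,
#' isoniazid, isonicotinamide). Every value can be overridden by building
#' a [solvent_spec()]/[solute_spec()] directly.
#'
#' @return A named list of `solvent_spec` (for `default_solvents()`) or
#'   `solute_spec` (for `default_solutes()`) objects.
#' @export
default_solvents <- function() {
  list(
    octanol = solvent_spec("1-octanol", 130.23, 0.8262),
    hexane = solvent_spec("n-hexane", 86.18, 0.6548)
  )
}

#' @rdname default_solvents
#' @export
default_solutes <- function() {
  list(
    IPN = solute_spec("iproniazid", 179.22),
    INZ = solute_spec("isoniazid", 137.14),
    iNAM = solute_spec("isonicotinamide", 122.12)
  )
}
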