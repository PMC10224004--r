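#' Reference dataset: pyridinecarboxamide solubility study
#'
#' Packaged plain-text copies of the published measurement tables for
#' iproniazid (IPN), isoniazid (INZ) and isonicotinamide (iNAM):
#' molar solubilities in 1-octanol and n-hexane (IPN at five temperatures
#' from 290.2 to 310.2 K, the others at 310.2 K), and apparent
#' distribution coefficients at 310.2 K in both two-phase systems,
#' without cyclodextrin and with HP-b-CD or M-b-CD at 0.0115, 0.025 and
#' 0.035 M in the aqueous phase. Hexane-system D values are on the
#' absolute scale (of order 1e-4).
#'
#' @return A tibble.
#' @examples
#' head(ipn_solubility_data())
#' @export
ipn_solubility_data <- function() {
  read_table(
    system.file("extdata", "ipn_solubility_molar.csv", package = "partperm"),
    "solubility"
  )
}

#' @rdname ipn_solubility_data
#' @export
ipn_distribution_data <- function() {
  path <- system.file("extdata", "ipn_distribution_310K.csv",
                      package = "partperm")
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

#' Reported van't Hoff coefficients for iproniazid
#'
#' The published coefficients of the line `ln X2 = A + B/T` for
#' iproniazid in each solvent, with their standard errors, as reported
#' alongside the thermodynamic summary (five temperatures each). These
#' are inputs for reproducing the published thermodynamic functions
#' without refitting.
#'
#' @return A tibble with columns `solvent`, `A`, `B`, `se_A`, `se_B`, `n`.
#' @export
ipn_vant_hoff_coefficients <- function() {
  tibble::tibble(
    solvent = c("octanol", "hexane"),
    A = c(5.79, 7.28),
    B = c(-2469, -4809),
    se_A = c(0.08, 0.35),
    se_B = c(23, 104),
    n = c(5L, 5L)
  )
}

#' Reported apparent permeabilities at 310.2 K
#'
#' Published apparent permeability coefficients through a biomimetic
#' phospholipid barrier (cm/s), used as generating truths for simulation
#' round trips (the underlying time courses are not published).
#'
#' @return A tibble with columns `solute`, `Papp`.
#' @export
reported_papp <- function() {
  tibble::tibble(
    solute = c("IPN", "INZ", "iNAM"),
    Papp = c(2.03e-5, 1.44e-5, 0.73e-5)
  )
}
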