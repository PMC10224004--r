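#' Temperature-indexed solubility series
#'
#' Container for the solubility of one solute in one solvent at several
#' temperatures. The `scale` attribute records whether the values are
#' molar solubilities (mol/L) or mole fractions; fitting requires the
#' mole-fraction scale (see [as_mole_fraction()]).
#'
#' @param solute_id,solvent_id Identifiers.
#' @param T Temperatures in kelvin.
#' @param S2 Solubilities (mol/L for `scale = "molar"`, dimensionless
#'   mole fractions for `scale = "mole_fraction"`).
#' @param sd Optional per-point uncertainties, same units as `S2`.
#' @param scale Concentration scale of `S2`.
#' @return An object of class `solubility_series` with a `points` tibble
#'   sorted by temperature.
#' @examples
#' solubility_series("IPN", "octanol",
#'   T = c(290.2, 298.2, 310.2), S2 = c(0.409, 0.506, 0.686)
#' )
#' @export
solubility_series <- function(solute_id, solvent_id, T, S2, sd = NULL,
                              scale = c("molar", "mole_fraction")) {
  scale <- match.arg(scale)
  if (length(T) != length(S2) || length(T) == 0L) {
    stop_partperm("`T` and `S2` must be non-empty and of equal length",
                  "partperm_domain_error")
  }
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop_partperm("all temperatures must be positive and finite",
                  "partperm_domain_error")
  }
  if (any(!is.finite(S2)) || any(S2 <= 0)) {
    stop_partperm("all solubilities must be positive and finite",
                  "partperm_domain_error")
  }
  if (scale == "mole_fraction" && any(S2 >= 1)) {
    stop_partperm("mole fractions must be < 1", "partperm_invalid_composition")
  }
  if (!is.null(sd) && (length(sd) != length(S2) || any(sd < 0, na.rm = TRUE))) {
    stop_partperm("`sd` must be non-negative and match `S2` in length",
                  "partperm_domain_error")
  }
  ord <- order(T)
  pts <- tibble::tibble(
    T = T[ord], S2 = S2[ord],
    sd = if (is.null(sd)) NA_real_ else sd[ord]
  )
  structure(
    list(solute_id = solute_id, solvent_id = solvent_id, points = pts),
    scale = scale, class = "solubility_series"
  )
}

#' @export
print.solubility_series <- function(x, ...) {
  cat(sprintf(
    "<solubility_series> %s in %s (%s scale), %d points\n",
    x$solute_id, x$solvent_id, attr(x, "scale"), nrow(x$points)
  ))
  print(x$points)
  invisible(x)
}

#' Convert molar solubility to mole fraction
#'
#' Converts a molar solubility (mol per litre of solution) to the solute
#' mole fraction using the solvent's pure density. Two algebraic variants
#' of the conversion are provided, differing in the sign of the
#' `S2 * (M1 - M2)` correction in the denominator:
#'
#' * `as_printed`: `X2 = M2*S2 / (S2*(M1 - M2) + 1000*rho)`
#' * `mass_balance`: `X2 = M2*S2 / (1000*rho - S2*(M1 - M2))`, the
#'   first-principles form obtained by counting solvent mass as the
#'   solution mass (density `rho`) minus the dissolved solute mass.
#'
#' For the dilute systems this package targets the two differ by a few
#' per cent at most; the default follows the published convention.
#'
#' @param S2 Molar solubility, mol/L. Vectorised.
#' @param solute A [solute_spec()] (molar mass `M1`).
#' @param solvent A [solvent_spec()] (molar mass `M2`, density `rho`).
#' @param mode Conversion variant, see Details.
#' @return Mole fraction(s) in (0, 1).
#' @examples
#' molar_to_mole_fraction(
#'   0.686, solute_spec("iproniazid", 179.22),
#'   solvent_spec("1-octanol", 130.23, 0.8262)
#' )
#' @export
molar_to_mole_fraction <- function(S2, solute, solvent,
                                   mode = c("as_printed", "mass_balance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(solute, "solute_spec"), inherits(solvent, "solvent_spec"))
  if (any(!is.finite(S2)) || any(S2 <= 0)) {
    stop_partperm("`S2` must be positive and finite", "partperm_domain_error")
  }
  M1 <- solute$molar_mass
  M2 <- solvent$molar_mass
  rho <- solvent$density
  denom <- switch(mode,
    as_printed = S2 * (M1 - M2) + 1000 * rho,
    mass_balance = 1000 * rho - S2 * (M1 - M2)
  )
  if (any(denom <= 0)) {
    stop_partperm("non-positive denominator in mole-fraction conversion",
                  "partperm_invalid_composition")
  }
  X2 <- M2 * S2 / denom
  if (any(X2 >= 1)) {
    stop_partperm("computed mole fraction >= 1; inputs are not a dilute solution",
                  "partperm_invalid_composition")
  }
  X2
}

#' Convert a molar solubility series to the mole-fraction scale
#'
#' @param series A `solubility_series` on the molar scale.
#' @inheritParams molar_to_mole_fraction
#' @return A `solubility_series` on the mole-fraction scale. Per-point
#'   uncertainties are rescaled by the local derivative dX2/dS2
#'   (first-order propagation).
#' @export
as_mole_fraction <- function(series, solute, solvent,
                             mode = c("as_printed", "mass_balance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "solubility_series"))
  if (attr(series, "scale") == "mole_fraction") {
    return(series)
  }
  S2 <- series$points$S2
  X2 <- molar_to_mole_fraction(S2, solute, solvent, mode)
  sd <- series$points$sd
  if (!all(is.na(sd))) {
    # numerical derivative for first-order uncertainty propagation
    h <- S2 * 1e-6
    dX <- (molar_to_mole_fraction(S2 + h, solute, solvent, mode) - X2) / h
    sd <- abs(dX) * sd
  }
  solubility_series(series$solute_id, series$solvent_id,
    T = series$points$T, S2 = X2,
    sd = if (all(is.na(sd))) NULL else sd,
    scale = "mole_fraction"
  )
}
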