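#' Single two-phase distribution measurement
#'
#' Equilibrium phase concentrations and phase volumes for one
#' organic/aqueous shake-flask system, optionally in the presence of a
#' cyclodextrin in the aqueous phase. Concentration of the solute may be
#' given for both phases (`C_org`, `C_aq`) or for the aqueous phase only
#' together with the pre-equilibration stock concentration (`C0_aq`),
#' from which the organic-phase amount follows by mass balance.
#'
#' @param system_id,solute_id Identifiers.
#' @param C_aq Equilibrium aqueous-phase concentration, mol/L.
#' @param C_org Equilibrium organic-phase concentration, mol/L (optional).
#' @param C0_aq Initial aqueous stock concentration, mol/L (optional).
#' @param V_org,V_aq Phase volumes, mL.
#' @param cd_name Cyclodextrin name, or `NULL` if absent.
#' @param cd_conc Cyclodextrin concentration in the aqueous phase, mol/L.
#' @return An object of class `distribution_measurement`.
#' @examples
#' distribution_measurement("octanol", "IPN",
#'   C_aq = 2e-3, C0_aq = 6e-3, V_org = 3, V_aq = 3
#' )
#' @export
distribution_measurement <- function(system_id, solute_id, C_aq,
                                     C_org = NULL, C0_aq = NULL,
                                     V_org, V_aq,
                                     cd_name = NULL, cd_conc = 0) {
  check_positive_scalar(V_org, "V_org")
  check_positive_scalar(V_aq, "V_aq")
  if (!is.numeric(C_aq) || C_aq < 0) {
    stop_partperm("`C_aq` must be non-negative", "partperm_domain_error")
  }
  if (is.null(C_org) && is.null(C0_aq)) {
    stop_partperm("at least one of `C_org` or `C0_aq` is required",
                  "partperm_domain_error")
  }
  if (cd_conc < 0) {
    stop_partperm("`cd_conc` must be >= 0", "partperm_domain_error")
  }
  structure(
    list(
      system_id = system_id, solute_id = solute_id,
      C_org = C_org, C_aq = C_aq, C0_aq = C0_aq,
      V_org = V_org, V_aq = V_aq,
      cd_name = cd_name, cd_conc = cd_conc
    ),
    class = "distribution_measurement"
  )
}

#' Apparent distribution coefficient
#'
#' Computes the apparent distribution coefficient `D` of a solute between
#' an organic phase and an aqueous buffer, and its base-10 logarithm.
#' Two computation modes are supported:
#'
#' * `mass_balance` (default): the organic-phase amount is inferred by
#'   conservation from the assayed aqueous phase,
#'   `D = ((C0_aq - C_aq) * V_aq) / (C_aq * V_org)`. This matches
#'   shake-flask practice where only one phase is assayed and is the
#'   volume-bearing reading of the published working equation.
#' * `direct_ratio`: both phases assayed, `D = C_org / C_aq`.
#'
#' No ionization correction is applied: for solutes un-ionized at the
#' working pH the apparent D coincides with the partition coefficient.
#'
#' @param m A [distribution_measurement()].
#' @param mode Computation mode, see Details.
#' @return An object of class `distribution_result` with fields `D`,
#'   `logD` and `mode_used`.
#' @examples
#' m <- distribution_measurement("octanol", "IPN",
#'   C_aq = 2e-3, C0_aq = 6e-3, V_org = 3, V_aq = 3
#' )
#' apparent_distribution(m) # D = 2
#' @export
apparent_distribution <- function(m, mode = c("mass_balance", "direct_ratio")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "distribution_measurement"))
  if (m$C_aq <= 0) {
    stop_partperm("`C_aq` must be > 0 to form a distribution coefficient",
                  "partperm_division_error")
  }
  D <- switch(mode,
    direct_ratio = {
      if (is.null(m$C_org) || m$C_org <= 0) {
        stop_partperm("direct_ratio mode requires positive `C_org`",
                      "partperm_domain_error")
      }
      m$C_org / m$C_aq
    },
    mass_balance = {
      if (is.null(m$C0_aq)) {
        stop_partperm("mass_balance mode requires `C0_aq`",
                      "partperm_domain_error")
      }
      if (m$C0_aq <= m$C_aq) {
        stop_partperm("`C0_aq` must exceed `C_aq`: no solute left the aqueous phase",
                      "partperm_negative_partition")
      }
      ((m$C0_aq - m$C_aq) * m$V_aq) / (m$C_aq * m$V_org)
    }
  )
  structure(
    list(D = D, logD = log10(D), mode_used = mode),
    class = "distribution_result"
  )
}

#' @export
print.distribution_result <- function(x, ...) {
  cat(sprintf("<distribution_result> D = %.4g (logD = %.3f), mode = %s\n",
              x$D, x$logD, x$mode_used))
  invisible(x)
}

#' Hydrogen-bonding parameter delta-logD
#'
#' Difference between a solute's distribution coefficients (base-10 logs)
#' in the 1-octanol/buffer and alkane/buffer systems,
#' `delta_logD = logD_oct - logD_hex`. Because the alkane partitions only
#' by non-specific forces while 1-octanol can also hydrogen-bond, the
#' difference indexes the solute's hydrogen-bonding capacity.
#'
#' @param logD_oct logD in the 1-octanol/buffer system.
#' @param logD_hex logD in the alkane (n-hexane)/buffer system.
#' @return `logD_oct - logD_hex` (dimensionless). Vectorised.
#' @examples
#' delta_logD(0.423, -2.907) # 3.33
#' @export
delta_logD <- function(logD_oct, logD_hex) {
  if (any(!is.finite(logD_oct)) || any(!is.finite(logD_hex))) {
    stop_partperm("both logD values must be finite", "partperm_domain_error")
  }
  logD_oct - logD_hex
}

#' Aggregate replicate distribution coefficients
#'
#' Arithmetic mean and sample standard deviation over replicate D values,
#' as conventionally reported for shake-flask experiments.
#'
#' @param D Numeric vector of replicate distribution coefficients.
#' @return A list with `D` (mean), `sd` (NA for a single replicate) and
#'   `n`.
#' @export
aggregate_replicates <- function(D) {
  if (length(D) == 0L || any(!is.finite(D)) || any(D <= 0)) {
    stop_partperm("`D` must be a non-empty vector of positive values",
                  "partperm_domain_error")
  }
  list(D = mean(D), sd = if (length(D) > 1L) stats::sd(D) else NA_real_,
       n = length(D))
}
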