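#' Construct a van't Hoff fit from known coefficients
#'
#' Builds a `vant_hoff_fit` object directly from the coefficients of the
#' line `ln X2 = A + B/T`, e.g. when the coefficients are taken from a
#' published table rather than refitted from raw solubilities.
#'
#' @param A Dimensionless intercept.
#' @param B Slope of `ln X2` versus `1/T`, in kelvin (signed).
#' @param se_A,se_B Optional standard errors.
#' @param r Optional correlation coefficient of the underlying fit.
#' @param rss Optional residual sum of squares.
#' @param n Number of points behind the coefficients (>= 2).
#' @param label Optional label (e.g. the solvent).
#' @return An object of class `vant_hoff_fit`.
#' @examples
#' vant_hoff_fit(5.79, -2469, label = "1-octanol")
#' @export
vant_hoff_fit <- function(A, B, se_A = NA_real_, se_B = NA_real_,
                          r = NA_real_, rss = NA_real_, n = 2L,
                          label = NULL) {
  stopifnot(is.numeric(A), is.numeric(B), length(A) == 1L, length(B) == 1L)
  if (n < 2L) {
    stop_partperm("a van't Hoff fit needs at least 2 points",
                  "partperm_insufficient_data")
  }
  if (!is.na(r) && abs(r) > 1 + 1e-12) {
    stop_partperm("|r| must be <= 1", "partperm_domain_error")
  }
  if (!is.na(rss) && rss < 0) {
    stop_partperm("rss must be >= 0", "partperm_domain_error")
  }
  structure(
    list(
      A = A, B = B, se_A = se_A, se_B = se_B, cov_AB = NA_real_,
      r = r, rss = rss, n = as.integer(n), label = label
    ),
    class = "vant_hoff_fit"
  )
}

#' Fit the van't Hoff solubility line
#'
#' Ordinary least squares of `ln X2` on `1/T`, giving the line
#' `ln X2 = A + B/T`. The slope carries the apparent dissolution enthalpy
#' (`dH = -R*B`) and the line evaluated at a temperature gives the
#' dissolution Gibbs energy (see [gibbs_at()]).
#'
#' The regression is unweighted: the published per-line summary (single
#' correlation coefficient and residual scatter) corresponds to an
#' unweighted fit, and per-point uncertainties are rarely available on
#' the mole-fraction scale.
#'
#' @param series A `solubility_series` on the mole-fraction scale, or any
#'   list/data frame with components `T` (kelvin) and `S2`/`X2`
#'   (mole fraction).
#' @return A `vant_hoff_fit` with components `A`, `B`, `se_A`, `se_B`,
#'   `cov_AB`, `r` (correlation of `ln X2` with `1/T`, signed), `rss`, `n`.
#' @examples
#' s <- simulate_solubility_series(5.79, -2469,
#'   temps = c(290.2, 293.2, 298.2, 303.2, 310.2)
#' )
#' fit_vant_hoff(s)
#' @export
fit_vant_hoff <- function(series) {
  if (inherits(series, "solubility_series")) {
    if (attr(series, "scale") != "mole_fraction") {
      stop_partperm(
        "series must be on the mole-fraction scale; see as_mole_fraction()",
        "partperm_domain_error"
      )
    }
    T <- series$points$T
    X2 <- series$points$S2
    label <- series$solvent_id
  } else {
    T <- series$T
    X2 <- if (!is.null(series$X2)) series$X2 else series$S2
    label <- NULL
  }
  if (length(T) < 2L) {
    stop_partperm("at least 2 points are required", "partperm_insufficient_data")
  }
  if (length(unique(T)) < 2L) {
    stop_partperm("all temperatures identical: degenerate design",
                  "partperm_degenerate_design")
  }
  y <- log(X2)
  invT <- 1 / T
  m <- stats::lm(y ~ invT)
  cf <- stats::coef(m)
  # suppress the "essentially perfect fit" chatter on noiseless series
  vc <- suppressWarnings(stats::vcov(m))
  se <- sqrt(diag(vc))
  fit <- vant_hoff_fit(
    A = unname(cf[1]), B = unname(cf[2]),
    se_A = unname(se[1]), se_B = unname(se[2]),
    r = stats::cor(invT, y),
    rss = sum(stats::resid(m)^2),
    n = length(T), label = label
  )
  fit$cov_AB <- vc[1, 2]
  fit
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "<vant_hoff_fit>%s ln X2 = %.4g %s %.4g/T  (n = %d%s)\n",
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    x$A, ifelse(x$B < 0, "-", "+"), abs(x$B), x$n,
    if (is.na(x$r)) "" else sprintf(", |r| = %.4f", abs(x$r))
  ))
  invisible(x)
}

#' Apparent dissolution enthalpy from a van't Hoff fit
#'
#' `dH = -R * B` with `R = 8.314` J/(mol K); treated as
#' temperature-independent over the fitted interval (linear van't Hoff
#' behaviour, no heat-capacity term).
#'
#' @param fit A `vant_hoff_fit`.
#' @return Enthalpy in J/mol.
#' @export
enthalpy_from_fit <- function(fit) {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  -GAS_CONSTANT * fit$B
}

#' Dissolution Gibbs energy at a temperature
#'
#' `dG(T) = -R*T*(A + B/T) = -R*T*ln X2(T)`, the ideal-solution Gibbs
#' energy of dissolution evaluated from the fitted line.
#'
#' @param fit A `vant_hoff_fit`.
#' @param T Temperature in kelvin.
#' @return Gibbs energy in J/mol.
#' @export
gibbs_at <- function(fit, T) {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  check_positive_scalar(T, "T")
  -GAS_CONSTANT * T * (fit$A + fit$B / T)
}

thermo_functions_obj <- function(T, dG, dH, TdS, se_dG, se_dH, se_TdS, label) {
  if (dH == 0 && TdS == 0) {
    stop_partperm("dH and TdS both zero: enthalpy fraction undefined",
                  "partperm_degenerate")
  }
  zeta <- abs(dH) / (abs(dH) + abs(TdS)) * 100
  structure(
    list(
      T = T, dG = dG, dH = dH, TdS = TdS, zeta_H = zeta,
      se_dG = se_dG, se_dH = se_dH, se_TdS = se_TdS, label = label
    ),
    class = "thermo_functions"
  )
}

#' Dissolution thermodynamic functions at a temperature
#'
#' Computes `dG`, `dH`, `TdS` (all J/mol) and the enthalpy fraction
#' `zeta_H = |dH| / (|dH| + |TdS|) * 100` (%) from a van't Hoff fit.
#' `TdS = dH - dG` so the Gibbs identity holds exactly; algebraically
#' `TdS = R*T*A`. Standard errors are first-order propagations of the fit
#' standard errors (`se_dH = R*se_B`, `se_TdS = R*T*se_A`, `se_dG` uses
#' the full coefficient covariance when available).
#'
#' @param fit A `vant_hoff_fit`.
#' @param T Temperature in kelvin.
#' @return An object of class `thermo_functions` with fields `T`, `dG`,
#'   `dH`, `TdS`, `zeta_H`, and `se_*` counterparts.
#' @examples
#' thermo_functions(vant_hoff_fit(5.79, -2469), 298.2)
#' @export
thermo_functions <- function(fit, T) {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  check_positive_scalar(T, "T")
  dG <- gibbs_at(fit, T)
  dH <- enthalpy_from_fit(fit)
  TdS <- dH - dG
  varA <- fit$se_A^2
  varB <- fit$se_B^2
  covAB <- if (is.na(fit$cov_AB)) 0 else fit$cov_AB
  se_dG <- GAS_CONSTANT * sqrt(T^2 * varA + varB + 2 * T * covAB)
  thermo_functions_obj(
    T = T, dG = dG, dH = dH, TdS = TdS,
    se_dG = se_dG, se_dH = GAS_CONSTANT * fit$se_B,
    se_TdS = GAS_CONSTANT * T * fit$se_A,
    label = fit$label
  )
}

#' Transfer thermodynamic functions between two solvents
#'
#' Thermodynamic functions of the hypothetical transfer of the solute
#' from the `from` solvent to the `to` solvent, computed component-wise
#' as destination minus source dissolution functions at the same
#' temperature. The enthalpy fraction `zeta_H` is recomputed from the
#' transfer `dH` and `TdS`. Transfer functions are antisymmetric under
#' exchange of the two solvents (except `zeta_H`, which is symmetric).
#'
#' @param from_fit,to_fit `vant_hoff_fit` objects for the source and
#'   destination solvents.
#' @param T Temperature in kelvin.
#' @return A `thermo_functions` object for the transfer process.
#' @examples
#' hex <- vant_hoff_fit(7.28, -4809, label = "n-hexane")
#' oct <- vant_hoff_fit(5.79, -2469, label = "1-octanol")
#' transfer_functions(hex, oct, 298.2)
#' @export
transfer_functions <- function(from_fit, to_fit, T) {
  a <- thermo_functions(from_fit, T)
  b <- thermo_functions(to_fit, T)
  comb <- function(x, y) if (is.na(x) || is.na(y)) NA_real_ else sqrt(x^2 + y^2)
  thermo_functions_obj(
    T = T,
    dG = b$dG - a$dG, dH = b$dH - a$dH, TdS = b$TdS - a$TdS,
    se_dG = comb(a$se_dG, b$se_dG),
    se_dH = comb(a$se_dH, b$se_dH),
    se_TdS = comb(a$se_TdS, b$se_TdS),
    label = paste(from_fit$label %||% "from", "->", to_fit$label %||% "to")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.thermo_functions <- function(x, ...) {
  cat(sprintf(
    "<thermo_functions>%s at %.1f K (kJ/mol): dG = %.1f, dH = %.1f, TdS = %.1f, zeta_H = %.1f%%\n",
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    x$T, x$dG / 1000, x$dH / 1000, x$TdS / 1000, x$zeta_H
  ))
  invisible(x)
}
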