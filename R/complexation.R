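#' Cyclodextrin suppression series
#'
#' Distribution coefficients of a solute measured at several cyclodextrin
#' concentrations in the aqueous phase, together with the cyclodextrin-free
#' reference value `D0`. Suppression of `D` with increasing host
#' concentration carries the drug-cyclodextrin association constant
#' (phase-distribution method).
#'
#' Points with `D >= D0` (no suppression) are retained in the container
#' but cannot enter the logarithmic transform; a warning is raised.
#' Non-monotone suppression (D not strictly decreasing with host
#' concentration) is flagged with a warning, not an error, since it can
#' arise from measurement noise.
#'
#' @param system_id,cd_name Identifiers (two-phase system, cyclodextrin).
#' @param D0 Distribution coefficient without cyclodextrin (> 0).
#' @param C_CD Cyclodextrin concentrations, mol/L (> 0).
#' @param D Distribution coefficients at each `C_CD` (> 0).
#' @return An object of class `cd_suppression_series`.
#' @examples
#' cd_suppression_series("octanol", "HP-b-CD",
#'   D0 = 2.651,
#'   C_CD = c(0.0115, 0.025, 0.035), D = c(2.413, 2.138, 1.922)
#' )
#' @export
cd_suppression_series <- function(system_id, cd_name, D0, C_CD, D) {
  check_positive_scalar(D0, "D0")
  if (length(C_CD) != length(D) || length(D) == 0L) {
    stop_partperm("`C_CD` and `D` must be non-empty and of equal length",
                  "partperm_domain_error")
  }
  if (any(!is.finite(C_CD)) || any(C_CD <= 0)) {
    stop_partperm("all `C_CD` must be positive", "partperm_domain_error")
  }
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop_partperm("all `D` must be positive", "partperm_domain_error")
  }
  ord <- order(C_CD)
  C_CD <- C_CD[ord]
  D <- D[ord]
  if (any(D >= D0)) {
    warn_partperm(
      "some points show no suppression (D >= D0); they are excluded from the log transform",
      "partperm_non_suppressed"
    )
  }
  if (is.unsorted(rev(D), strictly = TRUE) && length(D) > 1L) {
    warn_partperm("D is not strictly decreasing with C_CD",
                  "partperm_non_monotone")
  }
  structure(
    list(system_id = system_id, cd_name = cd_name, D0 = D0,
         points = tibble::tibble(C_CD = C_CD, D = D)),
    class = "cd_suppression_series"
  )
}

#' Log-log linearization of one suppression point
#'
#' Transforms a suppression measurement to the coordinates of the
#' phase-distribution linearization
#' `log10((D0 - D)/D0) = log10(K_C) + alpha * log10(C_CD)`:
#' returns `y = log10((D0 - D)/D0)` and `x = log10(C_CD)`. Base-10
#' logarithms throughout (the van't Hoff module, by contrast, uses
#' natural logs; the two conventions are deliberate and kept separate).
#'
#' @param D0 Distribution coefficient without cyclodextrin.
#' @param D Distribution coefficient at cyclodextrin concentration `C_CD`.
#' @param C_CD Cyclodextrin concentration, mol/L.
#' @return Named numeric vector `c(x = ..., y = ...)`.
#' @examples
#' linearized_point(2.651, 2.413, 0.0115)
#' @export
linearized_point <- function(D0, D, C_CD) {
  check_positive_scalar(D0, "D0")
  check_positive_scalar(C_CD, "C_CD")
  if (!is.numeric(D) || length(D) != 1L || D <= 0 || D >= D0) {
    stop_partperm(
      "point is outside the transform domain: requires 0 < D < D0 (strict suppression)",
      "partperm_non_suppressed_point"
    )
  }
  c(x = log10(C_CD), y = log10((D0 - D) / D0))
}

#' Association constant by the linearized phase-distribution method
#'
#' Unweighted OLS of `y = log10((D0 - D)/D0)` on `x = log10(C_CD)`. The
#' intercept estimates `log10(K_C)` and the slope `alpha` the complex
#' stoichiometry exponent (`alpha` near 1 indicates a 1:1 complex). Both
#' the intercept and its antilog `10^intercept` are reported, since
#' published tables sometimes list the intercept itself under the name of
#' the association constant.
#'
#' The Fisher criterion is `F = R^2 * (n - 2) / (1 - R^2)` for the simple
#' regression; on an exact fit (`rss = 0`) it is `Inf`. With only three
#' host concentrations both `R` and `F` are hypersensitive to input
#' rounding and should be read as diagnostics, not estimates.
#'
#' @param series A [cd_suppression_series()]. Points with `D >= D0` are
#'   dropped before fitting.
#' @return An object of class `kc_fit` with fields `intercept`,
#'   `Kc_antilog`, `alpha`, `se_intercept`, `se_alpha`, `R`, `rss`, `F`,
#'   `n`.
#' @examples
#' s <- cd_suppression_series("octanol", "HP-b-CD",
#'   D0 = 2.651,
#'   C_CD = c(0.0115, 0.025, 0.035), D = c(2.413, 2.138, 1.922)
#' )
#' fit_kc(s)
#' @export
fit_kc <- function(series) {
  stopifnot(inherits(series, "cd_suppression_series"))
  keep <- series$points$D < series$D0
  pts <- series$points[keep, ]
  if (nrow(pts) < 2L) {
    stop_partperm("fewer than 2 suppressed points: cannot fit the linearization",
                  "partperm_insufficient_data")
  }
  x <- log10(pts$C_CD)
  y <- log10((series$D0 - pts$D) / series$D0)
  m <- stats::lm(y ~ x)
  cf <- stats::coef(m)
  se <- sqrt(diag(suppressWarnings(stats::vcov(m))))
  rss <- sum(stats::resid(m)^2)
  R <- stats::cor(x, y)
  n <- length(x)
  tss <- sum((y - mean(y))^2)
  Fstat <- if (rss <= 1e-14 * tss) Inf else R^2 / (1 - R^2) * (n - 2)
  structure(
    list(
      intercept = unname(cf[1]), Kc_antilog = 10^unname(cf[1]),
      alpha = unname(cf[2]),
      se_intercept = unname(se[1]), se_alpha = unname(se[2]),
      R = R, rss = rss, F = Fstat, n = n,
      system_id = series$system_id, cd_name = series$cd_name
    ),
    class = "kc_fit"
  )
}

#' @export
print.kc_fit <- function(x, ...) {
  cat(sprintf(
    "<kc_fit> %s / %s: log10(Kc) = %.3f +/- %.3f (Kc = %.3g), alpha = %.3f +/- %.3f, R = %.4f, n = %d\n",
    x$system_id, x$cd_name, x$intercept, x$se_intercept, x$Kc_antilog,
    x$alpha, x$se_alpha, x$R, x$n
  ))
  invisible(x)
}

#' Association constant by exact 1:1 nonlinear least squares
#'
#' Fits the exact 1:1 complexation-suppressed partition model
#' `D(C) = D0 / (1 + K_C * C_CD)` by least squares over `K_C >= 0`,
#' serving as the independent oracle for the linearized estimator: in the
#' small-saturation limit (`K_C * C_CD << 1`) the linearization's slope
#' tends to 1 and its intercept to `log10(K_C)`.
#'
#' @param series A [cd_suppression_series()].
#' @return A list with `Kc` (per mol) and `rss`. If no point shows
#'   suppression the boundary `Kc = 0` is returned with a warning.
#' @examples
#' s <- simulate_cd_suppression(2.651, 10, c(0.0115, 0.025, 0.035))
#' fit_kc_nonlinear(s)
#' @export
fit_kc_nonlinear <- function(series) {
  stopifnot(inherits(series, "cd_suppression_series"))
  C <- series$points$C_CD
  D <- series$points$D
  D0 <- series$D0
  ss <- function(K) sum((D - D0 / (1 + K * C))^2)
  if (all(D >= D0)) {
    warn_partperm("no suppression in any point; returning Kc = 0 boundary",
                  "partperm_no_suppression")
    return(list(Kc = 0, rss = ss(0)))
  }
  # bracket: the most-suppressed point sets the scale of K
  K_hi <- 10 * max((D0 / pmin(D, D0 - .Machine$double.eps * D0) - 1) / C)
  K_hi <- max(K_hi, 1)
  opt <- stats::optimize(ss, interval = c(0, K_hi), tol = 1e-10 * K_hi)
  Kc <- opt$minimum
  if (ss(0) <= opt$objective) {
    Kc <- 0
  }
  list(Kc = Kc, rss = ss(Kc))
}
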