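#' Summarise dissolution thermodynamics across solvents
#'
#' Builds the conventional thermodynamic summary table — fit
#' coefficients, `dG` and `TdS` at each requested temperature, `dH` and
#' the enthalpy fraction — from a named list of van't Hoff fits. Energies
#' are reported in kJ/mol.
#'
#' @param fits Named list of `vant_hoff_fit` objects (names = solvents).
#' @param temps Temperatures (K) at which to evaluate `dG` and `TdS`.
#' @return A tibble with one row per solvent.
#' @examples
#' thermo_summary(list(
#'   octanol = vant_hoff_fit(5.79, -2469),
#'   hexane = vant_hoff_fit(7.28, -4809)
#' ))
#' @export
thermo_summary <- function(fits, temps = c(298.2, 310.2)) {
  stopifnot(length(fits) > 0, !is.null(names(fits)))
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    row <- tibble::tibble(
      solvent = nm, A = fit$A, B = fit$B,
      se_A = fit$se_A, se_B = fit$se_B,
      dH_kJ = enthalpy_from_fit(fit) / 1000
    )
    for (T in temps) {
      tf <- thermo_functions(fit, T)
      row[[sprintf("dG_%g_kJ", T)]] <- tf$dG / 1000
      row[[sprintf("TdS_%g_kJ", T)]] <- tf$TdS / 1000
      row[[sprintf("zeta_H_%g", T)]] <- tf$zeta_H
    }
    row
  })
  do.call(rbind, rows)
}

#' Assemble a transport-property report
#'
#' Collects the results of the four analysis stages into one structured
#' document mirroring the conventional reporting tables: dissolution
#' thermodynamics per solvent, distribution coefficients with delta-logD,
#' cyclodextrin association fits, and apparent permeabilities. At least
#' one block must be supplied. Each block keeps a provenance field naming
#' the operation that produced it.
#'
#' @param thermo A tibble from [thermo_summary()], or `NULL`.
#' @param distribution A tibble with at least `system`, `solute`, `D`,
#'   `logD` columns, or `NULL`.
#' @param complexation A list of `kc_fit` objects, or `NULL`.
#' @param permeability A list of `permeability_result` objects, or `NULL`.
#' @return An object of class `transport_report`: a list of tibbles, one
#'   per supplied block.
#' @export
transport_report <- function(thermo = NULL, distribution = NULL,
                             complexation = NULL, permeability = NULL) {
  blocks <- list()
  if (!is.null(thermo)) {
    attr(thermo, "provenance") <- "thermo_summary"
    blocks$thermo <- thermo
  }
  if (!is.null(distribution)) {
    stopifnot(all(c("system", "solute", "D", "logD") %in% names(distribution)))
    attr(distribution, "provenance") <- "apparent_distribution"
    blocks$distribution <- distribution
  }
  if (!is.null(complexation)) {
    tbl <- do.call(rbind, lapply(complexation, function(f) {
      tibble::tibble(
        system = f$system_id, cd_name = f$cd_name,
        intercept = f$intercept, Kc_antilog = f$Kc_antilog,
        alpha = f$alpha, se_intercept = f$se_intercept,
        se_alpha = f$se_alpha, R = f$R, rss = f$rss, F = f$F, n = f$n
      )
    }))
    attr(tbl, "provenance") <- "fit_kc"
    blocks$complexation <- tbl
  }
  if (!is.null(permeability)) {
    tbl <- do.call(rbind, lapply(permeability, function(p) {
      tibble::tibble(
        solute = p$solute_id, J = p$J, Papp = p$Papp,
        Papp_1e5 = round(p$Papp * 1e5, 2), fit_r = p$fit_r,
        sink_ok = p$sink_ok, method = p$method
      )
    }))
    attr(tbl, "provenance") <- "estimate_papp"
    blocks$permeability <- tbl
  }
  if (length(blocks) == 0L) {
    stop_partperm("no results supplied: nothing to report",
                  "partperm_empty_input")
  }
  structure(blocks, class = "transport_report")
}

#' @export
print.transport_report <- function(x, ...) {
  cat(sprintf("<transport_report> blocks: %s\n",
              paste(names(x), collapse = ", ")))
  for (nm in names(x)) {
    cat("\n--", nm, "--\n")
    print(x[[nm]])
  }
  invisible(x)
}

#' Write a transport report to disk
#'
#' One CSV per block plus a combined JSON document carrying every block
#' and its provenance field.
#'
#' @param report A [transport_report()].
#' @param dir Output directory (created if needed).
#' @param digits Rounding applied to the JSON copy (CSV keeps full
#'   precision).
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(report, dir, digits = 6) {
  stopifnot(inherits(report, "transport_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  json <- list()
  for (nm in names(report)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table(report[[nm]], p)
    paths <- c(paths, p)
    block <- as.data.frame(report[[nm]])
    num <- vapply(block, is.numeric, logical(1))
    block[num] <- lapply(block[num], function(v) round(v, digits))
    json[[nm]] <- list(provenance = attr(report[[nm]], "provenance"),
                       rows = block)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(paths, jp))
}
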