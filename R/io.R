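# CSV schemas: required columns and their types, one entry per input kind.
pp_schemas <- list(
  solubility = list(
    required = c(solute = "character", solvent = "character",
                 T_K = "numeric", S2_mol_per_L = "numeric"),
    optional = c(sd = "numeric")
  ),
  distribution = list(
    required = c(system = "character", solute = "character",
                 C_aq = "numeric", V_org_mL = "numeric", V_aq_mL = "numeric"),
    optional = c(C0_aq = "numeric", C_org = "numeric",
                 cd_name = "character", cd_conc_M = "numeric")
  ),
  suppression = list(
    required = c(system = "character", cd_name = "character",
                 C_CD_M = "numeric", D = "numeric"),
    optional = c(sd = "numeric")
  ),
  permeation = list(
    required = c(solute = "character", t_min = "numeric",
                 C_acceptor_M = "numeric"),
    optional = character()
  )
)

#' Read a typed input table
#'
#' Reads one of the package's CSV input schemas with validation: the
#' header must contain the schema's required columns and every cell in a
#' numeric column must parse as a number. Violations raise a schema error
#' naming the offending column (and row where applicable). Comma
#' delimiter, UTF-8, decimal point.
#'
#' Schemas:
#' * `solubility`: `solute,solvent,T_K,S2_mol_per_L[,sd]`
#' * `distribution`: `system,solute,C_aq,V_org_mL,V_aq_mL[,C0_aq,C_org,cd_name,cd_conc_M]`
#' * `suppression`: `system,cd_name,C_CD_M,D[,sd]`
#' * `permeation`: `solute,t_min,C_acceptor_M`
#'
#' @param path File path.
#' @param schema_id One of `"solubility"`, `"distribution"`,
#'   `"suppression"`, `"permeation"`.
#' @return A tibble with validated, typed columns and a `row` column
#'   holding source row numbers for error reporting downstream.
#' @export
read_table <- function(path, schema_id = names(pp_schemas)) {
  schema_id <- match.arg(schema_id)
  schema <- pp_schemas[[schema_id]]
  if (!file.exists(path)) {
    stop_partperm(sprintf("file not found: %s", path), "partperm_schema_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) {
      stop_partperm(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                    "partperm_schema_error")
    }
  )
  if (nrow(raw) == 0L) {
    stop_partperm(sprintf("empty input: %s", path), "partperm_empty_input")
  }
  missing_cols <- setdiff(names(schema$required), names(raw))
  if (length(missing_cols) > 0L) {
    stop_partperm(
      sprintf("missing required column(s) in %s: %s", path,
              paste(missing_cols, collapse = ", ")),
      "partperm_schema_error"
    )
  }
  types <- c(schema$required, schema$optional)
  keep <- intersect(names(types), names(raw))
  out <- raw[keep]
  for (col in keep) {
    if (types[[col]] == "numeric") {
      vals <- out[[col]]
      blank <- is.na(vals) | trimws(vals) == ""
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(!blank & is.na(parsed))
      if (length(bad) > 0L) {
        stop_partperm(
          sprintf("non-numeric value in column `%s`, row %d of %s: \"%s\"",
                  col, bad[1], path, vals[bad[1]]),
          "partperm_schema_error"
        )
      }
      out[[col]] <- parsed
    }
  }
  out <- tibble::as_tibble(out)
  out$row <- seq_len(nrow(out))
  out
}

#' Write a table to CSV
#'
#' Comma-delimited UTF-8 with a header, no row names; the inverse of
#' [read_table()] for all schemas (a write/read round trip is
#' value-identical).
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  df$row <- NULL
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a solubility table into per-system series
#'
#' @param tbl A tibble from `read_table(..., "solubility")`.
#' @return A list of [solubility_series()] (molar scale), one per
#'   solute x solvent combination, named `"<solute>/<solvent>"`.
#' @export
solubility_series_from_table <- function(tbl) {
  keys <- paste(tbl$solute, tbl$solvent, sep = "/")
  lapply(split(tbl, keys), function(g) {
    solubility_series(
      g$solute[1], g$solvent[1], T = g$T_K, S2 = g$S2_mol_per_L,
      sd = if ("sd" %in% names(g) && !all(is.na(g$sd))) g$sd else NULL,
      scale = "molar"
    )
  })
}

#' Read an analysis configuration file
#'
#' Single YAML document with optional blocks `solvents:` (name ->
#' `molar_mass`, `density`), `solutes:` (name -> `molar_mass`),
#' `modes:` (`mole_fraction`, `distribution`, `flux_window`) and
#' `geometry:` (Franz-cell fields). Unspecified entries fall back to
#' package defaults.
#'
#' @param path YAML file path.
#' @return A list with `solvents`, `solutes`, `modes`, `geometry`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    stop_partperm(sprintf("config not found: %s", path), "partperm_schema_error")
  }
  cfg <- yaml::read_yaml(path)
  solvents <- default_solvents()
  for (nm in names(cfg$solvents)) {
    s <- cfg$solvents[[nm]]
    solvents[[nm]] <- solvent_spec(nm, s$molar_mass, s$density,
                                   s$density_reference_T %||% 298.2)
  }
  solutes <- default_solutes()
  for (nm in names(cfg$solutes)) {
    solutes[[nm]] <- solute_spec(nm, cfg$solutes[[nm]]$molar_mass)
  }
  geometry <- do.call(franz_cell_geometry, cfg$geometry %||% list())
  modes <- list(
    mole_fraction = cfg$modes$mole_fraction %||% "as_printed",
    distribution = cfg$modes$distribution %||% "mass_balance",
    flux_window = cfg$modes$flux_window %||% "all"
  )
  list(solvents = solvents, solutes = solutes, modes = modes,
       geometry = geometry)
}
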