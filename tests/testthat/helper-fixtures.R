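# Shared fixtures built in code.

# Published van't Hoff coefficients for iproniazid in each solvent.
oct_fit <- vant_hoff_fit(5.79, -2469, se_A = 0.08, se_B = 23, n = 5,
                         label = "octanol")
hex_fit <- vant_hoff_fit(7.28, -4809, se_A = 0.35, se_B = 104, n = 5,
                         label = "hexane")

# Study temperatures of the solubility experiment.
study_temps <- c(290.2, 293.2, 298.2, 303.2, 310.2)

# Cyclodextrin concentrations used in the distribution experiments.
cd_concs <- c(0.0115, 0.025, 0.035)

# Suppression series taken from the packaged distribution table.
suppression_series_from_reference <- function(system, cd) {
  tbl <- ipn_distribution_data()
  d0 <- tbl$D[tbl$system == system & tbl$solute == "IPN" & tbl$cd_conc_M == 0]
  rows <- tbl[tbl$system == system & tbl$cd_name == cd & tbl$cd_conc_M > 0, ]
  cd_suppression_series(system, cd, D0 = d0,
                        C_CD = rows$cd_conc_M, D = rows$D)
}
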