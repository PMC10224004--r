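test_that("mole-fraction conversion matches hand-evaluated values in both modes", {
  ipn <- solute_spec("iproniazid", 179.22)
  octanol <- solvent_spec("1-octanol", 130.23, 0.8262)
  hexane <- solvent_spec("n-hexane", 86.18, 0.6548)

  # hand evaluation: 130.23*0.686 / (0.686*(179.22-130.23) + 826.2)
  expect_equal(molar_to_mole_fraction(0.686, ipn, octanol), 0.1039, tolerance = 1e-3)
  expect_equal(molar_to_mole_fraction(0.00203, ipn, hexane), 2.67e-4, tolerance = 1e-3)

  # mass-balance variant flips the sign of the S2*(M1-M2) correction
  X_printed <- molar_to_mole_fraction(0.686, ipn, octanol, "as_printed")
  X_mb <- molar_to_mole_fraction(0.686, ipn, octanol, "mass_balance")
  expect_gt(X_mb, X_printed) # smaller denominator
  expect_lt(abs(X_mb / X_printed - 1), 0.1)

  # infinite-dilution limit and strict monotonicity in S2
  expect_lt(molar_to_mole_fraction(1e-10, ipn, octanol), 1e-9)
  S2 <- seq(0.01, 1, length.out = 50)
  for (mode in c("as_printed", "mass_balance")) {
    X <- molar_to_mole_fraction(S2, ipn, octanol, mode)
    expect_true(all(diff(X) > 0))
    expect_true(all(X > 0 & X < 1))
  }

  # cross-check against the published hexane line at 310.2 K (within 10%)
  lnX_pred <- 7.28 - 4809 / 310.2
  expect_equal(log(molar_to_mole_fraction(0.00203, ipn, hexane)), lnX_pred,
               tolerance = 0.1)

  # invalid-composition errors
  heavy <- solute_spec("heavy", 1e6)
  expect_error(molar_to_mole_fraction(1, heavy, octanol, "mass_balance"),
               class = "partperm_invalid_composition")
})

test_that("van't Hoff fit recovers generating coefficients and flags bad designs", {
  # noiseless recovery of the published coefficients, machine precision
  for (cf in list(c(5.79, -2469), c(7.28, -4809))) {
    s <- simulate_solubility_series(cf[1], cf[2], study_temps)
    f <- fit_vant_hoff(s)
    expect_equal(f$A, cf[1], tolerance = 1e-10)
    expect_equal(f$B, cf[2], tolerance = 1e-10)
    expect_lt(f$rss, 1e-20)
    expect_equal(f$n, 5L)
  }

  # two points: exact interpolating line
  s2 <- simulate_solubility_series(5, -2000, c(290, 310))
  f2 <- fit_vant_hoff(s2)
  expect_equal(f2$A, 5, tolerance = 1e-10)
  expect_equal(f2$rss, 0, tolerance = 1e-25)

  expect_error(fit_vant_hoff(list(T = 298.2, X2 = 0.1)),
               class = "partperm_insufficient_data")
  expect_error(fit_vant_hoff(list(T = c(298.2, 298.2), X2 = c(0.1, 0.11))),
               class = "partperm_degenerate_design")
  expect_error(
    fit_vant_hoff(solubility_series("x", "y", T = c(290, 300), S2 = c(0.1, 0.2))),
    class = "partperm_domain_error" # molar scale not accepted
  )
})

test_that("thermodynamic functions reproduce the published dissolution table", {
  kJ <- function(x) x / 1000
  t_oct <- thermo_functions(oct_fit, 298.2)
  expect_equal(kJ(t_oct$dG), 6.2, tolerance = 0.1 / 6.2)
  expect_equal(kJ(t_oct$dH), 20.5, tolerance = 0.1 / 20.5)
  expect_equal(kJ(t_oct$TdS), 14.3, tolerance = 0.1 / 14.3)
  expect_equal(t_oct$zeta_H, 58.9, tolerance = 0.2 / 58.9)

  t_hex310 <- thermo_functions(hex_fit, 310.2)
  expect_equal(kJ(t_hex310$dG), 21.2, tolerance = 0.1 / 21.2)
  expect_equal(kJ(t_hex310$TdS), 18.8, tolerance = 0.1 / 18.8)
  expect_equal(kJ(enthalpy_from_fit(hex_fit)), 40.0, tolerance = 0.1 / 40)

  # Gibbs identity holds exactly for every computed set
  for (fit in list(oct_fit, hex_fit)) {
    for (T in c(290, 298.2, 310.2)) {
      tf <- thermo_functions(fit, T)
      expect_equal(tf$dG, tf$dH - tf$TdS, tolerance = 1e-6)
      expect_true(tf$zeta_H >= 0 && tf$zeta_H <= 100)
    }
  }

  # B = 0: temperature-independent solubility, zero enthalpy
  flat <- vant_hoff_fit(-1, 0)
  expect_equal(enthalpy_from_fit(flat), 0)

  # ideal-solubility boundary: A + B/T = 0 gives dG = 0
  expect_equal(gibbs_at(vant_hoff_fit(10, -2982), 298.2), 0, tolerance = 1e-9)

  # pure-enthalpy control: TdS = 0 (A = 0) makes zeta_H = 100%
  expect_equal(thermo_functions(vant_hoff_fit(0, -2000), 298.2)$zeta_H, 100)
  expect_error(thermo_functions(vant_hoff_fit(0, 0), 298.2),
               class = "partperm_degenerate")

  # positive entropy: dG strictly decreases with temperature
  dG <- vapply(seq(290, 320, 5), function(T) gibbs_at(oct_fit, T), numeric(1))
  expect_true(all(diff(dG) < 0))
})

test_that("transfer functions reproduce the published transfer row and are antisymmetric", {
  tr <- transfer_functions(hex_fit, oct_fit, 298.2)
  expect_equal(tr$dG / 1000, -15.8, tolerance = 0.1 / 15.8)
  expect_equal(tr$dH / 1000, -19.5, tolerance = 0.1 / 19.5)
  expect_equal(tr$TdS / 1000, -3.7, tolerance = 0.1 / 3.7)
  expect_equal(tr$zeta_H, 84.1, tolerance = 0.2 / 84.1)

  rev <- transfer_functions(oct_fit, hex_fit, 298.2)
  expect_equal(rev$dG, -tr$dG)
  expect_equal(rev$dH, -tr$dH)
  expect_equal(rev$TdS, -tr$TdS)
  expect_equal(rev$zeta_H, tr$zeta_H)

  self <- transfer_functions(
    vant_hoff_fit(5, -2000), vant_hoff_fit(5, -2100), 298.2
  )
  expect_equal(self$dG, self$dH - self$TdS, tolerance = 1e-6)
})

test_that("noisy van't Hoff replicates keep the true slope inside its confidence interval", {
  # multiplicative 2% noise at n = 5; 95% CI on B should cover the truth
  # in at least 90% of seeded replicates
  A <- 5.79
  B <- -2469
  n_rep <- 500
  covered <- 0L
  for (i in seq_len(n_rep)) {
    s <- simulate_solubility_series(
      A, B, study_temps,
      noise = noise_spec("multiplicative_lognormal", sigma = 0.02, seed = 1000 + i)
    )
    f <- fit_vant_hoff(s)
    half <- stats::qt(0.975, f$n - 2) * f$se_B
    if (abs(f$B - B) <= half) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.90)
})
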