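test_that("log-log linearization of single points", {
  p <- linearized_point(2.651, 2.413, 0.0115)
  expect_equal(unname(p["y"]), -1.0468, tolerance = 1e-4)
  expect_equal(unname(p["x"]), -1.9393, tolerance = 1e-4)

  # zero suppression is outside the transform's domain
  expect_error(linearized_point(2.651, 2.651, 0.01),
               class = "partperm_non_suppressed_point")
  expect_error(linearized_point(2.651, 3.0, 0.01),
               class = "partperm_non_suppressed_point")

  # closed form: K*C = 1 halves D, so y = log10(0.5)
  D0 <- 1; K <- 10; C <- 0.1
  D <- D0 / (1 + K * C)
  expect_equal(unname(linearized_point(D0, D, C)["y"]), log10(0.5))
})

test_that("linearized Kc fit reproduces the published association table", {
  cases <- list(
    list("octanol", "HP-b-CD", 0.899, 1.004, 0.9999, 5441.26, 0.01),
    list("octanol", "M-b-CD", 0.479, 1.000, 0.9979, 235.47, 0.01),
    list("hexane", "HP-b-CD", 1.536, 1.087, 0.9975, 201.42, 0.005),
    list("hexane", "M-b-CD", 1.311, 1.057, 0.9909, 53.97, 0.005)
  )
  for (cs in cases) {
    s <- suppression_series_from_reference(cs[[1]], cs[[2]])
    f <- fit_kc(s)
    expect_equal(f$intercept, cs[[3]], tolerance = cs[[7]] / abs(cs[[3]]))
    expect_equal(f$alpha, cs[[4]], tolerance = cs[[7]] / cs[[4]])
    expect_equal(f$R, cs[[5]], tolerance = 0.001 / cs[[5]])
    expect_gt(f$F / cs[[6]], 0.1) # order-of-magnitude only: F is
    expect_lt(f$F / cs[[6]], 10)  # hypersensitive to rounding at n = 3
    expect_equal(f$Kc_antilog, 10^f$intercept)
    expect_equal(f$n, 3L)
  }
})

test_that("Kc fit is exact on exact power-law data and order-invariant", {
  C <- c(0.005, 0.012, 0.02, 0.03)
  c_true <- 0.9
  D0 <- 2.5
  y <- c_true + 1 * log10(C)
  D <- D0 * (1 - 10^y)
  s <- cd_suppression_series("sys", "cd", D0, C, D)
  f <- fit_kc(s)
  expect_equal(f$intercept, c_true, tolerance = 1e-12)
  expect_equal(f$alpha, 1, tolerance = 1e-12)
  expect_lt(f$rss, 1e-25)
  expect_equal(f$R, 1, tolerance = 1e-12)
  expect_true(is.infinite(f$F)) # rss = 0 guard

  # order of points does not matter
  perm <- c(3, 1, 4, 2)
  f2 <- fit_kc(cd_suppression_series("sys", "cd", D0, C[perm], D[perm]))
  expect_equal(f2$intercept, f$intercept)
  expect_equal(f2$alpha, f$alpha)

  # all points unsuppressed -> insufficient data for the transform
  s_flat <- suppressWarnings(
    cd_suppression_series("sys", "cd", 1, C, rep(1, 4))
  )
  expect_error(fit_kc(s_flat), class = "partperm_insufficient_data")
})

test_that("nonlinear 1:1 oracle recovers the generating constant", {
  s <- simulate_cd_suppression(2.651, 10, cd_concs)
  fit <- fit_kc_nonlinear(s)
  expect_equal(fit$Kc, 10, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-15)

  # no binding: flat series, boundary Kc = 0 with warning
  s0 <- simulate_cd_suppression(2.651, 0, cd_concs)
  expect_true(all(s0$points$D == 2.651))
  expect_warning(f0 <- fit_kc_nonlinear(s0), class = "partperm_no_suppression")
  expect_equal(f0$Kc, 0)

  # published-scale round trip: Kc chosen to mimic the octanol suppressions
  s_ipn <- simulate_cd_suppression(2.651, 8, cd_concs,
    noise = noise_spec("multiplicative_lognormal", 0.03, seed = 7)
  )
  f_ipn <- fit_kc_nonlinear(s_ipn)
  expect_gt(f_ipn$Kc, 0)
  expect_equal(f_ipn$Kc, 8, tolerance = 0.5)
})

test_that("linearization converges to the 1:1 model in the small-saturation limit", {
  # deep-dilution regime: the log-log linearization carries an
  # O(K*C/ln 10) curvature term that is amplified by extrapolating the
  # intercept to C = 1 M, so 0.03 agreement needs K*C of order 0.02
  K <- 0.1
  C <- c(0.05, 0.1, 0.2) # K*C <= 0.02
  s <- simulate_cd_suppression(2.0, K, C)
  f <- fit_kc(s)
  expect_equal(f$alpha, 1, tolerance = 0.03)
  expect_equal(f$intercept, log10(K), tolerance = 0.03)

  # D strictly decreases with C under the exact model for K > 0
  expect_true(all(diff(s$points$D) < 0))
  # non-monotone experimental input warns but is not an error
  expect_warning(
    cd_suppression_series("sys", "cd", 2, c(0.01, 0.02, 0.03),
                          c(1.5, 1.6, 1.4)),
    class = "partperm_non_monotone"
  )
})
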