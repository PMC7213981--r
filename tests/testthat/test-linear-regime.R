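test_that("linear-regime slope and intercept follow the closed form", {
  # k_p' = 120, Gamma_p' = 15 -> slope -112 molecules/site
  p <- kinetic_params(Gamma_up = 1 / 120, Gamma_p = 1 / 8, k_p = 1,
                      NICD0 = 2000, N_e = 5.4)
  lr <- linear_regime(p)
  expect_equal(lr$slope_dimensionless, -112)
  expect_equal(lr$intercept, 2000 - 5.4 * 112)
  expect_equal(lr$slope_normalized, -112 / (2000 - 5.4 * 112))
})

test_that("the slope tends to -k_p' as phospho degradation becomes instant", {
  p <- kinetic_params(Gamma_up = 1 / 120, Gamma_p = 1e9, k_p = 1,
                      NICD0 = 2000)
  expect_equal(linear_regime(p)$slope_dimensionless, -120,
               tolerance = 1e-6)
})

test_that("halving the phosphorylation rate exactly halves the slope", {
  p1 <- central_params(k_p = 0.5)
  p2 <- update_params(p1, k_p = 0.25)
  expect_equal(linear_regime(p1)$slope_dimensionless /
                 linear_regime(p2)$slope_dimensionless, 2)
})

test_that("slow phospho degradation triggers the approximation warning", {
  p <- kinetic_params(Gamma_up = 1 / 8, Gamma_p = 1 / 120, k_p = 1,
                      NICD0 = 2000)
  expect_warning(lr <- linear_regime(p), "Gamma_p")
  expect_true(lr$gamma_warning)
})

test_that("validity flag tracks the configured linear-drop threshold", {
  expect_true(linear_regime(central_params(k_p = 0.1, N_s = 6L))$valid)
  expect_false(linear_regime(central_params(k_p = 1, N_s = 18L))$valid)
})

test_that("phosphorylation-rate inversion round-trips through the slope", {
  for (kp in c(0.05, 0.5, 2)) {
    lr <- linear_regime(central_params(k_p = kp))
    expect_equal(estimate_kp_from_slope(lr$slope_normalized, 2000, 1 / 120,
                                        1 / 8, 5.4),
                 kp, tolerance = 1e-9)
  }
  expect_equal(estimate_kp_from_slope(0, 2000, 1 / 120, 1 / 8, 5.4), 0)
})

test_that("measured reporter slope implies a phosphorylation rate of order 1/min", {
  kp <- estimate_kp_from_slope(-0.0294, 2000, 1 / 120, 1 / 8, 5.4)
  expect_gte(kp, 0.1)
  expect_lte(kp, 10)
})

test_that("slope inversion rejects impossible inputs", {
  expect_error(estimate_kp_from_slope(0.01, 2000, 1 / 120, 1 / 8, 5.4),
               class = "nicddrain_domain_error")
  # Gamma_up >= Gamma_p makes the denominator non-positive
  expect_error(estimate_kp_from_slope(-0.03, 2000, 1 / 8, 1 / 120, 5.4),
               class = "nicddrain_domain_error")
  expect_error(estimate_kp_from_slope(NA_real_, 2000, 1 / 120, 1 / 8, 5.4),
               class = "nicddrain_domain_error")
})

test_that("the closed-form linear curve tracks the full steady state in-regime", {
  # wherever the linear drop is at most 30% of baseline (and k_p >> Gamma_up,
  # the regime the closed form is derived in), agreement is within 5%
  for (NICD0 in c(500, 2000, 5000)) for (kp in c(0.05, 0.2, 0.45))
    for (Ns in c(0L, 6L, 12L)) {
      p <- kinetic_params(Gamma_up = 1 / 120, Gamma_p = 1 / 8, k_p = kp,
                          NICD0 = NICD0, k_alpha = 1, N_e = 5.4, N_s = Ns)
      d <- dimensionless_params(p)
      drop <- d$N * d$k_p_prime * (1 - 1 / d$Gamma_p_prime)
      if (drop > 0.3 * NICD0) next
      full <- steady_state(p)$NICD_tot
      expect_lt(abs((NICD0 - drop) - full) / full, 0.05)
    }
})

test_that("kp grid is monotone in both axes and matches scalar evaluations", {
  g <- kp_grid(NICD0_values = 10^seq(2, 4, length.out = 7),
               Gamma_up_values = 10^seq(log10(1 / 1000), log10(1 / 30),
                                        length.out = 7))
  expect_true(all(is.finite(g$kp_values)) && all(g$kp_values > 0))
  expect_true(all(apply(g$kp_values, 2, diff) > 0))  # increasing in NICD0
  expect_true(all(apply(g$kp_values, 1, diff) > 0))  # increasing in Gamma_up
  # corners equal independent scalar evaluations
  for (i in c(1, 7)) for (j in c(1, 7))
    expect_identical(g$kp_values[i, j],
                     estimate_kp_from_slope(-0.0294, g$NICD0_values[i],
                                            g$Gamma_up_values[j], 1 / 8, 5.4))
  # degenerate 1x1 grid is the scalar call
  g1 <- kp_grid(NICD0_values = 2000, Gamma_up_values = 1 / 120)
  expect_identical(g1$kp_values[1, 1],
                   estimate_kp_from_slope(-0.0294, 2000, 1 / 120, 1 / 8, 5.4))
})

test_that("kp grid masks cells whose inversion fails", {
  g <- kp_grid(NICD0_values = c(100, 1000), Gamma_up_values = c(1 / 100, 1),
               Gamma_p = 1 / 8)
  expect_true(all(is.na(g$kp_values[, 2])))   # Gamma_up > Gamma_p column
  expect_true(all(is.finite(g$kp_values[, 1])))
})
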