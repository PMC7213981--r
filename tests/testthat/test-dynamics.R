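test_that("zero production from empty initial conditions stays at zero", {
  p <- kinetic_params(Gamma_up = 1 / 120, Gamma_p = 1 / 8, k_p = 0.5,
                      P_NICD = 0, N_e = 5, N_s = 12L)
  tr <- integrate_dynamics(p, seq(0, 1000, by = 100))
  expect_true(all(tr$nicd_tot == 0))
  expect_equal(steady_state(p)$NICD_tot, 0)
})

test_that("trajectories conserve the phospho/unphospho decomposition", {
  p <- central_params(k_p = 0.5, N_s = 12L)
  tr <- integrate_dynamics(p, seq(0, 2000, by = 50))
  expect_equal(tr$nicd_tot, tr$nicd_up + tr$nicd_p, tolerance = 1e-12)
  expect_true(all(tr$nicd_up >= 0 & tr$nicd_p >= 0))
})

test_that("dimensionless-time integration matches physical time rescaled", {
  p <- central_params(k_p = 0.5, N_s = 12L)
  t_phys <- seq(0, 1200, by = 120)
  tr_min <- integrate_dynamics(p, t_phys)
  tr_dim <- integrate_dynamics(p, t_phys * p$Gamma_up,
                               time_unit = "dimensionless")
  expect_equal(tr_min$nicd_tot, tr_dim$nicd_tot, tolerance = 1e-6)
})

test_that("time grid must be increasing from zero and initial state valid", {
  p <- central_params()
  expect_error(integrate_dynamics(p, c(1, 2, 3)),
               class = "nicddrain_domain_error")
  expect_error(integrate_dynamics(p, c(0, 2, 2)),
               class = "nicddrain_domain_error")
  expect_error(integrate_dynamics(p, c(0, 10), initial = c(-1, 0)),
               class = "nicddrain_domain_error")
})

test_that("unperturbed NICD exceeds both perturbed genotypes over time", {
  # comparison from t = 5 min on: in the first minutes of deep strong
  # binding, transient sequestration (bound NICD is shielded from
  # degradation) can briefly put the added-sites genotype above baseline
  kp <- estimate_kp_from_slope(-0.0294, 2000, 1 / 120, 1 / 8, 5.4)
  wt <- central_params(k_p = kp)
  times <- c(0, 10^seq(log10(5), 3.7, length.out = 25))
  tot <- function(p) integrate_dynamics(p, times)$nicd_tot[-1]
  wt_t <- tot(wt)
  sites_t <- tot(update_params(wt, N_s = 12L))
  het_t <- tot(update_params(wt, NICD0 = 1000))
  expect_true(all(wt_t > sites_t))
  expect_true(all(wt_t > het_t))
})

test_that("duration sensitivity separates short- from long-duration effects", {
  kp <- estimate_kp_from_slope(-0.0294, 2000, 1 / 120, 1 / 8, 5.4)
  ds <- duration_sensitivity(central_params(k_p = kp), Ns_transgene = 12L)
  expect_equal(ds$time, c(10, 2880))
  # halved production bites immediately; added sites do not
  expect_lt(ds$reduction_by_sites[1],
            0.5 * ds$reduction_by_halved_production[1])
  # at steady state both reductions are substantial
  expect_gt(ds$reduction_by_sites[2], 0.2)
  expect_gt(ds$reduction_by_halved_production[2], 0.2)
})

test_that("a zero-site transgene produces exactly no site reduction", {
  ds <- duration_sensitivity(central_params(k_p = 0.5), Ns_transgene = 0L)
  expect_equal(ds$reduction_by_sites, c(0, 0), tolerance = 1e-9)
})

test_that("robustness sweep handles empty, duplicate and failing variants", {
  base <- central_params(k_p = 0.5)
  expect_equal(nrow(robustness_sweep(base, list())), 0)
  sw <- robustness_sweep(base, list(same = list()),
                         recompute_kp_slope = NULL)
  direct <- duration_sensitivity(base)
  expect_equal(sw$red_sites_long, direct$reduction_by_sites[2])
  expect_equal(sw$red_prod_short, direct$reduction_by_halved_production[1])
  # an invalid variant is recorded, not fatal
  sw2 <- robustness_sweep(base, list(bad = list(Gamma_up = -1),
                                     ok = list()))
  expect_true(is.na(sw2$red_sites_long[1]) && !is.na(sw2$error[1]))
  expect_true(is.na(sw2$error[2]))
})

test_that("all printed robustness variants run and keep short-time protection", {
  sw <- robustness_sweep(central_params(k_p = 0.5), sweep_variants_default())
  expect_equal(nrow(sw), 6)
  expect_true(all(is.na(sw$error)))
  expect_true(all(sw$short_protected))
})
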