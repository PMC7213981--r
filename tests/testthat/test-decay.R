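test_that("the Hill decay curve hits its algebraic landmarks", {
  expect_equal(hill_decay(0, 120, 2, 0.1), 1)
  expect_equal(hill_decay(120, 120, 2, 0.1), (1 + 0.1) / 2)
  expect_equal(hill_decay(1e12, 120, 2, 0.1), 0.1, tolerance = 1e-6)
  # monotone non-increasing, bounded in (bg, 1]
  v <- hill_decay(seq(0, 2000, by = 10), 90, 1.7, 0.05)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v <= 1 & v > 0.05 - 1e-12))
  expect_error(hill_decay(-1, 120, 2, 0.1), class = "nicddrain_domain_error")
  expect_error(hill_decay(1, 0, 2, 0.1), class = "nicddrain_domain_error")
  expect_error(hill_decay(1, 120, 2, 1), class = "nicddrain_domain_error")
})

test_that("decay curves validate replicate structure", {
  bad <- data.frame(time_min = c(0, 10, 20), replicate = 1,
                    value = c(1, 0.9, 0.8))
  expect_error(decay_curve(bad), class = "nicddrain_config_error")  # < 4 pts
  un <- data.frame(time_min = c(0, 10, 20, 30), replicate = 1,
                   value = c(2, 1.8, 1.6, 1.4))
  expect_error(decay_curve(un), class = "nicddrain_config_error")  # not at 1
  expect_silent(decay_curve(un, normalize = TRUE))
})

test_that("noiseless curves are recovered to machine-level accuracy", {
  spec <- decay_sim_spec(t05 = 120, n_hill = 2, bg = 0.1, noise_sd = 0,
                         n_replicates = 1L, seed = 1)
  curve <- gen_decay_curves(spec)
  fit <- fit_hill_decay(curve, ci_method = "covariance")
  expect_equal(fit$t05, 120, tolerance = 1e-6)
  expect_equal(fit$n_hill, 2, tolerance = 1e-6)
  expect_equal(fit$bg, 0.1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("the fitted half-life is where the curve crosses (1+bg)/2", {
  spec <- decay_sim_spec(seed = 2)
  fit <- fit_hill_decay(gen_decay_curves(spec), ci_method = "covariance")
  expect_equal(hill_decay(fit$t05, fit$t05, fit$n_hill, fit$bg),
               (1 + fit$bg) / 2)
  expect_gt(fit$t05, 0)
})

test_that("noisy seeded curves recover the half-life within ten percent", {
  fit <- fit_hill_decay(gen_decay_curves(decay_sim_spec(seed = 1)),
                        ci_method = "covariance")
  expect_lt(abs(fit$t05 - 120) / 120, 0.10)
})

test_that("degenerate and unseeded inputs are refused", {
  const <- decay_curve(data.frame(time_min = seq(0, 60, by = 20),
                                  replicate = 1, value = rep(1, 4)))
  expect_error(fit_hill_decay(const, ci_method = "covariance"),
               class = "nicddrain_domain_error")
  curve <- gen_decay_curves(decay_sim_spec(seed = 3))
  expect_error(fit_hill_decay(curve, ci_method = "bootstrap", seed = NULL),
               class = "nicddrain_config_error")
})

test_that("bootstrap and covariance intervals agree on well-conditioned data", {
  curve <- gen_decay_curves(decay_sim_spec(seed = 11, n_replicates = 6,
                                           noise_sd = 0.03))
  f_cov <- fit_hill_decay(curve, ci_method = "covariance")
  f_boot <- fit_hill_decay(curve, ci_method = "bootstrap", n_boot = 400,
                           seed = 11)
  w_cov <- diff(f_cov$ci95["t05", ])
  w_boot <- diff(f_boot$ci95["t05", ])
  expect_lt(abs(w_cov - w_boot) / max(w_cov, w_boot), 0.5)
  # point estimates identical (CIs differ, fit does not)
  expect_identical(f_cov$t05, f_boot$t05)
})

test_that("bootstrap intervals are reproducible given the seed", {
  curve <- gen_decay_curves(decay_sim_spec(seed = 5))
  f1 <- fit_hill_decay(curve, n_boot = 100, seed = 7)
  f2 <- fit_hill_decay(curve, n_boot = 100, seed = 7)
  expect_identical(f1$ci95, f2$ci95)
})

test_that("single-replicate curves fit via residual resampling", {
  curve <- gen_decay_curves(decay_sim_spec(seed = 6, n_replicates = 1))
  fit <- fit_hill_decay(curve, n_boot = 100, seed = 6)
  expect_true(is.finite(fit$ci95["t05", 1]) && fit$ci95["t05", 1] > 0)
  expect_true(fit$ci95["t05", 1] <= fit$t05 && fit$t05 <= fit$ci95["t05", 2])
})

test_that("half-life recovery is nearly unbiased across many replicates", {
  t05s <- vapply(1:120, function(i) {
    curve <- gen_decay_curves(decay_sim_spec(seed = 400 + i))
    nicddrain:::hill_fit_core(curve$time_min, curve$value)$par[1]
  }, numeric(1))
  expect_lt(abs(mean(t05s) - 120) / 120, 0.03)
})
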