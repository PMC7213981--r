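make_ds <- function(values_ref, values_mut, ns = c(0, 6, 12, 18),
                    n_per = length(values_ref) / length(ns)) {
  df <- rbind(
    data.frame(genotype = "reference", n_sites = rep(ns, each = n_per),
               value = values_ref),
    data.frame(genotype = "mutant", n_sites = rep(ns, each = n_per),
               value = values_mut))
  df$disc_id <- seq_len(nrow(df))
  reporter_dataset(df)
}

test_that("normalization divides both genotypes by the reference baseline", {
  ds <- make_ds(c(400, 600, 300, 200, 100, 50, 40, 20),
                c(500, 500, 400, 300, 250, 200, 150, 100))
  nds <- normalize_reporter(ds)
  # baseline mean 500 -> a 250 becomes 0.5
  expect_equal(attr(nds, "normalization_constant"), 500)
  expect_equal(mean(nds$value[nds$genotype == "reference" &
                                nds$n_sites == 0]), 1)
  expect_equal(nds$value, ds$value / 500)
  # idempotent
  expect_identical(normalize_reporter(nds), nds)
})

test_that("normalization fails without a reference zero-site group", {
  df <- data.frame(genotype = "reference", n_sites = c(6, 6, 12, 12),
                   disc_id = 1:4, value = c(1, 2, 3, 4))
  expect_error(normalize_reporter(reporter_dataset(df)),
               class = "nicddrain_config_error")
})

test_that("line fit on exactly collinear means recovers slope and intercept", {
  df <- data.frame(genotype = "reference",
                   n_sites = rep(c(0, 6, 12), each = 2),
                   disc_id = 1:6,
                   value = rep(c(1, 0.9, 0.8), each = 2))
  ds <- normalize_reporter(reporter_dataset(df))
  fit <- fit_reporter_line(ds, "reference")
  expect_equal(fit$slope, -1 / 60, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)
  # restricting the points changes the bookkeeping
  fit2 <- fit_reporter_line(ds, "reference", points_used = c(0, 6))
  expect_equal(fit2$n_points, 2L)
  expect_true(fit2$exact_fit)
  expect_equal(unname(fit2$covariance), matrix(0, 2, 2))
  expect_error(fit_reporter_line(ds, "reference", points_used = 0),
               class = "nicddrain_config_error")
})

test_that("line fits demand normalized data", {
  ds <- make_ds(rep(1, 8), rep(1, 8))
  expect_error(fit_reporter_line(ds, "reference"),
               class = "nicddrain_config_error")
})

test_that("slope ratio and its degenerate cases follow the closed form", {
  f <- fake_fit(-0.0294, 1)
  expect_equal(slope_ratio(f, f)$ratio, 1)
  r <- slope_ratio(fake_fit(-0.0294, 1), fake_fit(-0.0147, 1.07938))
  expect_equal(r$ratio, 2)
  expect_equal(r$se, 0)
  expect_error(slope_ratio(f, fake_fit(0, 1)),
               class = "nicddrain_domain_error")
})

test_that("crossing-point estimate lands on the constructed site number", {
  # lines built to cross at -5.4: the mutant (half slope) line lies
  # 5.4 * 0.0147 higher at the axis
  ne <- estimate_ne(fake_fit(-0.0294, 1), fake_fit(-0.0147, 1 + 5.4 * 0.0147))
  expect_equal(ne$n_e, 5.4, tolerance = 1e-9)
  # equal intercepts cross on the axis
  expect_equal(estimate_ne(fake_fit(-0.03, 1), fake_fit(-0.015, 1))$n_e, 0)
  expect_error(estimate_ne(fake_fit(-0.03, 1), fake_fit(-0.03, 0.9)),
               class = "nicddrain_domain_error")
})

test_that("delta-method errors match Monte-Carlo propagation of known fits", {
  # moderate prescribed covariances so first-order propagation applies
  cov_ref <- matrix(c(4e-4, -3e-6, -3e-6, 4e-8), 2)
  cov_mut <- matrix(c(3e-4, -2e-6, -2e-6, 2e-8), 2)
  f_ref <- fake_fit(-0.0294, 1, cov_ref)
  f_mut <- fake_fit(-0.0147, 1.0794, cov_mut)
  r <- slope_ratio(f_ref, f_mut)
  ne <- estimate_ne(f_ref, f_mut)
  set.seed(99)
  n <- 2e5
  ch_r <- chol(cov_ref); ch_m <- chol(cov_mut)
  draws_r <- matrix(rnorm(2 * n), n) %*% ch_r
  draws_m <- matrix(rnorm(2 * n), n) %*% ch_m
  s_r <- -0.0294 + draws_r[, 2]; b_r <- 1 + draws_r[, 1]
  s_m <- -0.0147 + draws_m[, 2]; b_m <- 1.0794 + draws_m[, 1]
  expect_equal(r$se, sd(s_r / s_m), tolerance = 0.05)
  expect_equal(ne$se, sd(-(b_m - b_r) / (s_r - s_m)), tolerance = 0.05)
})

test_that("noiseless synthetic data reproduce the model titration exactly", {
  spec <- reporter_sim_spec(seed = 4, noise_cv = 0)
  ds <- normalize_reporter(gen_reporter_dataset(spec))
  tc <- titration_curve(spec$params_ref, c(0, 6, 12, 18))
  means <- tapply(ds$value[ds$genotype == "reference"],
                  ds$n_sites[ds$genotype == "reference"], mean)
  expect_equal(as.vector(means), tc$nicd_tot_norm, tolerance = 1e-12)
})

test_that("fits on noiseless model output recover the linear-regime slopes", {
  # within the validity threshold the fitted normalized slope matches the
  # closed form to a few percent (residual curvature of the full solution)
  p <- central_params(k_p = 0.15)
  spec <- reporter_sim_spec(params_ref = p, seed = 1, noise_cv = 0)
  an <- analyze_reporter(gen_reporter_dataset(spec))
  lr <- linear_regime(p)
  expect_true(linear_regime(update_params(p, N_s = 12L))$valid)
  expect_equal(an$fits$reference$slope, lr$slope_normalized, tolerance = 0.05)
})

test_that("seeded datasets recover the slope within three standard errors", {
  spec <- reporter_sim_spec(seed = 7)
  an <- analyze_reporter(gen_reporter_dataset(spec))
  truth <- attr(gen_reporter_dataset(spec), "truth")
  se <- sqrt(an$fits$reference$covariance[2, 2])
  expect_lt(abs(an$fits$reference$slope - truth$slope_normalized_ref), 3 * se)
})

test_that("median recovery over many seeds hits the generating truth", {
  ratios <- nes <- numeric(60)
  for (i in seq_along(ratios)) {
    an <- analyze_reporter(gen_reporter_dataset(reporter_sim_spec(seed = i)))
    ratios[i] <- an$ratio$ratio
    nes[i] <- an$ne$n_e
  }
  expect_gte(median(ratios), 1.8)
  expect_lte(median(ratios), 2.2)
  expect_lt(abs(median(nes) - 5.4), 3)
})

test_that("the kp wrapper delegates exactly", {
  f <- fake_fit(-0.0294, 1)
  expect_identical(infer_kp(f, 2000, 1 / 120, 1 / 8, 5.4),
                   estimate_kp_from_slope(-0.0294, 2000, 1 / 120, 1 / 8, 5.4))
})
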