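# Shared parameter constructors for the test suite.

# Central model parameters: 2000 molecules baseline, 120 min / 8 min
# half-lives, strong binding.
central_params <- function(k_p = 0.5, N_e = 5.4, N_s = 0L, k_alpha = 1,
                           NICD0 = 2000) {
  kinetic_params(Gamma_up = 1 / 120, Gamma_p = 1 / 8, k_p = k_p,
                 NICD0 = NICD0, k_alpha = k_alpha, N_e = N_e, N_s = N_s)
}

# Synthetic line fits with a prescribed covariance, for testing the error
# propagation in isolation from the regression step.
fake_fit <- function(slope, intercept, cov = matrix(0, 2, 2),
                     genotype = "x") {
  dimnames(cov) <- list(c("intercept", "slope"), c("intercept", "slope"))
  structure(list(slope = slope, intercept = intercept, covariance = cov,
                 n_points = 3L, points_used = c(0, 6, 12), exact_fit = FALSE,
                 genotype = genotype),
            class = "reporter_line_fit")
}
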