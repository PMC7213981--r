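#' Closed-form linear-regime analysis of the titration curve
#'
#' For low site numbers (and in the strong-binding regime, with
#' `k_p >> Gamma_up`), the steady-state total NICD falls linearly with the
#' number of synthetic sites:
#' \deqn{NICD_{tot}(N_s) \approx NICD_0 - (N_e + N_s)\, k_p' (1 - 1/\Gamma_p')}
#' with `k_p' = k_p/Gamma_up`, `Gamma_p' = Gamma_p/Gamma_up`. The per-site
#' slope is `-k_p'(1 - 1/Gamma_p')`, i.e. proportional to the
#' phosphorylation rate, which is what makes the slope ratio between two
#' genotypes measure their phosphorylation-rate ratio. The normalized slope
#' divides by the intercept `NICD_tot(N_s = 0)`, matching reporter data
#' normalized to the zero-site condition.
#'
#' @param params A [kinetic_params()] object.
#' @param validity_threshold The linear regime is flagged valid when the
#'   total linear drop `(N_e+N_s) k_p' (1 - 1/Gamma_p')` does not exceed
#'   this fraction of `NICD0`.
#' @return Object of class `linear_regime`: list with
#'   `slope_dimensionless` (molecules per site), `intercept`
#'   (molecules at `N_s = 0`), `slope_normalized` (per site, intercept
#'   units), `valid`, and `gamma_warning` (`TRUE` when
#'   `Gamma_p <= Gamma_up`, violating the fast-removal approximation).
#' @examples
#' linear_regime(default_reporter_params())
#' @export
linear_regime <- function(params, validity_threshold = 0.3) {
  stopifnot(inherits(params, "kinetic_params"))
  d <- dimensionless_params(params)
  gamma_warning <- d$Gamma_p_prime <= 1
  if (gamma_warning)
    warning("Gamma_p <= Gamma_up: linear-regime approximation assumes fast ",
            "removal of phosphorylated NICD")
  per_site <- d$k_p_prime * (1 - 1 / d$Gamma_p_prime)
  slope <- -per_site
  intercept <- d$NICD0 - params$N_e * per_site
  structure(list(slope_dimensionless = slope,
                 intercept = intercept,
                 slope_normalized = slope / intercept,
                 valid = d$N * per_site <= validity_threshold * d$NICD0,
                 gamma_warning = gamma_warning),
            class = "linear_regime")
}

#' @export
print.linear_regime <- function(x, ...) {
  cat(sprintf("Linear-regime titration: slope %.6g molecules/site, intercept %.6g\n",
              x$slope_dimensionless, x$intercept))
  cat(sprintf("  normalized slope %.6g per site; regime valid: %s\n",
              x$slope_normalized, x$valid))
  invisible(x)
}

#' Estimate the phosphorylation rate from a normalized titration slope
#'
#' Inverts the normalized linear-regime slope
#' \deqn{s = \frac{-k_p'(1-1/\Gamma_p')}{NICD_0 - N_e k_p'(1-1/\Gamma_p')}}
#' for `k_p`, giving the closed form
#' \deqn{k_p = \frac{NICD_0\,\Gamma_{up}}{(N_e - 1/s)\,(1 - \Gamma_{up}/\Gamma_p)}.}
#' Round-trips exactly with [linear_regime()].
#'
#' @param slope_normalized Normalized per-site slope (<= 0).
#' @param NICD0 Baseline abundance (molecules/nucleus).
#' @param Gamma_up,Gamma_p Degradation rates (min^-1).
#' @param N_e Effective endogenous site number.
#' @return Phosphorylation rate `k_p` (min^-1).
#' @examples
#' estimate_kp_from_slope(-0.0294, 2000, 1/120, 1/8, 5.4)
#' @export
estimate_kp_from_slope <- function(slope_normalized, NICD0, Gamma_up,
                                   Gamma_p, N_e) {
  for (v in list(slope_normalized, NICD0, Gamma_up, Gamma_p, N_e))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort_domain("all inputs must be single finite numbers")
  if (NICD0 <= 0 || Gamma_up <= 0 || Gamma_p <= 0 || N_e < 0)
    abort_domain("NICD0, Gamma_up, Gamma_p must be > 0 and N_e >= 0")
  if (slope_normalized > 0)
    abort_domain("`slope_normalized` must be <= 0 (NICD falls with added sites)")
  if (slope_normalized == 0) return(0)
  denom <- (N_e - 1 / slope_normalized) * (1 - Gamma_up / Gamma_p)
  kp <- NICD0 * Gamma_up / denom
  if (!is.finite(kp) || kp < 0)
    abort_domain("slope implies a negative or non-finite phosphorylation rate")
  kp
}

#' Phosphorylation-rate estimates over a grid of baseline parameters
#'
#' Applies [estimate_kp_from_slope()] elementwise over grids of the
#' baseline abundance `NICD0` and slow degradation rate `Gamma_up`, for a
#' fixed measured normalized slope. Defaults cover the plausible nuclear
#' abundance range (1e2-1e4 molecules) and unphosphorylated half-lives of
#' 0.5-16 h (`Gamma_up` between 1/1000 and 1/30 min^-1). Cells whose
#' inversion fails are masked as `NA`.
#'
#' @param NICD0_values,Gamma_up_values Grid axes (log-spaced by default).
#' @param Gamma_p Fast degradation rate (min^-1).
#' @param slope_normalized Measured normalized per-site slope.
#' @param N_e Effective endogenous site number.
#' @return Object of class `kp_grid`: list with the axes, the matrix
#'   `kp_values` (rows = `NICD0_values`, columns = `Gamma_up_values`), and
#'   the fixed inputs.
#' @export
kp_grid <- function(NICD0_values = 10^seq(2, 4, length.out = 41),
                    Gamma_up_values = 10^seq(log10(1 / 1000), log10(1 / 30),
                                             length.out = 41),
                    Gamma_p = 1 / 8, slope_normalized = -0.0294, N_e = 5.4) {
  kp <- matrix(NA_real_, length(NICD0_values), length(Gamma_up_values),
               dimnames = list(signif(NICD0_values, 6),
                               signif(Gamma_up_values, 6)))
  for (i in seq_along(NICD0_values))
    for (j in seq_along(Gamma_up_values))
      kp[i, j] <- tryCatch(
        estimate_kp_from_slope(slope_normalized, NICD0_values[i],
                               Gamma_up_values[j], Gamma_p, N_e),
        error = function(e) NA_real_)
  structure(list(NICD0_values = NICD0_values,
                 Gamma_up_values = Gamma_up_values,
                 kp_values = kp, Gamma_p = Gamma_p,
                 slope_normalized = slope_normalized, N_e = N_e),
            class = "kp_grid")
}

#' @export
print.kp_grid <- function(x, ...) {
  rng <- range(x$kp_values, na.rm = TRUE)
  cat(sprintf("k_p grid %d x %d (NICD0 x Gamma_up): %.3g - %.3g /min (%d masked)\n",
              nrow(x$kp_values), ncol(x$kp_values), rng[1], rng[2],
              sum(is.na(x$kp_values))))
  invisible(x)
}
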