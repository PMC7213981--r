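#' Time course of nuclear NICD pools
#'
#' Numerically integrates the reduced two-variable dynamic equations for
#' the total unphosphorylated and phosphorylated NICD pools, with the
#' bound fractions slaved to the equilibrium site occupancy (binding is
#' much faster than production/degradation). The equations are integrated
#' in physical minutes: the dimensionless right-hand sides (time in units
#' of `1/Gamma_up`) are multiplied by `Gamma_up`. Set
#' `time_unit = "dimensionless"` to integrate in units of `1/Gamma_up`
#' instead (useful for cross-checks).
#'
#' @param params A [kinetic_params()] object.
#' @param times Strictly increasing vector of output times starting at 0
#'   (minutes, or `1/Gamma_up` units in dimensionless mode).
#' @param initial Length-2 vector: initial `(NICD_up, NICD_p)` totals.
#'   Default `c(0, 0)` models the onset of signaling.
#' @param time_unit `"minutes"` (default) or `"dimensionless"`.
#' @param rtol,atol Solver tolerances; `atol` defaults to `1e-10 * NICD0`.
#' @param method A stiff-capable [deSolve::ode()] method.
#' @return Data frame of class `nicd_trajectory` with columns `time`,
#'   `nicd_up`, `nicd_p`, `nicd_tot`.
#' @examples
#' p <- update_params(default_reporter_params(), N_s = 12)
#' integrate_dynamics(p, seq(0, 480, by = 10))
#' @export
integrate_dynamics <- function(params, times, initial = c(0, 0),
                               time_unit = c("minutes", "dimensionless"),
                               rtol = 1e-8, atol = NULL, method = "lsoda") {
  stopifnot(inherits(params, "kinetic_params"))
  time_unit <- match.arg(time_unit)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    abort_domain("`times` must be strictly increasing and start at 0")
  if (length(initial) != 2 || any(!is.finite(initial)) || any(initial < 0))
    abort_domain("`initial` must be two finite non-negative values")

  d <- dimensionless_params(params)
  scale <- if (time_unit == "minutes") params$Gamma_up else 1
  if (is.null(atol)) atol <- max(1e-10 * d$NICD0, 1e-12)

  rhs <- function(t, y, parms) {
    f <- ss_residual(y, d$NICD0, d$N, d$k_alpha, d$k_p_prime, d$Gamma_p_prime)
    list(scale * f)
  }
  out <- tryCatch(
    deSolve::ode(y = c(u = initial[1], p = initial[2]), times = times,
                 func = rhs, parms = NULL, method = method,
                 rtol = rtol, atol = atol),
    warning = function(w) abort_numeric(paste("ODE integration problem:",
                                              conditionMessage(w))),
    error = function(e) abort_numeric(paste("ODE integration failed:",
                                            conditionMessage(e))))
  u <- pmax(out[, "u"], 0)
  p <- pmax(out[, "p"], 0)
  traj <- data.frame(time = out[, "time"], nicd_up = u, nicd_p = p,
                     nicd_tot = u + p)
  class(traj) <- c("nicd_trajectory", "data.frame")
  attr(traj, "time_unit") <- time_unit
  traj
}

#' Sensitivity of NICD levels to signal duration
#'
#' Compares, at a short and a long time after signaling onset (zero
#' initial NICD), the fractional reduction of total NICD caused by (a)
#' adding `Ns_transgene` synthetic SPS sites (faster degradation) and (b)
#' halving the production rate (gene-dose heterozygote), both relative to
#' the unperturbed trajectory. Long-duration processes are sensitive to
#' both perturbations; short-duration processes are much less sensitive to
#' the added binding sites, because site-coupled degradation only bites
#' once occupancy and the phosphorylated pool have built up.
#'
#' @param params_wt Baseline [kinetic_params()] (synthetic sites `N_s`
#'   is overridden to 0 for the baseline genotype).
#' @param Ns_transgene Number of synthetic sites in the transgene genotype.
#' @param t_short,t_long Evaluation times (min), `t_short < t_long`;
#'   `t_long` defaults to 24 relaxation times (`24/Gamma_up`, 2880 min at
#'   the central parameters) and should be close to steady state (checked,
#'   warning if the baseline is further than `steady_frac` from its steady
#'   state).
#' @param steady_frac Relative deviation from steady state tolerated at
#'   `t_long` before warning.
#' @param ... Passed to [integrate_dynamics()].
#' @return Data frame of class `duration_sensitivity` with one row per
#'   evaluation time and columns `time`, `reduction_by_sites`,
#'   `reduction_by_halved_production`.
#' @examples
#' duration_sensitivity(default_reporter_params(), Ns_transgene = 12)
#' @export
duration_sensitivity <- function(params_wt, Ns_transgene = 12L,
                                 t_short = 10, t_long = NULL,
                                 steady_frac = 0.01, ...) {
  stopifnot(inherits(params_wt, "kinetic_params"))
  if (is.null(t_long)) t_long <- 24 / params_wt$Gamma_up
  if (!(t_short < t_long)) abort_domain("`t_short` must be < `t_long`")
  p_wt <- update_params(params_wt, N_s = 0L)
  p_sites <- update_params(params_wt, N_s = as.integer(Ns_transgene))
  p_het <- update_params(p_wt, NICD0 = p_wt$NICD0 / 2)

  times <- sort(unique(c(0, t_short, t_long)))
  tot_at <- function(p) {
    tr <- integrate_dynamics(p, times, ...)
    tr$nicd_tot[match(c(t_short, t_long), tr$time)]
  }
  wt <- tot_at(p_wt); sites <- tot_at(p_sites); het <- tot_at(p_het)

  ss_wt <- steady_state(p_wt)$NICD_tot
  if (abs(wt[2] - ss_wt) > steady_frac * ss_wt)
    warning(sprintf("baseline at t_long is %.1f%% away from steady state",
                    100 * abs(wt[2] - ss_wt) / ss_wt))

  out <- data.frame(time = c(t_short, t_long),
                    reduction_by_sites = 1 - sites / wt,
                    reduction_by_halved_production = 1 - het / wt)
  class(out) <- c("duration_sensitivity", "data.frame")
  attr(out, "Ns_transgene") <- as.integer(Ns_transgene)
  out
}

#' Duration-sensitivity robustness sweep over parameter variants
#'
#' Runs [duration_sensitivity()] for a base parameter set and a list of
#' parameter overrides, collecting the short- and long-time reductions per
#' variant and flagging variants for which the short-duration protection
#' (added sites reducing NICD by less than half as much as halved
#' production at the short time) does not hold.
#'
#' @param base Baseline [kinetic_params()].
#' @param variants Named list; each element is a named list of
#'   [kinetic_params()] field overrides (see [update_params()]). If an
#'   override changes `NICD0`, `Gamma_up` or `Gamma_p` and
#'   `recompute_kp_slope` is non-`NULL`, `k_p` is re-estimated from that
#'   normalized titration slope under the variant's rates.
#' @param recompute_kp_slope Normalized per-site slope used to re-estimate
#'   `k_p` per variant (default -0.0294, the measured reporter slope);
#'   `NULL` keeps the base `k_p`.
#' @param ... Passed to [duration_sensitivity()].
#' @return Data frame of class `robustness_sweep` with one row per variant:
#'   reductions at both times, `short_protected` flag, and `error` message
#'   (NA on success).
#' @export
robustness_sweep <- function(base, variants, recompute_kp_slope = -0.0294,
                             ...) {
  stopifnot(inherits(base, "kinetic_params"))
  if (length(variants) == 0) {
    out <- data.frame(variant = character(), t_short = numeric(),
                      red_sites_short = numeric(), red_prod_short = numeric(),
                      t_long = numeric(), red_sites_long = numeric(),
                      red_prod_long = numeric(), short_protected = logical(),
                      error = character(), stringsAsFactors = FALSE)
    class(out) <- c("robustness_sweep", "data.frame")
    return(out)
  }
  nms <- names(variants) %||% paste0("variant", seq_along(variants))
  rows <- lapply(seq_along(variants), function(i) {
    res <- tryCatch({
      p <- do.call(update_params, c(list(base), variants[[i]]))
      if (!is.null(recompute_kp_slope) && is.null(variants[[i]]$k_p)) {
        kp <- estimate_kp_from_slope(recompute_kp_slope, p$NICD0,
                                     p$Gamma_up, p$Gamma_p, p$N_e)
        p <- update_params(p, k_p = kp)
      }
      ds <- duration_sensitivity(p, ...)
      data.frame(variant = nms[i],
                 t_short = ds$time[1],
                 red_sites_short = ds$reduction_by_sites[1],
                 red_prod_short = ds$reduction_by_halved_production[1],
                 t_long = ds$time[2],
                 red_sites_long = ds$reduction_by_sites[2],
                 red_prod_long = ds$reduction_by_halved_production[2],
                 short_protected = ds$reduction_by_sites[1] <
                   0.5 * ds$reduction_by_halved_production[1],
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(variant = nms[i], t_short = NA_real_,
                 red_sites_short = NA_real_, red_prod_short = NA_real_,
                 t_long = NA_real_, red_sites_long = NA_real_,
                 red_prod_long = NA_real_, short_protected = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_sweep", "data.frame")
  out
}

#' The printed robustness variants
#'
#' The six single-parameter variants explored around the central dynamics
#' parameter set: baseline abundance 200 and 20000 molecules/nucleus,
#' unphosphorylated degradation 1/30 and 1/1000 min^-1 (half-lives 30 min
#' and 1000 min), and phosphorylated degradation 1/4 and 1/30 min^-1.
#'
#' @return Named list of override lists for [robustness_sweep()].
#' @export
sweep_variants_default <- function() {
  list(nicd0_low = list(NICD0 = 200),
       nicd0_high = list(NICD0 = 20000),
       gup_fast = list(Gamma_up = 1 / 30),
       gup_slow = list(Gamma_up = 1 / 1000),
       gp_fast = list(Gamma_p = 1 / 4),
       gp_slow = list(Gamma_p = 1 / 30))
}
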