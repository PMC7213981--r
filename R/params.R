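#' Kinetic parameters of the site-coupled NICD degradation model
#'
#' Bundles all rates and site numbers of the nuclear NICD turnover model.
#' NICD is produced at rate `P_NICD`, degrades at `Gamma_up`
#' (unphosphorylated) or `Gamma_p` (phosphorylated, much faster), and while
#' bound to one of the `N_e + N_s` SPS sites is phosphorylated by the Cdk8
#' kinase module at rate `k_p`. Binding is described thermodynamically by
#' the dissociation constant `k_alpha`; explicit association/dissociation
#' rates `k_on`/`k_off` are only needed by the stochastic simulator.
#'
#' The baseline abundance `NICD0 = P_NICD / Gamma_up` is the steady state
#' with no binding sites. Either `NICD0` or `P_NICD` may be given; the other
#' is derived. If both are given they must agree to 1e-12 relative.
#'
#' @param Gamma_up Degradation rate of unbound unphosphorylated NICD
#'   (min^-1). Corresponds to a half-life of `1/Gamma_up` minutes.
#' @param Gamma_p Degradation rate of unbound phosphorylated NICD (min^-1).
#' @param k_p Phosphorylation rate of bound unphosphorylated NICD (min^-1).
#' @param NICD0 Baseline steady-state abundance (molecules/nucleus).
#' @param P_NICD Nuclear entry (production) rate
#'   (molecules nucleus^-1 min^-1).
#' @param k_alpha Dissociation constant of the NICD complex-SPS interaction
#'   (molecules/nucleus). Default 1: deep strong-binding regime, where
#'   steady-state results are insensitive to its value.
#' @param N_e Effective number of endogenous SPS-equivalent sites
#'   (dimensionless, real-valued, >= 0).
#' @param N_s Number of synthetic SPS sites (integer >= 0).
#' @param k_on,k_off Optional explicit association (molecules^-1 min^-1) and
#'   dissociation (min^-1) rates; must satisfy `k_off/k_on = k_alpha` to
#'   1e-9 relative.
#' @return An object of class `kinetic_params` (a named list).
#' @examples
#' p <- kinetic_params(Gamma_up = 1/120, Gamma_p = 1/8, k_p = 0.5,
#'                     NICD0 = 2000, N_e = 5.4, N_s = 12)
#' dimensionless_params(p)
#' @export
kinetic_params <- function(Gamma_up, Gamma_p, k_p,
                           NICD0 = NULL, P_NICD = NULL,
                           k_alpha = 1, N_e = 0, N_s = 0L,
                           k_on = NULL, k_off = NULL) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      abort_domain(sprintf("`%s` must be a single finite positive number", nm))
  }
  chk_pos(Gamma_up, "Gamma_up"); chk_pos(Gamma_p, "Gamma_p")
  chk_pos(k_alpha, "k_alpha")
  if (!is.numeric(k_p) || length(k_p) != 1L || !is.finite(k_p) || k_p < 0)
    abort_domain("`k_p` must be a single finite number >= 0")
  if (!is.numeric(N_e) || length(N_e) != 1L || !is.finite(N_e) || N_e < 0)
    abort_domain("`N_e` must be a single finite number >= 0")
  if (!is.numeric(N_s) || length(N_s) != 1L || !is.finite(N_s) || N_s < 0 ||
      abs(N_s - round(N_s)) > 1e-9)
    abort_domain("`N_s` must be a single non-negative integer")
  N_s <- as.integer(round(N_s))

  if (is.null(NICD0) && is.null(P_NICD))
    abort_domain("one of `NICD0` or `P_NICD` must be given")
  if (is.null(NICD0)) NICD0 <- P_NICD / Gamma_up
  if (is.null(P_NICD)) P_NICD <- NICD0 * Gamma_up
  chk_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      abort_domain(sprintf("`%s` must be a single finite number >= 0", nm))
  }
  # zero production (a signaling-off nucleus) is a valid degenerate state
  chk_nonneg(NICD0, "NICD0"); chk_nonneg(P_NICD, "P_NICD")
  if (abs(NICD0 - P_NICD / Gamma_up) > 1e-12 * NICD0)
    abort_domain("`NICD0` and `P_NICD`/`Gamma_up` disagree (must match to 1e-12 relative)")

  if (xor(is.null(k_on), is.null(k_off)))
    abort_domain("`k_on` and `k_off` must be given together")
  if (!is.null(k_on)) {
    chk_pos(k_on, "k_on"); chk_pos(k_off, "k_off")
    if (abs(k_off / k_on - k_alpha) > 1e-9 * k_alpha)
      abort_domain("`k_off/k_on` must equal `k_alpha` (to 1e-9 relative)")
  }

  structure(list(P_NICD = P_NICD, NICD0 = NICD0,
                 Gamma_up = Gamma_up, Gamma_p = Gamma_p,
                 k_p = k_p, k_alpha = k_alpha,
                 N_e = N_e, N_s = N_s,
                 k_on = k_on, k_off = k_off),
            class = "kinetic_params")
}

#' Dimensionless parameter group of a kinetic parameter set
#'
#' Rescales rates by the slow degradation rate `Gamma_up`:
#' `Gamma_p_prime = Gamma_p/Gamma_up`, `k_p_prime = k_p/Gamma_up`, and the
#' total site number `N = N_e + N_s`.
#'
#' @param params A [kinetic_params()] object.
#' @return Named list with `NICD0`, `Gamma_p_prime`, `k_p_prime`, `N`,
#'   `k_alpha`.
#' @export
dimensionless_params <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  list(NICD0 = params$NICD0,
       Gamma_p_prime = params$Gamma_p / params$Gamma_up,
       k_p_prime = params$k_p / params$Gamma_up,
       N = params$N_e + params$N_s,
       k_alpha = params$k_alpha)
}

#' Modify a kinetic parameter set
#'
#' Rebuilds a [kinetic_params()] object with some fields replaced,
#' re-running all validation. Overriding `NICD0` drops the stored `P_NICD`
#' (it is re-derived), and vice versa.
#'
#' @param params A [kinetic_params()] object.
#' @param ... Named fields to replace (any argument of [kinetic_params()]).
#' @return A new `kinetic_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  over <- list(...)
  bad <- setdiff(names(over), c("P_NICD", "NICD0", "Gamma_up", "Gamma_p",
                                "k_p", "k_alpha", "N_e", "N_s", "k_on", "k_off"))
  if (length(bad)) abort_config(paste("unknown parameter field(s):",
                                      paste(bad, collapse = ", ")))
  cur <- unclass(params)
  if ("NICD0" %in% names(over) && !("P_NICD" %in% names(over))) cur$P_NICD <- NULL
  if ("P_NICD" %in% names(over) && !("NICD0" %in% names(over))) cur$NICD0 <- NULL
  if ("Gamma_up" %in% names(over) &&
      !any(c("NICD0", "P_NICD") %in% names(over))) cur$P_NICD <- NULL
  cur[names(over)] <- over
  do.call(kinetic_params, cur[!vapply(cur, is.null, logical(1))])
}

#' @export
print.kinetic_params <- function(x, ...) {
  d <- dimensionless_params(x)
  cat("Kinetic parameters (molecules/nucleus, minutes):\n")
  cat(sprintf("  NICD0 = %g  (P_NICD = %g /min)\n", x$NICD0, x$P_NICD))
  cat(sprintf("  Gamma_up = %g /min (half-life %g min), Gamma_p = %g /min\n",
              x$Gamma_up, 1 / x$Gamma_up, x$Gamma_p))
  cat(sprintf("  k_p = %g /min, k_alpha = %g\n", x$k_p, x$k_alpha))
  cat(sprintf("  sites: N_e = %g, N_s = %d (N = %g)\n", x$N_e, x$N_s, d$N))
  if (!is.null(x$k_on))
    cat(sprintf("  k_on = %g, k_off = %g\n", x$k_on, x$k_off))
  cat(sprintf("  dimensionless: k_p' = %g, Gamma_p' = %g\n",
              d$k_p_prime, d$Gamma_p_prime))
  invisible(x)
}

#' Load a shipped parameter preset
#'
#' Presets mirror the parameter sets used throughout the package's
#' worked analyses. `nicd_presets()` lists the available names;
#' `load_preset()` returns the raw configuration list and
#' `preset_params()` builds the corresponding [kinetic_params()] object
#' (estimating `k_p` from a stored normalized titration slope where the
#' preset specifies one).
#'
#' @param name Preset name, one of `nicd_presets()`.
#' @return `load_preset()`: a named list. `preset_params()`: a
#'   `kinetic_params` object.
#' @export
load_preset <- function(name) {
  dir <- system.file("extdata", "presets", package = "nicddrain")
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path))
    abort_config(sprintf("unknown preset '%s'; see nicd_presets()", name))
  yaml::read_yaml(path)
}

#' @rdname load_preset
#' @export
nicd_presets <- function() {
  dir <- system.file("extdata", "presets", package = "nicddrain")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' @rdname load_preset
#' @export
preset_params <- function(name) {
  cfg <- load_preset(name)
  params_from_config(cfg)
}

# Build kinetic_params from a preset/config list. A config may either give
# k_p directly or give slope_normalized (per-site normalized titration
# slope), in which case k_p is back-calculated from the linear regime.
params_from_config <- function(cfg) {
  if (is.null(cfg$k_p)) {
    if (is.null(cfg$slope_normalized))
      abort_config("config must provide either `k_p` or `slope_normalized`")
    cfg$k_p <- estimate_kp_from_slope(cfg$slope_normalized, cfg$NICD0,
                                      cfg$Gamma_up, cfg$Gamma_p,
                                      cfg$N_e %||% 0)
  }
  kinetic_params(Gamma_up = cfg$Gamma_up, Gamma_p = cfg$Gamma_p,
                 k_p = cfg$k_p, NICD0 = cfg$NICD0,
                 k_alpha = cfg$k_alpha %||% 1,
                 N_e = cfg$N_e %||% 0, N_s = cfg$N_s %||% 0L,
                 k_on = cfg$k_on, k_off = cfg$k_off)
}

#' Default parameters of the reporter-titration analysis
#'
#' The central parameter set used for reporter-data work: baseline
#' abundance 2000 molecules/nucleus, unphosphorylated half-life 120 min,
#' phosphorylated half-life 8 min, 5.4 effective endogenous sites, and the
#' phosphorylation rate back-calculated from the measured normalized
#' titration slope of -0.0294 per site (about 0.45 min^-1).
#'
#' @param slope_normalized Normalized per-site titration slope used to set
#'   `k_p`.
#' @param k_alpha Binding dissociation constant (molecules/nucleus).
#' @return A [kinetic_params()] object.
#' @export
default_reporter_params <- function(slope_normalized = -0.0294, k_alpha = 1) {
  kp <- estimate_kp_from_slope(slope_normalized, NICD0 = 2000,
                               Gamma_up = 1 / 120, Gamma_p = 1 / 8, N_e = 5.4)
  kinetic_params(Gamma_up = 1 / 120, Gamma_p = 1 / 8, k_p = kp,
                 NICD0 = 2000, k_alpha = k_alpha, N_e = 5.4, N_s = 0L)
}
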