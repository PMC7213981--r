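#' Simulation specification for synthetic reporter titration data
#'
#' Defines the study conditions emulated by the synthetic per-disc
#' reporter generator: two genotypes (a reference and a mutant whose
#' phosphorylation rate is halved, the expected effect of removing one
#' copy of a limiting Cdk8-kinase-module gene), synthetic site numbers
#' 0/6/12/18, at least eight discs per condition, and multiplicative
#' lognormal per-disc noise. The 15% coefficient of variation is a chosen
#' default (per-disc variance is not tabulated anywhere); fluorescence is
#' assumed proportional to steady-state total NICD.
#'
#' @param params_ref Reference-genotype [kinetic_params()]
#'   (default [default_reporter_params()]).
#' @param params_mut Mutant parameters; default: reference with `k_p/2`.
#' @param ns_values Synthetic site numbers (must include 0).
#' @param n_discs Discs per genotype/site-number condition (>= 2).
#' @param noise_cv Multiplicative coefficient of variation (>= 0).
#' @param reporter_gain Fluorescence units per molecule.
#' @param seed Integer seed (mandatory).
#' @return Object of class `reporter_sim_spec`.
#' @export
reporter_sim_spec <- function(params_ref = default_reporter_params(),
                              params_mut = NULL,
                              ns_values = c(0L, 6L, 12L, 18L),
                              n_discs = 8L, noise_cv = 0.15,
                              reporter_gain = 1, seed) {
  stopifnot(inherits(params_ref, "kinetic_params"))
  if (is.null(params_mut))
    params_mut <- update_params(params_ref, k_p = params_ref$k_p / 2)
  stopifnot(inherits(params_mut, "kinetic_params"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    abort_config("an explicit integer `seed` is mandatory")
  if (!0 %in% ns_values) abort_config("`ns_values` must include 0")
  if (n_discs < 2) abort_config("`n_discs` must be >= 2")
  if (noise_cv < 0) abort_config("`noise_cv` must be >= 0")
  if (reporter_gain <= 0) abort_config("`reporter_gain` must be > 0")
  structure(list(params_ref = params_ref, params_mut = params_mut,
                 ns_values = as.integer(sort(unique(ns_values))),
                 n_discs = as.integer(n_discs), noise_cv = noise_cv,
                 reporter_gain = reporter_gain, seed = as.integer(seed)),
            class = "reporter_sim_spec")
}

#' Generate a synthetic per-disc reporter dataset
#'
#' Per-disc fluorescence values are the steady-state total NICD of the
#' condition's parameters times `reporter_gain`, multiplied by lognormal
#' noise with unit mean and coefficient of variation `noise_cv`.
#' Reproducible given the spec's seed. The generating truth (per-condition
#' expectations, true phosphorylation rates and their ratio, true
#' endogenous site number, true linear-regime slopes) is attached as
#' attribute `"truth"` for recovery tests.
#'
#' @param spec A [reporter_sim_spec()].
#' @return A [reporter_dataset()] with genotypes `"reference"` and
#'   `"mutant"` and attribute `truth`.
#' @examples
#' ds <- gen_reporter_dataset(reporter_sim_spec(seed = 1))
#' head(ds)
#' @export
gen_reporter_dataset <- function(spec) {
  stopifnot(inherits(spec, "reporter_sim_spec"))
  set.seed(spec$seed)
  sdlog <- sqrt(log1p(spec$noise_cv^2))
  genos <- list(reference = spec$params_ref, mutant = spec$params_mut)
  rows <- list()
  expectations <- list()
  for (g in names(genos)) {
    for (ns in spec$ns_values) {
      ss <- tryCatch(steady_state(update_params(genos[[g]], N_s = ns)),
                     error = function(e) abort_numeric(sprintf(
                       "steady state failed for genotype %s, n_sites %d: %s",
                       g, ns, conditionMessage(e))))
      mu <- spec$reporter_gain * ss$NICD_tot
      expectations[[paste(g, ns, sep = "_")]] <- mu
      noise <- if (spec$noise_cv == 0) rep(1, spec$n_discs) else
        stats::rlnorm(spec$n_discs, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rows[[paste(g, ns, sep = "_")]] <- data.frame(
        genotype = g, n_sites = ns,
        disc_id = sprintf("%s_ns%02d_d%02d", g, ns, seq_len(spec$n_discs)),
        value = mu * noise, stringsAsFactors = FALSE)
    }
  }
  ds <- reporter_dataset(do.call(rbind, c(rows, make.row.names = FALSE)))
  lr_ref <- linear_regime(spec$params_ref)
  lr_mut <- linear_regime(spec$params_mut)
  attr(ds, "truth") <- list(
    expectations = unlist(expectations),
    k_p_ref = spec$params_ref$k_p, k_p_mut = spec$params_mut$k_p,
    ratio = spec$params_ref$k_p / spec$params_mut$k_p,
    N_e = spec$params_ref$N_e,
    slope_normalized_ref = lr_ref$slope_normalized,
    slope_normalized_mut = lr_mut$slope_normalized,
    seed = spec$seed)
  ds
}

#' Simulation specification for synthetic decay curves
#'
#' Decay curves follow the decreasing Hill function ([hill_decay()]) plus
#' additive Gaussian noise, sampled on 17 timepoints over 0-480 min in
#' replicate wells, then renormalized so each replicate is 1 at time zero
#' (mirroring per-well normalization to the first reading).
#'
#' @param t05 True half-life (min).
#' @param n_hill True Hill coefficient (in (0, 10]).
#' @param bg True background fraction in [0, 1).
#' @param timepoints Sampling times (min), starting at 0.
#' @param n_replicates Number of replicate wells.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed (mandatory).
#' @return Object of class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(t05 = 120, n_hill = 2, bg = 0.1,
                           timepoints = seq(0, 480, length.out = 17),
                           n_replicates = 3L, noise_sd = 0.05, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    abort_config("an explicit integer `seed` is mandatory")
  if (t05 <= 0 || n_hill <= 0 || n_hill > 10 || bg < 0 || bg >= 1)
    abort_config("decay parameters out of range (t05>0, n_hill in (0,10], bg in [0,1))")
  if (length(timepoints) < 4 || timepoints[1] != 0 ||
      any(diff(timepoints) <= 0))
    abort_config("`timepoints` must start at 0, be increasing, length >= 4")
  if (n_replicates < 1) abort_config("`n_replicates` must be >= 1")
  if (noise_sd < 0) abort_config("`noise_sd` must be >= 0")
  structure(list(t05 = t05, n_hill = n_hill, bg = bg,
                 timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "decay_sim_spec")
}

#' Generate synthetic normalized decay curves
#'
#' @param spec A [decay_sim_spec()].
#' @return A [decay_curve()] with attribute `truth` (the generating
#'   parameters).
#' @examples
#' gen_decay_curves(decay_sim_spec(seed = 1))
#' @export
gen_decay_curves <- function(spec) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  set.seed(spec$seed)
  rows <- lapply(seq_len(spec$n_replicates), function(r) {
    v <- hill_decay(spec$timepoints, spec$t05, spec$n_hill, spec$bg)
    if (spec$noise_sd > 0)
      v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
    v <- v / v[1]  # per-well renormalization to the first reading
    data.frame(time_min = spec$timepoints, replicate = r, value = v)
  })
  curve <- decay_curve(do.call(rbind, rows))
  attr(curve, "truth") <- list(t05 = spec$t05, n_hill = spec$n_hill,
                               bg = spec$bg, seed = spec$seed)
  curve
}
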