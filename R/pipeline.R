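# Pipeline layer: one run_* function per command, each a thin wrapper over
# the modelling/inference functions that reads a config list (or YAML
# file), writes CSV/JSON outputs with a provenance block, and raises
# nicddrain_config_error / nicddrain_numeric_error so the CLI can map them
# to exit codes.

#' Read a run configuration file
#'
#' Configurations are YAML mappings; each command reads the keys it
#' documents and rejects unknown ones.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(paste("no such config file:", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) abort_config(paste(
                    "could not parse config:", conditionMessage(e))))
  if (!is.list(cfg)) abort_config("config must be a YAML mapping")
  cfg
}

check_config_keys <- function(cfg, allowed, command) {
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    abort_config(sprintf("unknown config key(s) for %s: %s", command,
                         paste(bad, collapse = ", ")))
}

provenance <- function(cfg, seed = NULL) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  list(package = "nicddrain",
       version = as.character(utils::packageVersion("nicddrain")),
       config_hash = unname(tools::md5sum(tmp)),
       seed = seed)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

config_params <- function(cfg) {
  if (!is.null(cfg$preset)) preset_params(cfg$preset)
  else if (!is.null(cfg$params)) params_from_config(cfg$params)
  else abort_config("config needs a `preset` name or a `params` block")
}

#' Run the pipeline commands
#'
#' Each `run_*()` executes one stage end to end and writes its outputs
#' under `out_dir`:
#' \describe{
#'   \item{`run_steady()`}{steady-state titration curve
#'     (`titration.csv`: `n_sites, nicd_up, nicd_p, nicd_tot,
#'     nicd_tot_norm`). Config keys: `preset` or `params`, optional
#'     `ns_values`.}
#'   \item{`run_dynamics()`}{time courses for the baseline, halved
#'     production, and added-sites genotypes (`trajectory_*.csv`) plus a
#'     `duration_sensitivity.json` summary. Keys: `preset`/`params`,
#'     optional `times`, `Ns_transgene`, `t_short`, `t_long`.}
#'   \item{`run_kp_grid()`}{phosphorylation-rate grid (`kp_grid.csv`
#'     matrix and `kp_grid_axes.json` sidecar). Keys: `preset`/`params`
#'     not used; optional `NICD0_values`, `Gamma_up_values`, `Gamma_p`,
#'     `slope_normalized`, `N_e`.}
#'   \item{`run_fit_reporter()`}{reporter inference from a per-disc CSV
#'     (`reporter_fit.json`). Keys: optional `reference`, `mutant`,
#'     `points_ref`, `points_mut`, `NICD0`, `Gamma_up`, `Gamma_p`,
#'     `weighted`.}
#'   \item{`run_fit_decay()`}{Hill-decay fit from a decay CSV
#'     (`decay_fit.json`). Keys: optional `ci_method`, `n_boot`, `seed`.}
#'   \item{`run_synth()`}{synthetic datasets + ground-truth JSON. Keys:
#'     `kind` ("reporter" or "decay"), `seed` (required), plus the
#'     corresponding sim-spec fields.}
#' }
#' Every JSON output carries a provenance block (package version, config
#' hash, seed).
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @param input_csv Input data file (fit commands).
#' @return Invisibly, a list with the computed objects and output paths.
#' @name pipeline
NULL

as_config <- function(config) {
  if (is.character(config) && length(config) == 1L) read_run_config(config)
  else if (is.list(config)) config
  else abort_config("`config` must be a list or a YAML file path")
}

#' @rdname pipeline
#' @export
run_steady <- function(config, out_dir) {
  cfg <- as_config(config)
  check_config_keys(cfg, c("preset", "params", "ns_values"), "steady")
  params <- config_params(cfg)
  ns <- cfg$ns_values %||% c(0L, 6L, 12L, 18L)
  curve <- titration_curve(params, ns)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "titration.csv")
  utils::write.csv(as.data.frame(curve), csv, row.names = FALSE)
  write_json_out(list(provenance = provenance(cfg)),
                 file.path(out_dir, "titration_provenance.json"))
  invisible(list(curve = curve, csv = csv))
}

#' @rdname pipeline
#' @export
run_dynamics <- function(config, out_dir) {
  cfg <- as_config(config)
  check_config_keys(cfg, c("preset", "params", "times", "Ns_transgene",
                           "t_short", "t_long"), "dynamics")
  params <- config_params(cfg)
  t_long <- cfg$t_long %||% (24 / params$Gamma_up)
  t_short <- cfg$t_short %||% 10
  times <- cfg$times %||% seq(0, t_long, length.out = 289)
  ns_tg <- cfg$Ns_transgene %||% 12L
  genos <- list(baseline = update_params(params, N_s = 0L),
                added_sites = update_params(params, N_s = as.integer(ns_tg)),
                halved_production = update_params(params, N_s = 0L,
                                                  NICD0 = params$NICD0 / 2))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  trajs <- lapply(names(genos), function(g) {
    tr <- integrate_dynamics(genos[[g]], times)
    f <- file.path(out_dir, sprintf("trajectory_%s.csv", g))
    utils::write.csv(as.data.frame(tr), f, row.names = FALSE)
    paths[[g]] <<- f
    tr
  })
  names(trajs) <- names(genos)
  ds <- duration_sensitivity(update_params(params, N_s = 0L),
                             Ns_transgene = ns_tg, t_short = t_short,
                             t_long = t_long)
  write_json_out(list(duration_sensitivity =
                        lapply(seq_len(nrow(ds)), function(i) as.list(ds[i, ])),
                      provenance = provenance(cfg)),
                 file.path(out_dir, "duration_sensitivity.json"))
  invisible(list(trajectories = trajs, duration = ds, paths = paths))
}

#' @rdname pipeline
#' @export
run_kp_grid <- function(config, out_dir) {
  cfg <- as_config(config)
  check_config_keys(cfg, c("preset", "NICD0_values", "Gamma_up_values",
                           "Gamma_p", "slope_normalized", "N_e"), "kp-grid")
  if (!is.null(cfg$preset)) cfg <- utils::modifyList(load_preset(cfg$preset),
                                                     cfg[names(cfg) != "preset"])
  args <- cfg[intersect(names(cfg), c("NICD0_values", "Gamma_up_values",
                                      "Gamma_p", "slope_normalized", "N_e"))]
  grid <- do.call(kp_grid, args)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "kp_grid.csv")
  utils::write.csv(as.data.frame(grid$kp_values), csv, row.names = TRUE)
  write_json_out(list(NICD0_values = grid$NICD0_values,
                      Gamma_up_values = grid$Gamma_up_values,
                      Gamma_p = grid$Gamma_p,
                      slope_normalized = grid$slope_normalized,
                      N_e = grid$N_e,
                      provenance = provenance(cfg)),
                 file.path(out_dir, "kp_grid_axes.json"))
  invisible(list(grid = grid, csv = csv))
}

#' @rdname pipeline
#' @export
run_fit_reporter <- function(config, input_csv, out_dir) {
  cfg <- as_config(config)
  check_config_keys(cfg, c("reference", "mutant", "points_ref", "points_mut",
                           "NICD0", "Gamma_up", "Gamma_p", "weighted"),
                    "fit-reporter")
  ds <- read_reporter_csv(input_csv,
                          reference = cfg$reference %||% "reference",
                          mutant = cfg$mutant %||% "mutant")
  an <- analyze_reporter(ds,
                         points_ref = cfg$points_ref %||% c(0, 6, 12),
                         points_mut = cfg$points_mut %||% c(0, 6, 12, 18),
                         NICD0 = cfg$NICD0 %||% 2000,
                         Gamma_up = cfg$Gamma_up %||% (1 / 120),
                         Gamma_p = cfg$Gamma_p %||% (1 / 8),
                         weighted = isTRUE(cfg$weighted))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit_json <- function(f) list(genotype = f$genotype, slope = f$slope,
                               intercept = f$intercept,
                               covariance = f$covariance,
                               n_points = f$n_points,
                               points_used = f$points_used)
  out <- list(fits = list(reference = fit_json(an$fits$reference),
                          mutant = fit_json(an$fits$mutant)),
              ratio = list(ratio = an$ratio$ratio, se = an$ratio$se,
                           ci95 = an$ratio$ci95),
              ne = list(n_e = an$ne$n_e, se = an$ne$se, ci95 = an$ne$ci95),
              kp = an$kp,
              inputs = c(an$config, list(input_csv = input_csv)),
              provenance = provenance(cfg))
  path <- file.path(out_dir, "reporter_fit.json")
  write_json_out(out, path)
  invisible(list(analysis = an, json = path))
}

#' @rdname pipeline
#' @export
run_fit_decay <- function(config, input_csv, out_dir) {
  cfg <- as_config(config)
  check_config_keys(cfg, c("ci_method", "n_boot", "seed"), "fit-decay")
  curve <- read_decay_csv(input_csv)
  fit <- fit_hill_decay(curve, ci_method = cfg$ci_method %||% "bootstrap",
                        n_boot = cfg$n_boot %||% 1000L, seed = cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "decay_fit.json")
  write_json_out(list(t05 = fit$t05, n_hill = fit$n_hill, bg = fit$bg,
                      rss = fit$rss, ci95 = fit$ci95,
                      ci_method = fit$ci_method, seed = fit$seed,
                      provenance = provenance(cfg, seed = cfg$seed)),
                 path)
  invisible(list(fit = fit, json = path))
}

#' @rdname pipeline
#' @export
run_synth <- function(config, out_dir) {
  cfg <- as_config(config)
  kind <- cfg$kind %||% "reporter"
  if (is.null(cfg$seed)) abort_config("synthetic data generation requires a `seed`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "reporter") {
    check_config_keys(cfg, c("kind", "seed", "params_ref", "ns_values",
                             "n_discs", "noise_cv", "reporter_gain"), "synth")
    pref <- if (is.null(cfg$params_ref)) default_reporter_params()
            else params_from_config(cfg$params_ref)
    spec <- reporter_sim_spec(params_ref = pref,
                              ns_values = cfg$ns_values %||% c(0, 6, 12, 18),
                              n_discs = cfg$n_discs %||% 8L,
                              noise_cv = cfg$noise_cv %||% 0.15,
                              reporter_gain = cfg$reporter_gain %||% 1,
                              seed = cfg$seed)
    ds <- gen_reporter_dataset(spec)
    csv <- file.path(out_dir, "reporter_synthetic.csv")
    write_reporter_csv(ds, csv)
    write_json_out(c(attr(ds, "truth"), list(provenance = provenance(cfg,
                                                                     seed = cfg$seed))),
                   file.path(out_dir, "reporter_truth.json"))
    invisible(list(dataset = ds, csv = csv))
  } else if (kind == "decay") {
    check_config_keys(cfg, c("kind", "seed", "t05", "n_hill", "bg",
                             "timepoints", "n_replicates", "noise_sd"),
                      "synth")
    spec <- decay_sim_spec(t05 = cfg$t05 %||% 120,
                           n_hill = cfg$n_hill %||% 2,
                           bg = cfg$bg %||% 0.1,
                           timepoints = cfg$timepoints %||%
                             seq(0, 480, length.out = 17),
                           n_replicates = cfg$n_replicates %||% 3L,
                           noise_sd = cfg$noise_sd %||% 0.05,
                           seed = cfg$seed)
    curve <- gen_decay_curves(spec)
    csv <- file.path(out_dir, "decay_synthetic.csv")
    write_decay_csv(curve, csv)
    write_json_out(c(attr(curve, "truth"),
                     list(provenance = provenance(cfg, seed = cfg$seed))),
                   file.path(out_dir, "decay_truth.json"))
    invisible(list(curve = curve, csv = csv))
  } else abort_config("`kind` must be 'reporter' or 'decay'")
}
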