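#' Per-disc reporter titration dataset
#'
#' Container for reporter fluorescence measurements across genotypes and
#' synthetic site numbers: one row per imaginal disc, with the mean
#' fluorescence of the readout reporter in that disc. Two genotype labels
#' are expected, a reference (e.g. wild type) and a mutant with altered
#' phosphorylation activity (e.g. a Cdk8-kinase-module heterozygote).
#'
#' @param data Data frame with columns `genotype`, `n_sites`, `disc_id`,
#'   `value`.
#' @param reference,mutant Genotype labels in `data`.
#' @return Data frame of class `reporter_dataset` carrying attributes
#'   `normalized` (flag), `normalization_constant`, `reference`, `mutant`.
#' @export
reporter_dataset <- function(data, reference = "reference",
                             mutant = "mutant") {
  need <- c("genotype", "n_sites", "disc_id", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    abort_config(paste("reporter data must have columns:",
                       paste(need, collapse = ", ")))
  data <- as.data.frame(data)[need]
  if (!all(data$genotype %in% c(reference, mutant)))
    abort_config("`genotype` contains labels other than the reference/mutant")
  if (any(!is.finite(data$value)))
    abort_config("`value` must be finite")
  if (any(data$n_sites < 0 | data$n_sites != round(data$n_sites)))
    abort_config("`n_sites` must be non-negative integers")
  data$n_sites <- as.integer(data$n_sites)
  structure(data,
            normalized = FALSE, normalization_constant = NA_real_,
            reference = reference, mutant = mutant,
            class = c("reporter_dataset", "data.frame"))
}

#' Normalize a reporter dataset to the reference zero-site baseline
#'
#' Divides every fluorescence value (both genotypes) by the mean value of
#' the reference genotype at `n_sites = 0`, so the reference baseline has
#' mean exactly 1. A single constant is used for the whole dataset, so
#' slope ratios and crossing points are unaffected by it. Idempotent.
#'
#' @param ds A [reporter_dataset()].
#' @return The normalized `reporter_dataset` (attribute `normalized` set,
#'   `normalization_constant` recorded in original units).
#' @export
normalize_reporter <- function(ds) {
  stopifnot(inherits(ds, "reporter_dataset"))
  if (isTRUE(attr(ds, "normalized"))) return(ds)
  ref <- attr(ds, "reference")
  base <- ds$value[ds$genotype == ref & ds$n_sites == 0]
  if (length(base) == 0)
    abort_config("no reference-genotype rows with n_sites = 0 to normalize by")
  const <- mean(base)
  ds$value <- ds$value / const
  attr(ds, "normalized") <- TRUE
  attr(ds, "normalization_constant") <- const
  ds
}

#' Read / write the reporter CSV schema
#'
#' CSV columns (header required): `genotype,n_sites,disc_id,value`.
#'
#' @param path File path.
#' @param reference,mutant Genotype labels (see [reporter_dataset()]).
#' @param ds A [reporter_dataset()] to write.
#' @return `read_reporter_csv()`: a [reporter_dataset()];
#'   `write_reporter_csv()`: the path, invisibly.
#' @export
read_reporter_csv <- function(path, reference = "reference",
                              mutant = "mutant") {
  if (!file.exists(path)) abort_config(paste("no such file:", path))
  reporter_dataset(utils::read.csv(path, stringsAsFactors = FALSE),
                   reference = reference, mutant = mutant)
}

#' @rdname read_reporter_csv
#' @export
write_reporter_csv <- function(ds, path) {
  stopifnot(inherits(ds, "reporter_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' Least-squares line through per-condition reporter means
#'
#' Ordinary least squares of the per-condition mean fluorescence against
#' synthetic site number, one point per distinct site count (mirroring
#' regression on condition means rather than on individual discs). The
#' saturated high-site-number condition of the reference genotype is
#' excluded by restricting `points_used`. The parameter covariance comes
#' from the residual variance of the means fit; with only two points the
#' fit is exact and the covariance is zero-filled and flagged.
#'
#' @param ds A normalized [reporter_dataset()].
#' @param genotype Genotype label to fit.
#' @param points_used Site counts to include (default: all present).
#' @param weighted If `TRUE`, weight condition means by inverse squared
#'   SEM (off by default; the default mirrors an unweighted means fit).
#' @return Object of class `reporter_line_fit`: `slope`, `intercept`,
#'   `covariance` (2x2, order intercept then slope), `n_points`,
#'   `points_used`, `exact_fit` flag, `genotype`.
#' @export
fit_reporter_line <- function(ds, genotype, points_used = NULL,
                              weighted = FALSE) {
  stopifnot(inherits(ds, "reporter_dataset"))
  if (!isTRUE(attr(ds, "normalized")))
    abort_config("dataset must be normalized first (see normalize_reporter())")
  sub <- ds[ds$genotype == genotype, , drop = FALSE]
  if (nrow(sub) == 0) abort_config(paste("no rows for genotype", genotype))
  if (is.null(points_used)) points_used <- sort(unique(sub$n_sites))
  sub <- sub[sub$n_sites %in% points_used, , drop = FALSE]
  agg <- stats::aggregate(value ~ n_sites, sub,
                          function(v) c(m = mean(v), s = stats::sd(v),
                                        n = length(v)))
  means <- data.frame(n_sites = agg$n_sites, m = agg$value[, "m"],
                      sem = agg$value[, "s"] / sqrt(agg$value[, "n"]))
  if (nrow(means) < 2)
    abort_config("need at least 2 distinct site counts to fit a line")
  w <- if (weighted) 1 / means$sem^2 else rep(1, nrow(means))
  fit <- stats::lm(m ~ n_sites, data = means,
                   weights = if (weighted) w else NULL)
  cf <- stats::coef(fit)
  exact <- nrow(means) == 2
  if (exact) {
    covm <- matrix(0, 2, 2)
  } else {
    # residual-variance covariance computed directly (avoids summary.lm
    # complaints on exactly collinear means)
    X <- cbind(1, means$n_sites)
    sigma2 <- sum(w * stats::resid(fit)^2) / (nrow(means) - 2)
    covm <- sigma2 * solve(t(X) %*% (w * X))
  }
  dimnames(covm) <- list(c("intercept", "slope"), c("intercept", "slope"))
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 covariance = covm, n_points = nrow(means),
                 points_used = means$n_sites, exact_fit = exact,
                 genotype = genotype, means = means),
            class = "reporter_line_fit")
}

#' @export
print.reporter_line_fit <- function(x, ...) {
  cat(sprintf("Line fit [%s]: slope %.6g +/- %.2g per site, intercept %.6g (n = %d)\n",
              x$genotype, x$slope, sqrt(x$covariance[2, 2]), x$intercept,
              x$n_points))
  invisible(x)
}

#' Ratio of reference to mutant titration slopes
#'
#' Point estimate and first-order (delta-method) standard error of
#' `slope_ref / slope_mut`, assuming independence between the two genotype
#' fits: `var(r) = var(s_ref)/s_mut^2 + s_ref^2 var(s_mut)/s_mut^4`. In
#' the linear regime this ratio equals the phosphorylation-rate ratio of
#' the two genotypes, so a mutant with half the Cdk8 activity gives 2.
#' The 95% interval uses the normal approximation (`ratio +/- 1.96 se`);
#' no small-sample t correction is applied.
#'
#' @param fit_ref,fit_mut [fit_reporter_line()] results for the reference
#'   and mutant genotypes.
#' @return Object of class `slope_ratio`: `ratio`, `se`, `ci95`.
#' @export
slope_ratio <- function(fit_ref, fit_mut) {
  stopifnot(inherits(fit_ref, "reporter_line_fit"),
            inherits(fit_mut, "reporter_line_fit"))
  if (fit_mut$slope == 0) abort_domain("mutant slope is zero; ratio undefined")
  sr <- fit_ref$slope; sm <- fit_mut$slope
  vr <- fit_ref$covariance[2, 2]; vm <- fit_mut$covariance[2, 2]
  ratio <- sr / sm
  se <- sqrt(vr / sm^2 + sr^2 * vm / sm^4)
  structure(list(ratio = ratio, se = se,
                 ci95 = c(ratio - 1.96 * se, ratio + 1.96 * se)),
            class = "slope_ratio")
}

#' @export
print.slope_ratio <- function(x, ...) {
  cat(sprintf("Slope ratio (reference/mutant): %.4g +/- %.3g (95%% CI %.4g - %.4g)\n",
              x$ratio, x$se, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Effective endogenous site number from the line crossing
#'
#' The two genotype lines cross where the synthetic sites exactly cancel
#' the genotypes' differing per-site degradation, which happens at
#' `N_s = -N_e`: extrapolating the fitted lines to their crossing abscissa
#' `x* = (b_mut - b_ref)/(s_ref - s_mut)` and negating gives the effective
#' number of endogenous SPS-equivalent sites. The standard error is a
#' first-order delta method over the four fit parameters, using each
#' fit's internal intercept-slope covariance and independence between
#' genotypes.
#'
#' @param fit_ref,fit_mut [fit_reporter_line()] results.
#' @return Object of class `ne_estimate`: `n_e`, `se`, `ci95`.
#' @export
estimate_ne <- function(fit_ref, fit_mut) {
  stopifnot(inherits(fit_ref, "reporter_line_fit"),
            inherits(fit_mut, "reporter_line_fit"))
  ds <- fit_ref$slope - fit_mut$slope
  if (abs(ds) <= 1e-12 * (abs(fit_ref$slope) + abs(fit_mut$slope)))
    abort_domain("slopes are equal: lines are parallel, no crossing")
  db <- fit_mut$intercept - fit_ref$intercept
  # crossing abscissa x* = db/ds; the lines cross at N_s = -N_e
  n_e <- -db / ds
  # gradient of n_e wrt (b_ref, s_ref, b_mut, s_mut)
  g_ref <- c(1 / ds, db / ds^2)
  g_mut <- c(-1 / ds, -db / ds^2)
  v <- drop(t(g_ref) %*% fit_ref$covariance %*% g_ref +
            t(g_mut) %*% fit_mut$covariance %*% g_mut)
  se <- sqrt(max(v, 0))
  structure(list(n_e = n_e, se = se,
                 ci95 = c(n_e - 1.96 * se, n_e + 1.96 * se)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Effective endogenous sites N_e = %.4g +/- %.3g\n", x$n_e, x$se))
  invisible(x)
}

#' Phosphorylation rate implied by a fitted reference slope
#'
#' Thin wrapper passing the fitted normalized slope of the reference
#' genotype to [estimate_kp_from_slope()].
#'
#' @param fit_ref A [fit_reporter_line()] result on normalized data.
#' @param NICD0,Gamma_up,Gamma_p,n_e Model parameters (see
#'   [estimate_kp_from_slope()]).
#' @return `k_p` (min^-1).
#' @export
infer_kp <- function(fit_ref, NICD0, Gamma_up, Gamma_p, n_e) {
  stopifnot(inherits(fit_ref, "reporter_line_fit"))
  estimate_kp_from_slope(fit_ref$slope, NICD0, Gamma_up, Gamma_p, n_e)
}

#' Full reporter-titration analysis
#'
#' Runs the whole inference chain on a per-disc dataset: normalization to
#' the reference zero-site baseline, per-genotype line fits on condition
#' means, slope ratio with delta-method error, crossing-point estimate of
#' the effective endogenous site number, and back-calculation of the
#' phosphorylation rate under the supplied model parameters.
#'
#' @param ds A [reporter_dataset()] (raw or normalized).
#' @param points_ref,points_mut Site counts used per genotype; the default
#'   excludes the saturated 18-site reference condition.
#' @param NICD0,Gamma_up,Gamma_p Model parameters for the `k_p`
#'   back-calculation.
#' @param weighted Passed to [fit_reporter_line()].
#' @return Object of class `reporter_analysis`: list with `fits`, `ratio`,
#'   `ne`, `kp`, and the configuration used.
#' @export
analyze_reporter <- function(ds, points_ref = c(0, 6, 12),
                             points_mut = c(0, 6, 12, 18),
                             NICD0 = 2000, Gamma_up = 1 / 120,
                             Gamma_p = 1 / 8, weighted = FALSE) {
  ds <- normalize_reporter(ds)
  fit_ref <- fit_reporter_line(ds, attr(ds, "reference"), points_ref,
                               weighted = weighted)
  fit_mut <- fit_reporter_line(ds, attr(ds, "mutant"), points_mut,
                               weighted = weighted)
  ratio <- slope_ratio(fit_ref, fit_mut)
  ne <- estimate_ne(fit_ref, fit_mut)
  kp <- tryCatch(infer_kp(fit_ref, NICD0, Gamma_up, Gamma_p,
                          max(ne$n_e, 0)),
                 error = function(e) NA_real_)
  structure(list(fits = list(reference = fit_ref, mutant = fit_mut),
                 ratio = ratio, ne = ne, kp = kp,
                 config = list(points_ref = points_ref,
                               points_mut = points_mut, NICD0 = NICD0,
                               Gamma_up = Gamma_up, Gamma_p = Gamma_p,
                               weighted = weighted,
                               normalization_constant =
                                 attr(ds, "normalization_constant"))),
            class = "reporter_analysis")
}

#' @export
print.reporter_analysis <- function(x, ...) {
  print(x$fits$reference); print(x$fits$mutant)
  print(x$ratio); print(x$ne)
  cat(sprintf("Implied phosphorylation rate k_p = %.4g /min\n", x$kp))
  invisible(x)
}
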