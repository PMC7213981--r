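#' Decreasing Hill decay function
#'
#' The empirical decay form used for normalized luminescence signals that
#' do not follow simple exponential decay:
#' \deqn{f(t) = \frac{t_{0.5}^n + bg\, t^n}{t_{0.5}^n + t^n}}
#' with half-life `t05`, Hill coefficient `n_hill` and background `bg`.
#' It equals 1 at `t = 0`, `(1 + bg)/2` at `t = t05`, and decreases
#' monotonically to `bg` as `t` grows.
#'
#' @param t Time (min, >= 0); vectorized.
#' @param t05 Half-life (min, > 0).
#' @param n_hill Hill coefficient (> 0).
#' @param bg Background fraction in `[0, 1)`.
#' @return Signal values in `(bg, 1]`.
#' @examples
#' hill_decay(c(0, 120, 1e6), t05 = 120, n_hill = 2, bg = 0.1)
#' @export
hill_decay <- function(t, t05, n_hill, bg) {
  if (any(!is.finite(t)) || any(t < 0)) abort_domain("`t` must be finite and >= 0")
  for (v in list(t05, n_hill, bg))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort_domain("parameters must be single finite numbers")
  if (t05 <= 0) abort_domain("`t05` must be > 0")
  if (n_hill <= 0) abort_domain("`n_hill` must be > 0")
  if (bg < 0 || bg >= 1) abort_domain("`bg` must be in [0, 1)")
  # divide through by t05^n for stability at large t/t05
  r <- (t / t05)^n_hill
  (1 + bg * r) / (1 + r)
}

#' Normalized decay curve container
#'
#' One or more replicate time series of a normalized decay signal
#' (luminescence divided by its value at time zero, so every replicate
#' starts at 1).
#'
#' @param data Data frame with columns `time_min`, `replicate`, `value`.
#' @param normalize If `TRUE`, divide each replicate by its first value.
#' @param tol Tolerance on the first value being 1.
#' @return Data frame of class `decay_curve`.
#' @export
decay_curve <- function(data, normalize = FALSE, tol = 1e-6) {
  need <- c("time_min", "replicate", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    abort_config(paste("decay data must have columns:",
                       paste(need, collapse = ", ")))
  data <- as.data.frame(data)[need]
  if (any(!is.finite(data$time_min)) || any(data$time_min < 0) ||
      any(!is.finite(data$value)))
    abort_config("times must be finite and >= 0, values finite")
  data <- data[order(data$replicate, data$time_min), ]
  for (r in unique(data$replicate)) {
    sub <- data$replicate == r
    tt <- data$time_min[sub]
    if (length(tt) < 4)
      abort_config(sprintf("replicate %s has fewer than 4 timepoints", r))
    if (any(diff(tt) <= 0))
      abort_config(sprintf("replicate %s has non-increasing times", r))
    if (normalize) data$value[sub] <- data$value[sub] / data$value[sub][1]
    if (abs(data$value[sub][1] - 1) > tol)
      abort_config(sprintf(
        "replicate %s is not normalized to 1 at its first timepoint", r))
  }
  structure(data, class = c("decay_curve", "data.frame"))
}

#' Read / write the decay-curve CSV schema
#'
#' CSV columns (header required): `time_min,replicate,value`.
#'
#' @param path File path.
#' @param curve A [decay_curve()] to write.
#' @param ... Passed to [decay_curve()].
#' @return `read_decay_csv()`: a [decay_curve()]; `write_decay_csv()`:
#'   the path, invisibly.
#' @export
read_decay_csv <- function(path, ...) {
  if (!file.exists(path)) abort_config(paste("no such file:", path))
  decay_curve(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' @rdname read_decay_csv
#' @export
write_decay_csv <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Fit the decreasing Hill function to a decay curve
#'
#' Pooled nonlinear least squares of [hill_decay()] over all replicates
#' jointly (one parameter set per condition), with bounds `t05 > 0`,
#' `n_hill` in (0, 10], `bg` in [0, 1). Initialization: `bg0 = min(value)`,
#' `t05_0` = the time whose value is closest to `(1 + bg0)/2`, `n0 = 2`.
#' 95% intervals come either from a seeded bootstrap (resampling
#' replicates, or residuals when there is a single replicate) or from the
#' asymptotic covariance of the least-squares fit.
#'
#' @param curve A [decay_curve()].
#' @param ci_method `"bootstrap"` (default) or `"covariance"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed (required for the bootstrap).
#' @return Object of class `hill_decay_fit`: `t05`, `n_hill`, `bg`, `rss`,
#'   `ci95` (3x2 matrix, rows t05/n_hill/bg), `ci_method`, `seed`.
#' @examples
#' spec <- decay_sim_spec(t05 = 120, n_hill = 2, bg = 0.1, seed = 7)
#' fit_hill_decay(gen_decay_curves(spec), seed = 7)
#' @export
fit_hill_decay <- function(curve, ci_method = c("bootstrap", "covariance"),
                           n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(curve, "decay_curve"))
  ci_method <- match.arg(ci_method)
  if (ci_method == "bootstrap" &&
      (is.null(seed) || !is.finite(seed)))
    abort_config("bootstrap confidence intervals require an explicit `seed`")
  if (stats::sd(curve$value) == 0)
    abort_domain("decay values are constant; nothing to fit")

  fit <- hill_fit_core(curve$time_min, curve$value)
  est <- fit$par

  ci <- matrix(NA_real_, 3, 2, dimnames = list(c("t05", "n_hill", "bg"),
                                               c("low", "high")))
  if (ci_method == "covariance") {
    se <- tryCatch(sqrt(diag(stats::vcov(fit$nls))), error = function(e) rep(NA_real_, 3))
    ci[, 1] <- est - 1.96 * se
    ci[, 2] <- est + 1.96 * se
  } else {
    set.seed(as.integer(seed))
    reps <- unique(curve$replicate)
    boot <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      if (length(reps) > 1) {
        pick <- sample(reps, length(reps), replace = TRUE)
        dat <- do.call(rbind, lapply(pick, function(r)
          curve[curve$replicate == r, c("time_min", "value")]))
      } else {
        res <- curve$value - hill_decay(curve$time_min, est[1], est[2], est[3])
        dat <- data.frame(time_min = curve$time_min,
                          value = hill_decay(curve$time_min, est[1], est[2],
                                             est[3]) +
                            sample(res, length(res), replace = TRUE))
      }
      bf <- tryCatch(hill_fit_core(dat$time_min, dat$value, start = est),
                     error = function(e) NULL)
      if (!is.null(bf)) boot[b, ] <- bf$par
    }
    qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci[, 1] <- qs[1, ]; ci[, 2] <- qs[2, ]
  }

  structure(list(t05 = est[1], n_hill = est[2], bg = est[3],
                 rss = fit$rss, ci95 = ci, ci_method = ci_method,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "hill_decay_fit")
}

hill_fit_core <- function(t, v, start = NULL) {
  if (is.null(start)) {
    bg0 <- max(min(v), 0)
    bg0 <- min(bg0, 0.98)
    target <- (1 + bg0) / 2
    t05_0 <- t[which.min(abs(v - target))]
    if (t05_0 <= 0) t05_0 <- min(t[t > 0]) / 2
    start <- c(t05 = t05_0, n_hill = 2, bg = bg0)
  }
  names(start) <- c("t05", "n_hill", "bg")
  dat <- data.frame(t = t, v = v)
  nls <- tryCatch(
    minpack.lm::nlsLM(v ~ (1 + bg * (t / t05)^n_hill) / (1 + (t / t05)^n_hill),
                      data = dat, start = as.list(start),
                      lower = c(t05 = 1e-8, n_hill = 1e-8, bg = 0),
                      upper = c(t05 = Inf, n_hill = 10, bg = 1 - 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort_numeric(paste("Hill decay fit failed:",
                                            conditionMessage(e))))
  par <- stats::coef(nls)
  list(par = unname(par), nls = nls, rss = sum(stats::resid(nls)^2))
}

#' @export
print.hill_decay_fit <- function(x, ...) {
  cat(sprintf("Hill decay fit: t05 = %.4g min (95%% CI %.4g - %.4g, %s)\n",
              x$t05, x$ci95[1, 1], x$ci95[1, 2], x$ci_method))
  cat(sprintf("  n = %.3g, bg = %.3g, RSS = %.3g\n", x$n_hill, x$bg, x$rss))
  invisible(x)
}
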