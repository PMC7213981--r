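# Reduced two-variable steady-state system.
#
# With u = total unphosphorylated NICD, p = total phosphorylated NICD,
# N = N_e + N_s sites, D = k_alpha + u + p, and dimensionless rates
# kp' = k_p/Gamma_up, Gp' = Gamma_p/Gamma_up, the steady state solves
#   0 = NICD0 - u - N*(u/D)*(kp' - 1)
#   0 = N*(u/D)*kp' - (p - N*(p/D))*Gp'
# Bound pools are N*u/D and N*p/D; only unbound molecules degrade.
ss_residual <- function(x, NICD0, N, ka, kp, gp) {
  u <- x[1]; p <- x[2]
  D <- ka + u + p
  c(NICD0 - u - N * (u / D) * (kp - 1),
    N * (u / D) * kp - (p - N * (p / D)) * gp)
}

ss_jacobian <- function(x, NICD0, N, ka, kp, gp) {
  u <- x[1]; p <- x[2]
  D <- ka + u + p
  D2 <- D * D
  matrix(c(-1 - N * (kp - 1) * (ka + p) / D2,
           N * kp * (ka + p) / D2 - gp * N * p / D2,
           N * (kp - 1) * u / D2,
           -N * kp * u / D2 - gp + gp * N * (ka + u) / D2),
         nrow = 2)
}

#' Steady state of the site-coupled NICD degradation model
#'
#' Solves the two coupled steady-state equations for the total
#' unphosphorylated and phosphorylated NICD pools, with site occupancy
#' evaluated self-consistently at the solution (see [site_occupancy()]).
#' A damped Newton iteration with analytic Jacobian is run from three
#' starting points; the first root with residual below `tol * NICD0` and
#' non-negative pools is accepted.
#'
#' @param params A [kinetic_params()] object with `NICD0 > 0`.
#' @param tol Relative residual tolerance; a root is accepted when the max
#'   absolute residual is below `tol * NICD0`.
#' @param max_iter Newton iterations per start.
#' @return Object of class `nicd_steady_state`: list with total pools
#'   `NICD_up`, `NICD_p`, `NICD_tot`, bound amounts `NICD_up_b`,
#'   `NICD_p_b`, unbound amounts `NICD_up_ub`, `NICD_p_ub`, the
#'   `occupancy` ([site_occupancy()]), `residual_norm` and `converged`.
#' @examples
#' p <- default_reporter_params()
#' steady_state(update_params(p, N_s = 12))
#' @export
steady_state <- function(params, tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(params, "kinetic_params"))
  d <- dimensionless_params(params)
  NICD0 <- d$NICD0; N <- d$N; ka <- d$k_alpha
  kp <- d$k_p_prime; gp <- d$Gamma_p_prime

  if (NICD0 == 0) {
    occ <- site_occupancy(0, 0, ka)
    return(structure(list(NICD_up = 0, NICD_p = 0, NICD_tot = 0,
                          NICD_up_b = 0, NICD_p_b = 0,
                          NICD_up_ub = 0, NICD_p_ub = 0, occupancy = occ,
                          residual_norm = 0, converged = TRUE,
                          params = params),
                     class = "nicd_steady_state"))
  }

  starts <- list(c(NICD0, 0), c(NICD0 / 2, NICD0 / 10),
                 c(1e-8 * NICD0, 1e-8 * NICD0))
  best <- NULL
  for (x0 in starts) {
    sol <- newton_2d(x0, NICD0, N, ka, kp, gp, tol * NICD0, max_iter)
    if (is.null(best) || sol$rnorm < best$rnorm) best <- sol
    if (sol$converged) break
  }
  if (!best$converged)
    abort_numeric(sprintf(
      "steady-state solver failed to converge (best residual %.3e)", best$rnorm),
      data = best)

  u <- best$x[1]; p <- best$x[2]
  # clip solver-level negative dust
  if (u < 0 && u > -1e-9) u <- 0
  if (p < 0 && p > -1e-9) p <- 0
  occ <- site_occupancy(u, p, ka)
  up_b <- N * occ$p_up
  p_b <- N * occ$p_p
  structure(list(NICD_up = u, NICD_p = p, NICD_tot = u + p,
                 NICD_up_b = up_b, NICD_p_b = p_b,
                 NICD_up_ub = u - up_b, NICD_p_ub = p - p_b,
                 occupancy = occ,
                 residual_norm = best$rnorm, converged = best$converged,
                 params = params),
            class = "nicd_steady_state")
}

newton_2d <- function(x0, NICD0, N, ka, kp, gp, tol_abs, max_iter) {
  x <- x0
  f <- ss_residual(x, NICD0, N, ka, kp, gp)
  rnorm <- max(abs(f))
  for (i in seq_len(max_iter)) {
    if (rnorm < tol_abs && all(x > -1e-9))
      return(list(x = x, rnorm = rnorm, converged = TRUE))
    J <- ss_jacobian(x, NICD0, N, ka, kp, gp)
    dx <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dx)) break
    # keep the iterate strictly inside the positive quadrant
    lambda <- 1
    for (j in 1:2) if (dx[j] < 0)
      lambda <- min(lambda, -0.95 * x[j] / dx[j])
    if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-12
    # backtracking line search on the residual norm
    repeat {
      xn <- x + lambda * dx
      fn <- ss_residual(xn, NICD0, N, ka, kp, gp)
      if (max(abs(fn)) < rnorm || lambda < 1e-12) break
      lambda <- lambda / 2
    }
    if (max(abs(fn)) >= rnorm) break  # stalled
    x <- xn; f <- fn; rnorm <- max(abs(f))
  }
  list(x = x, rnorm = rnorm, converged = rnorm < tol_abs && all(x > -1e-9))
}

#' @export
print.nicd_steady_state <- function(x, ...) {
  cat("Steady-state nuclear NICD (molecules/nucleus):\n")
  cat(sprintf("  total %.6g  (unphospho %.6g, phospho %.6g)\n",
              x$NICD_tot, x$NICD_up, x$NICD_p))
  cat(sprintf("  bound %.4g + %.4g of %g sites; residual %.2e\n",
              x$NICD_up_b, x$NICD_p_b,
              x$params$N_e + x$params$N_s, x$residual_norm))
  invisible(x)
}

#' Steady-state NICD titration curve over synthetic site numbers
#'
#' Solves the steady state for each synthetic site count and reports total
#' NICD both raw and normalized to the zero-site condition. In the
#' strong-binding, low-site-number regime the curve falls linearly with
#' site number, with slope proportional to the phosphorylation rate `k_p`,
#' then saturates at high site numbers.
#'
#' @param params A [kinetic_params()] object; its `N_s` is ignored.
#' @param Ns_values Integer vector of synthetic site numbers; must
#'   contain 0 (the normalization point).
#' @param ... Passed to [steady_state()].
#' @return Data frame of class `titration_curve` with columns `n_sites`,
#'   `nicd_up`, `nicd_p`, `nicd_tot`, `nicd_tot_norm`.
#' @examples
#' titration_curve(default_reporter_params(), c(0, 6, 12, 18))
#' @export
titration_curve <- function(params, Ns_values = c(0L, 6L, 12L, 18L), ...) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!0 %in% Ns_values)
    abort_domain("`Ns_values` must contain 0 (normalization reference)")
  Ns_values <- as.integer(sort(unique(Ns_values)))
  rows <- lapply(Ns_values, function(ns) {
    ss <- steady_state(update_params(params, N_s = ns), ...)
    data.frame(n_sites = ns, nicd_up = ss$NICD_up, nicd_p = ss$NICD_p,
               nicd_tot = ss$NICD_tot)
  })
  out <- do.call(rbind, rows)
  out$nicd_tot_norm <- out$nicd_tot / out$nicd_tot[out$n_sites == 0]
  class(out) <- c("titration_curve", "data.frame")
  out
}
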