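#' Equilibrium occupancy of one SPS binding site
#'
#' Thermodynamic (partition-function) occupancy of a single binding site
#' exposed to unphosphorylated and phosphorylated NICD pools. Each bound
#' state carries a statistical weight equal to the relevant abundance over
#' the dissociation constant: `alpha_up = NICD_up/k_alpha`,
#' `alpha_p = NICD_p/k_alpha`. With partition function
#' `Z = 1 + alpha_up + alpha_p`, the per-site probabilities are
#' `p_empty = 1/Z`, `p_up = alpha_up/Z`, `p_p = alpha_p/Z`.
#'
#' Binding to different sites is treated as independent, and the number of
#' NICD molecules is assumed large compared to the number of sites, so the
#' pools are not depleted by binding.
#'
#' @param nicd_up Unphosphorylated NICD abundance (molecules/nucleus, >= 0).
#' @param nicd_p Phosphorylated NICD abundance (molecules/nucleus, >= 0).
#' @param k_alpha Dissociation constant (molecules/nucleus, > 0).
#' @return Object of class `site_occupancy`: list with `alpha_up`,
#'   `alpha_p`, `Z`, `p_empty`, `p_up`, `p_p` (vectorized over the inputs).
#' @examples
#' site_occupancy(2000, 100, 1)  # p_up = 2000/2101
#' @export
site_occupancy <- function(nicd_up, nicd_p, k_alpha) {
  if (!is.numeric(nicd_up) || !is.numeric(nicd_p) || !is.numeric(k_alpha) ||
      any(!is.finite(nicd_up)) || any(!is.finite(nicd_p)) ||
      any(!is.finite(k_alpha)))
    abort_domain("occupancy inputs must be finite numbers")
  if (any(nicd_up < 0) || any(nicd_p < 0))
    abort_domain("NICD abundances must be >= 0")
  if (any(k_alpha <= 0))
    abort_domain("`k_alpha` must be > 0")
  alpha_up <- nicd_up / k_alpha
  alpha_p <- nicd_p / k_alpha
  Z <- 1 + alpha_up + alpha_p
  structure(list(alpha_up = alpha_up, alpha_p = alpha_p, Z = Z,
                 p_empty = 1 / Z, p_up = alpha_up / Z, p_p = alpha_p / Z),
            class = "site_occupancy")
}

#' @export
print.site_occupancy <- function(x, ...) {
  cat("Per-site occupancy: p_empty =", format(x$p_empty),
      " p_up =", format(x$p_up), " p_p =", format(x$p_p), "\n")
  invisible(x)
}
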