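#' Density-dependent growth factor
#'
#' Beverton-Holt style self-limitation of the host:
#' `g = 1 / (1 + N (lambda - 1) / K)`. At `N = 0` the factor is 1, and at
#' `N = K` it equals `1/lambda`, so the parasitoid-free host equilibrates at
#' its carrying capacity. For growth rates at or below replacement
#' (`lambda_t <= 1`, possible after cost deduction) the compensatory term is
#' switched off and `g = 1`: the population is already declining and the
#' hyperbola would otherwise lose its meaning (its denominator can reach zero
#' near `N = K`).
#'
#' All arguments are vectorized.
#'
#' @param N Host density (>= 0).
#' @param lambda_t Current (cost-adjusted) growth rate.
#' @param K Carrying capacity (> 0).
#' @return Dimensionless factor in (0, 1] (for `lambda_t > 1`), strictly
#'   decreasing in `N`.
#' @examples
#' density_dependence(0, 10, 720)    # 1
#' density_dependence(720, 10, 720)  # 1/10
#' @export
density_dependence <- function(N, lambda_t, K) {
  if (any(K <= 0)) stop("`K` must be > 0")
  1 / (1 + N * (pmax(lambda_t, 1) - 1) / K)
}

#' Resistant proportion of the host population
#'
#' The proportion of hosts refractory to a parasitoid is a Gaussian-type
#' function of the gap between the host's and that parasitoid's mean
#' characters: `alpha = 1 - exp(-(n_bar - x_bar)^2)`. It is 0 only when the
#' characters coincide, symmetric in the sign of the gap, and invariant under
#' joint translation of both characters.
#'
#' @param n_bar Mean host character.
#' @param x_bar Mean character of the attacking parasitoid.
#' @return Proportion in [0, 1). Computed as `-expm1(-(gap)^2)` for accuracy
#'   at small gaps.
#' @examples
#' resistance_alpha(1, 1)     # 0
#' resistance_alpha(1, 0.9)   # 1 - exp(-0.01)
#' @export
resistance_alpha <- function(n_bar, x_bar) {
  -expm1(-(n_bar - x_bar)^2)
}

#' Probability that a susceptible host escapes parasitism
#'
#' Negative-binomial (May 1978) escape function with a type-II saturating
#' attack rate:
#' `f = [1 + a X / (kappa (1 + a N g (1 - alpha) / eta_t))]^(-kappa)`,
#' where `g = density_dependence(N, lambda_t, K)`. Aggregated attacks
#' (small `kappa`) leave a larger escaping fraction; the saturation term
#' caps each female at `eta_t` hosts.
#'
#' @param N Host density.
#' @param X Density of the attacking parasitoid.
#' @param a Searching efficiency.
#' @param kappa Spatial heterogeneity of parasitism (> 0).
#' @param eta_t Current (cost-adjusted) intrinsic attack rate (> 0).
#' @param alpha Resistant proportion towards this parasitoid.
#' @param lambda_t Current host growth rate (used inside `g`).
#' @param K Host carrying capacity.
#' @return Escape probability in (0, 1]; exactly 1 when `X = 0` or `a = 0`.
#' @export
escape_probability <- function(N, X, a, kappa, eta_t, alpha, lambda_t, K) {
  if (any(eta_t <= 0)) stop("`eta_t` must be > 0 (apply the rate floor upstream)")
  g <- density_dependence(N, lambda_t, K)
  S <- 1 + a * N * g * (1 - alpha) / eta_t
  (1 + a * X / (kappa * S))^(-kappa)
}

#' Cost-adjusted growth and attack rates
#'
#' Character evolution is costly: the realized host growth rate is
#' `lambda_t = lambda* - C_n n_bar` and the realized parasitoid attack rate is
#' `eta_t = eta* - C_p p_bar`. Both are floored at `rate_floor` rather than
#' allowed to go non-positive; a clamp triggers a warning (the simulators
#' record it as an event instead).
#'
#' @param host A [host_params()] object.
#' @param parasitoid A [parasitoid_params()] object.
#' @param n_bar,p_bar Current mean characters.
#' @param rate_floor Smallest admissible rate.
#' @param warn Emit a warning when a rate is clamped (default `TRUE`).
#' @return List with `lambda_t`, `eta_t` and logicals `lambda_clamped`,
#'   `eta_clamped`.
#' @examples
#' h <- host_params(10, 720); p <- parasitoid_params(42, 0.92, 4.14, 0.5)
#' cost_adjusted_rates(h, p, n_bar = 1, p_bar = 0.9)
#' @export
cost_adjusted_rates <- function(host, parasitoid, n_bar, p_bar,
                                rate_floor = 1e-9, warn = TRUE) {
  if (rate_floor <= 0) stop("`rate_floor` must be > 0")
  lam_raw <- host$lambda_star - host$C_n * n_bar
  eta_raw <- parasitoid$eta_star - parasitoid$C_p * p_bar
  lam_cl <- lam_raw < rate_floor
  eta_cl <- eta_raw < rate_floor
  if (warn && any(lam_cl)) warning("lambda_t clamped at the rate floor")
  if (warn && any(eta_cl)) warning("eta_t clamped at the rate floor")
  list(lambda_t = pmax(lam_raw, rate_floor),
       eta_t = pmax(eta_raw, rate_floor),
       lambda_clamped = lam_cl, eta_clamped = eta_cl)
}
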