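#' Host parameter set
#'
#' Bundles the ecological and evolutionary constants of the host (pest weevil)
#' population: the cost-free intrinsic growth rate, carrying capacity, the
#' linear cost of the resistance character, the additive genetic variance that
#' scales character evolution, and the initial condition.
#'
#' @param lambda_star Cost-free intrinsic growth rate (offspring per adult per
#'   generation); must be positive. The realized rate each generation is
#'   `lambda_star - C_n * n_bar`, floored at the configured rate floor.
#' @param K Carrying capacity (adults per square metre); must be positive.
#' @param C_n Cost coefficient on the host character (growth-rate units per
#'   character unit). A larger resistance character depresses the growth rate.
#' @param Gamma_n Additive genetic variance of the host character
#'   (character-units squared, non-negative). Zero freezes the character.
#' @param N0 Initial host density (adults per square metre); defaults to `K`.
#' @param n0 Initial mean host character (dimensionless).
#'
#' @return An object of class `host_params`.
#' @examples
#' host_params(lambda_star = 12, K = 720)
#' @export
host_params <- function(lambda_star, K, C_n = 1, Gamma_n = 0.01,
                        N0 = K, n0 = 1) {
  stopifnot(is.numeric(lambda_star), is.numeric(K))
  if (lambda_star <= 0) stop("`lambda_star` must be > 0")
  if (K <= 0) stop("`K` must be > 0")
  if (Gamma_n < 0) stop("`Gamma_n` must be >= 0")
  if (N0 < 0) stop("`N0` must be >= 0")
  structure(list(lambda_star = lambda_star, K = K, C_n = C_n,
                 Gamma_n = Gamma_n, N0 = N0, n0 = n0),
            class = "host_params")
}

#' Parasitoid parameter set
#'
#' Bundles the constants of one parasitoid population: cost-free intrinsic
#' attack rate, larval survival, searching efficiency, spatial heterogeneity
#' of parasitism, character cost, additive genetic variance (zero encodes a
#' strictly asexual, non-adapting line), the initial condition, and the
#' generation at which the parasitoid enters the system.
#'
#' @param eta_star Cost-free intrinsic attack rate (hosts per female per
#'   generation); must be positive.
#' @param c Survival of parasitoid larvae: female recruits per parasitized
#'   host, in (0, 1].
#' @param a Searching efficiency (m^2 per generation), non-negative.
#' @param kappa Spatial heterogeneity in parasitism (dimensionless, > 0).
#'   Small values mean strongly aggregated attacks; large values approach the
#'   random (Poisson) limit.
#' @param C_p Cost coefficient on the parasitoid character.
#' @param Gamma_p Additive genetic variance of the parasitoid character
#'   (>= 0). Zero encodes strict asexuality: the character never changes.
#' @param P0 Initial density (females per square metre) when introduced.
#' @param p0 Initial mean parasitoid character.
#' @param introduction_generation Generation index at which this parasitoid
#'   enters the system (0 for a parasitoid present from the start).
#'
#' @return An object of class `parasitoid_params`.
#' @examples
#' parasitoid_params(eta_star = 42, c = 0.92, a = 4.14, kappa = 0.3)
#' @export
parasitoid_params <- function(eta_star, c, a, kappa, C_p = 1, Gamma_p = 0,
                              P0 = 10, p0 = 0.9, introduction_generation = 0) {
  if (eta_star <= 0) stop("`eta_star` must be > 0")
  if (c <= 0 || c > 1) stop("`c` must be in (0, 1]")
  if (a < 0) stop("`a` must be >= 0")
  if (kappa <= 0) stop("`kappa` must be > 0")
  if (Gamma_p < 0) stop("`Gamma_p` must be >= 0")
  if (P0 < 0) stop("`P0` must be >= 0")
  if (introduction_generation < 0) stop("`introduction_generation` must be >= 0")
  structure(list(eta_star = eta_star, c = c, a = a, kappa = kappa, C_p = C_p,
                 Gamma_p = Gamma_p, P0 = P0, p0 = p0,
                 introduction_generation = introduction_generation),
            class = "parasitoid_params")
}

#' Simulation configuration
#'
#' Numerical settings shared by the simulators: run length, the
#' finite-difference step used for fitness gradients, the density below which
#' a population is reported extinct, the floor applied to cost-adjusted rates,
#' and an optional seed for stochastic components.
#'
#' Densities are continuous and by default are *not* zeroed during iteration;
#' `extinction_threshold` is used for event reporting and outcome
#' classification. Set `zero_on_extinction = TRUE` to hard-zero a population
#' the first time it falls below the threshold.
#'
#' @param generations Total number of discrete generations to iterate (>= 1).
#' @param gradient_step Finite-difference step `h` (character units) for
#'   fitness-gradient evaluation.
#' @param extinction_threshold Density (per m^2) below which a population is
#'   reported extinct.
#' @param rate_floor Smallest admissible value of the cost-adjusted rates
#'   `lambda_t` and `eta_t`.
#' @param zero_on_extinction If `TRUE`, set a population to exactly 0 once it
#'   falls below `extinction_threshold` (it can then never recover).
#' @param seed Optional integer seed for stochastic components.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(generations = 300, gradient_step = 1e-5,
                       extinction_threshold = 1e-6, rate_floor = 1e-9,
                       zero_on_extinction = FALSE, seed = NULL) {
  if (generations < 1) stop("`generations` must be >= 1")
  if (gradient_step <= 0) stop("`gradient_step` must be > 0")
  if (extinction_threshold < 0) stop("`extinction_threshold` must be >= 0")
  if (rate_floor <= 0) stop("`rate_floor` must be > 0")
  structure(list(generations = as.integer(generations),
                 gradient_step = gradient_step,
                 extinction_threshold = extinction_threshold,
                 rate_floor = rate_floor,
                 zero_on_extinction = isTRUE(zero_on_extinction),
                 seed = seed),
            class = "sim_config")
}

#' @export
print.host_params <- function(x, ...) {
  cat("<host_params>\n")
  cat(sprintf("  lambda* = %g, K = %g, C_n = %g, Gamma_n = %g\n",
              x$lambda_star, x$K, x$C_n, x$Gamma_n))
  cat(sprintf("  N0 = %g, n0 = %g\n", x$N0, x$n0))
  invisible(x)
}

#' @export
print.parasitoid_params <- function(x, ...) {
  cat("<parasitoid_params>\n")
  cat(sprintf("  eta* = %g, c = %g, a = %g, kappa = %g, C_p = %g, Gamma_p = %g\n",
              x$eta_star, x$c, x$a, x$kappa, x$C_p, x$Gamma_p))
  cat(sprintf("  P0 = %g, p0 = %g, introduced at generation %d\n",
              x$P0, x$p0, as.integer(x$introduction_generation)))
  invisible(x)
}

#' System state at one generation
#'
#' Snapshot of all state variables and derived quantities at one generation:
#' densities, mean character values, the resistant proportion towards each
#' parasitoid, the cost-adjusted rates, per-parasitoid escape probabilities
#' and realized parasitism rates.
#'
#' @param t Generation index (generation 0 is the initial condition).
#' @param N Host density.
#' @param parasitoid_densities Numeric vector with one density per parasitoid
#'   (one or two elements).
#' @param n_bar Mean host character.
#' @param characters Numeric vector of mean parasitoid characters, parallel to
#'   `parasitoid_densities`.
#' @param alpha,lambda_t,eta_t,escape,parasitism_rate Optional derived
#'   quantities (filled in by the simulators).
#'
#' @return An object of class `system_state`.
#' @export
system_state <- function(t, N, parasitoid_densities, n_bar, characters,
                         alpha = NULL, lambda_t = NULL, eta_t = NULL,
                         escape = NULL, parasitism_rate = NULL) {
  if (N < 0 || any(parasitoid_densities < 0)) stop("densities must be >= 0")
  if (length(parasitoid_densities) != length(characters))
    stop("one character per parasitoid is required")
  structure(list(t = as.integer(t), N = N,
                 parasitoid_densities = parasitoid_densities,
                 n_bar = n_bar, characters = characters,
                 alpha = alpha, lambda_t = lambda_t, eta_t = eta_t,
                 escape = escape, parasitism_rate = parasitism_rate),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> t = %d, N = %.4g, n_bar = %.4g\n",
              x$t, x$N, x$n_bar))
  for (i in seq_along(x$parasitoid_densities)) {
    cat(sprintf("  parasitoid %d: density = %.4g, character = %.4g", i,
                x$parasitoid_densities[i], x$characters[i]))
    if (!is.null(x$parasitism_rate))
      cat(sprintf(", parasitism rate = %.4g", x$parasitism_rate[i]))
    cat("\n")
  }
  invisible(x)
}
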