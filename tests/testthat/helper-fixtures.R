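# Shared fixture builders for the test suite. All fixtures are constructed in
# code; nothing is read from disk except the packaged parameter table.

lb_host <- function(...) host_params(lambda_star = 10, K = 720, C_n = 1,
                                     Gamma_n = 0.01, N0 = 720, n0 = 1, ...)

lb_parasitoid <- function(Gamma_p = 0, kappa = 0.5, eta_star = 42, ...) {
  parasitoid_params(eta_star = eta_star, c = 0.92, a = 4.14, kappa = kappa,
                    C_p = 1, Gamma_p = Gamma_p, P0 = 10, p0 = 0.9, ...)
}

# Straight-line transcription of the escape function, independent of the
# package implementation (used as the oracle in several tests).
oracle_escape <- function(N, X, a, kappa, eta, alpha, lambda, K) {
  g <- (1 + N * (lambda - 1) / K)^-1
  (1 + (a * X) / (kappa * (1 + a * N * g * (1 - alpha) / eta)))^-kappa
}

# Straight-line one-generation transcription of the two-species map
# (densities and characters), used as the oracle for the step operation.
oracle_two_species_step <- function(N, P, nb, pb, host, par, h = 1e-5,
                                    floor. = 1e-9) {
  lam <- function(n) max(host$lambda_star - host$C_n * n, floor.)
  eta <- function(p) max(par$eta_star - par$C_p * p, floor.)
  g <- function(n) (1 + N * (lam(n) - 1) / host$K)^-1
  alpha <- function(n, p) 1 - exp(-(n - p)^2)
  f <- function(n, p) {
    al <- alpha(n, p)
    (1 + (par$a * P) / (par$kappa * (1 + par$a * N * g(n) * (1 - al) / eta(p))))^-par$kappa
  }
  Wn <- function(n) lam(n) * g(n) * (alpha(n, pb) + (1 - alpha(n, pb)) * f(n, pb))
  Wp <- function(p) par$c * N * g(nb) * (1 - alpha(nb, p)) * (1 - f(nb, p)) / P
  N1 <- N * Wn(nb)
  P1 <- P * Wp(pb)
  n1 <- nb + host$Gamma_n * (log(Wn(nb + h)) - log(Wn(nb - h))) / (2 * h)
  p1 <- pb + par$Gamma_p * (log(Wp(pb + h)) - log(Wp(pb - h))) / (2 * h)
  list(N = N1, P = P1, n_bar = n1, p_bar = p1)
}

make_state <- function(N = 720, P = 10, nb = 1, pb = 0.9, t = 0) {
  system_state(t = t, N = N, parasitoid_densities = P, n_bar = nb,
               characters = pb)
}
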