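# Internal vectorized engine shared by the simulators, the sensitivity
# analysis and the experiment pipelines. All functions operate elementwise on
# equal-length vectors (a "batch" of independent systems), which is what makes
# the 6000-run sensitivity design take seconds rather than hours.
#
# Numerical policy:
#  * densities are continuous and never zeroed here (the paper-style
#    "catch-up" of a newly introduced parasitoid passes through extremely low
#    densities; zeroing is opt-in via sim_config(zero_on_extinction=));
#  * fitness pieces are computed in log space (log1p/expm1, and
#    ln(1 - alpha) = -(gap)^2 exactly) so gradients remain finite even when
#    escape probabilities or densities underflow;
#  * a non-finite gradient (log-domain failure at an evaluation point)
#    contributes zero character change for that generation.

# Escape-function pieces for one parasitoid. X = 0 encodes absence.
.escape_pieces <- function(N, X, a, kap, eta, gap, g) {
  one_minus_alpha <- exp(-gap^2)
  S <- 1 + a * N * g * one_minus_alpha / eta
  x <- a * X / (kap * S)
  lnf <- -kap * log1p(x)                          # ln f, exactly 0 when x = 0
  lnomf <- ifelse(x > 0, log(-expm1(lnf)), -Inf)  # ln(1 - f)
  list(alpha = -expm1(-gap^2), one_minus_alpha = one_minus_alpha,
       lnf = lnf, f = exp(lnf), lnomf = lnomf)
}

# ln(alpha + (1 - alpha) f): host survival through one parasitoid's attack.
.ln_host_surv <- function(gap, lnf) {
  v <- -expm1(-gap^2) + exp(lnf - gap^2)
  ifelse(v > 0, log(v), -Inf)
}

# One synchronous generation of the (up to) three-species map.
# st: list(N, P, Y, nb, pb, yb); Y = 0 rows have no second parasitoid.
# H: list(lam, K, Cn, Gn); A, B: list(eta, c, a, kap, Cp, G).
.step_core <- function(st, H, A, B, h = 1e-5, rate_floor = 1e-9) {
  N <- st$N; P <- st$P; Y <- st$Y
  nb <- st$nb; pb <- st$pb; yb <- st$yb
  y_on <- Y > 0
  p_on <- P > 0

  pieces <- function(nb., pb., yb.) {
    lam <- pmax(H$lam - H$Cn * nb., rate_floor)
    g <- 1 / (1 + N * (pmax(lam, 1) - 1) / H$K)
    ep <- pmax(A$eta - A$Cp * pb., rate_floor)
    ey <- pmax(B$eta - B$Cp * yb., rate_floor)
    list(lam = lam, g = g, ep = ep, ey = ey,
         e1 = .escape_pieces(N, P, A$a, A$kap, ep, nb. - pb., g),
         e2 = .escape_pieces(N, Y, B$a, B$kap, ey, nb. - yb., g))
  }

  lnWn <- function(nb.) {
    q <- pieces(nb., pb, yb)
    log(q$lam) + log(q$g) + .ln_host_surv(nb. - pb, q$e1$lnf) +
      ifelse(y_on, .ln_host_surv(nb. - yb, q$e2$lnf), 0)
  }
  lnWp <- function(pb.) {
    q <- pieces(nb, pb., yb)
    log(A$c * N * q$g) - (nb - pb.)^2 + q$e1$lnomf +
      ifelse(y_on, q$e2$lnf, 0) - log(P)
  }
  lnWy <- function(yb.) {
    q <- pieces(nb, pb, yb.)
    log(B$c * N * q$g) - (nb - yb.)^2 + q$e2$lnomf + q$e1$lnf - log(Y)
  }
  cgrad <- function(fn, x) {
    gv <- (fn(x + h) - fn(x - h)) / (2 * h)
    ifelse(is.finite(gv), gv, 0)
  }

  q <- pieces(nb, pb, yb)
  ap <- q$e1$alpha
  ay <- q$e2$alpha
  f <- q$e1$f
  hh <- ifelse(y_on, q$e2$f, 1)
  omf <- -expm1(q$e1$lnf)
  omh <- ifelse(y_on, -expm1(q$e2$lnf), 0)

  Nn <- q$lam * N * q$g * (ap + (1 - ap) * f) *
    ifelse(y_on, ay + (1 - ay) * hh, 1)
  Pn <- A$c * N * q$g * exp(-(nb - pb)^2) * omf * hh
  Yn <- ifelse(y_on, B$c * N * q$g * exp(-(nb - yb)^2) * omh * f, 0)

  list(N = Nn, P = Pn, Y = Yn,
       nb = ifelse(H$Gn > 0 & N > 0, nb + H$Gn * cgrad(lnWn, nb), nb),
       pb = ifelse(A$G > 0 & p_on, pb + A$G * cgrad(lnWp, pb), pb),
       yb = ifelse(B$G > 0 & y_on, yb + B$G * cgrad(lnWy, yb), yb),
       g = q$g, lambda_t = q$lam, eta_p = q$ep, eta_y = q$ey,
       alpha_p = ap, alpha_y = ay, f = f, h = hh,
       rate_p = (1 - ap) * omf * hh,
       rate_y = ifelse(y_on, (1 - ay) * omh * f, 0),
       lambda_clamped = (H$lam - H$Cn * nb) < rate_floor,
       eta_p_clamped = (A$eta - A$Cp * pb) < rate_floor,
       eta_y_clamped = y_on & (B$eta - B$Cp * yb) < rate_floor)
}

# Flatten S3 parameter objects into engine parameter lists.
.engine_host <- function(host) {
  list(lam = host$lambda_star, K = host$K, Cn = host$C_n, Gn = host$Gamma_n)
}
.engine_parasitoid <- function(p) {
  if (is.null(p)) {
    # inert placeholder: never attacks, never recruits
    list(eta = 1, c = 1, a = 0, kap = 1, Cp = 0, G = 0)
  } else {
    list(eta = p$eta_star, c = p$c, a = p$a, kap = p$kappa, Cp = p$C_p,
         G = p$Gamma_p)
  }
}

# Batch two-species run over vectors of parameters; returns final state and
# derived quantities after `gens` generations. Used by run_sensitivity() and
# system_prediction().
.batch_two_species <- function(lam, K, eta, c, kap, a, Gn, Gp, Cn, Cp,
                               N0, P0, n0, p0, gens,
                               h = 1e-5, rate_floor = 1e-9) {
  n <- max(lengths(list(lam, K, eta, c, kap, a, Gn, Gp, Cn, Cp, N0, P0, n0, p0)))
  H <- list(lam = rep_len(lam, n), K = rep_len(K, n),
            Cn = rep_len(Cn, n), Gn = rep_len(Gn, n))
  A <- list(eta = rep_len(eta, n), c = rep_len(c, n), a = rep_len(a, n),
            kap = rep_len(kap, n), Cp = rep_len(Cp, n), G = rep_len(Gp, n))
  B <- list(eta = 1, c = 1, a = 0, kap = 1, Cp = 0, G = 0)
  st <- list(N = rep_len(N0, n), P = rep_len(P0, n), Y = rep(0, n),
             nb = rep_len(n0, n), pb = rep_len(p0, n), yb = rep(0, n))
  s <- NULL
  for (t in seq_len(gens)) {
    s <- .step_core(st, H, A, B, h = h, rate_floor = rate_floor)
    st$N <- s$N; st$P <- s$P
    st$nb <- s$nb; st$pb <- s$pb
  }
  # derived quantities evaluated at the final state
  fin <- .step_core(st, H, A, B, h = h, rate_floor = rate_floor)
  list(N = st$N, P = st$P, n_bar = st$nb, p_bar = st$pb,
       alpha = fin$alpha_p, rate = fin$rate_p)
}
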