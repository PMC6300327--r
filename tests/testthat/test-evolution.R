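# Character dynamics: log fitness, fitness gradients, character update.

test_that("log fitness reduces to known compositions in degenerate cases", {
  # host alone, cost-free character: ln W_n = ln lambda* + ln g, flat in n_bar
  h <- host_params(10, 720, C_n = 0, Gamma_n = 0.01)
  p <- lb_parasitoid()
  st <- make_state(N = 500, P = 0)
  ctx <- fitness_context(st, h, list(p), "host")
  expected <- log(10) + log(density_dependence(500, 10, 720))
  expect_equal(log_fitness(ctx, 1), expected, tolerance = 1e-12)
  expect_equal(log_fitness(ctx, 7), expected, tolerance = 1e-12)

  # parasitoid with c = 1, matched characters (alpha = 0) and f ~ 0:
  # ln W_p -> ln(N g) (per capita at P = 1)
  p2 <- parasitoid_params(eta_star = 1e12, c = 1, a = 5e4, kappa = 5,
                          Gamma_p = 0.01, P0 = 1, p0 = 1)
  st2 <- make_state(N = 500, P = 1, nb = 1, pb = 1)
  ctx2 <- fitness_context(st2, h, list(p2), 1)
  f <- escape_probability(500, 1, 5e4, 5, 1e12 - 1, 0, 10, 720)
  expect_lt(f, 1e-3)
  expect_equal(log_fitness(ctx2, 1),
               log(500 * density_dependence(500, 10, 720)),
               tolerance = 1e-2)

  expect_error(fitness_context(make_state(P = 0), h, list(p), 3), "focal")
  ctx0 <- fitness_context(make_state(P = 0), h, list(p), 1)
  expect_error(log_fitness(ctx0, 1), "density 0")
})

test_that("log fitness at a generic state matches an independent transcription", {
  h <- lb_host(); p <- lb_parasitoid(Gamma_p = 0.01)
  st <- make_state(N = 720, P = 10, nb = 1, pb = 0.9)
  ctx <- fitness_context(st, h, list(p), "host")
  lam <- 10 - 1 * 1
  g <- (1 + 720 * (lam - 1) / 720)^-1
  al <- 1 - exp(-(1 - 0.9)^2)
  f <- oracle_escape(720, 10, 4.14, 0.5, 42 - 0.9, al, lam, 720)
  expect_equal(log_fitness(ctx, 1), log(lam * g * (al + (1 - al) * f)),
               tolerance = 1e-10)
  ctxp <- fitness_context(st, h, list(p), 1)
  expect_equal(log_fitness(ctxp, 0.9),
               log(0.92 * 720 * g * (1 - al) * (1 - f) / 10),
               tolerance = 1e-10)
})

test_that("fitness gradient is zero by symmetry at matched cost-free characters", {
  h <- host_params(10, 720, C_n = 0, Gamma_n = 0.01)
  p <- lb_parasitoid(Gamma_p = 0.01)
  st <- make_state(N = 400, P = 15, nb = 0.9, pb = 0.9)
  ctx <- fitness_context(st, h, list(p), "host")
  expect_equal(fitness_gradient(ctx), 0, tolerance = 1e-12)
})

test_that("cost-only gradient matches the analytic derivative of ln(lambda_t g)", {
  # host with parasitoid absent: d lnW / d n = -C_n/lambda_t + C_n N g / K
  # (the second term is the density-dependence relaxation; it vanishes as N -> 0)
  p <- lb_parasitoid()
  for (N in c(1e-6, 100, 700)) {
    h <- host_params(10, 720, C_n = 1, Gamma_n = 0.01)
    st <- make_state(N = N, P = 0, nb = 1.5)
    ctx <- fitness_context(st, h, list(p), "host")
    lam <- 10 - 1.5
    g <- density_dependence(N, lam, 720)
    expect_equal(fitness_gradient(ctx), -1 / lam + N * g / 720,
                 tolerance = 1e-7)
  }
})

test_that("finite-difference gradient matches the hand-differentiated chain rule", {
  lam_s <- 10; K <- 720; Cn <- 1; eta_s <- 42; Cp <- 1; a <- 4.14; kap <- 0.5
  N <- 500; P <- 20; nb <- 1.3; pb <- 0.8
  h <- host_params(lam_s, K, C_n = Cn, Gamma_n = 0.01)
  p <- lb_parasitoid(Gamma_p = 0.01)
  st <- make_state(N = N, P = P, nb = nb, pb = pb)
  ctx <- fitness_context(st, h, list(p), "host")

  lam <- lam_s - Cn * nb
  g <- 1 / (1 + N * (lam - 1) / K)
  dlng <- Cn * N * g / K                     # d ln g / d n
  gap <- nb - pb
  al <- 1 - exp(-gap^2)
  dal <- 2 * gap * exp(-gap^2)
  eta <- eta_s - Cp * pb
  S <- 1 + a * N * g * (1 - al) / eta
  dg <- g^2 * N * Cn / K
  dS <- (a * N / eta) * (dg * (1 - al) - g * dal)
  x <- a * P / (kap * S)
  dx <- -a * P * dS / (kap * S^2)
  f <- (1 + x)^(-kap)
  df <- -kap * (1 + x)^(-kap - 1) * dx
  TT <- al + (1 - al) * f
  dT <- dal * (1 - f) + (1 - al) * df
  analytic <- -Cn / lam + dlng + dT / TT

  expect_equal(fitness_gradient(ctx, h = 1e-5), analytic, tolerance = 1e-6)

  # Richardson check: halving h agrees to first order
  g1 <- fitness_gradient(ctx, h = 1e-4)
  g2 <- fitness_gradient(ctx, h = 5e-5)
  expect_equal(g1, g2, tolerance = 1e-6)
})

test_that("resistance pulls host and parasitoid characters in opposite directions", {
  # the alpha term rewards the host for widening the gap and the parasitoid
  # for closing it: numeric partials of alpha have opposite signs
  eps <- 1e-6
  dan <- (resistance_alpha(1 + eps, 0.9) - resistance_alpha(1 - eps, 0.9)) / (2 * eps)
  dap <- (resistance_alpha(1, 0.9 + eps) - resistance_alpha(1, 0.9 - eps)) / (2 * eps)
  expect_equal(dan, -dap, tolerance = 1e-6)
  expect_gt(dan, 0)
})

test_that("character update freezes zero-AGV and absent species, else ascends the gradient", {
  h <- lb_host(); p <- lb_parasitoid(Gamma_p = 0)  # asexual parasitoid
  st <- make_state()
  up <- update_characters(st, h, list(p))
  expect_identical(up$characters, 0.9)             # exactly unchanged
  ctx <- fitness_context(st, h, list(p), "host")
  expect_equal(up$n_bar, 1 + 0.01 * fitness_gradient(ctx), tolerance = 1e-12)

  # both frozen: pure ecological dynamics
  h0 <- lb_host(); h0$Gamma_n <- 0
  up0 <- update_characters(st, h0, list(p))
  expect_identical(up0$n_bar, 1)

  # gradient-ascent property on random states: for small Gamma the updated
  # character does not lose log fitness beyond O(Gamma^2)
  set.seed(7)
  hs <- host_params(12, 720, C_n = 1, Gamma_n = 1e-3)
  for (i in 1:20) {
    st <- make_state(N = runif(1, 10, 700), P = runif(1, 1, 60),
                     nb = runif(1, 0.5, 2.5), pb = runif(1, 0.5, 2.5))
    ps <- lb_parasitoid(Gamma_p = 1e-3)
    up <- update_characters(st, hs, list(ps))
    ctx <- fitness_context(st, hs, list(ps), "host")
    gr <- fitness_gradient(ctx)
    expect_gte(log_fitness(ctx, up$n_bar) - log_fitness(ctx, st$n_bar),
               -1e-4 * (1e-3 * gr)^2 - 1e-12)
  }
})
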