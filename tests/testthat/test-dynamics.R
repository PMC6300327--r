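# Simulators: one-generation maps, trajectories, outcome classification.

test_that("without parasitoids the host follows the Beverton-Holt map to K", {
  h <- host_params(10, 720, C_n = 0, Gamma_n = 0)
  p <- lb_parasitoid()
  st <- make_state(N = 50, P = 0)
  for (i in 1:200) st <- step_two_species(st, h, p)
  expect_equal(st$N, 720, tolerance = 1e-6)
  expect_identical(st$parasitoid_densities, 0)
})

test_that("full resistance shuts down parasitoid recruitment", {
  h <- lb_host(); p <- lb_parasitoid()
  st <- make_state(N = 500, P = 10, nb = 50, pb = 0.9)  # huge character gap
  s1 <- step_two_species(st, h, p)
  expect_lt(s1$parasitoid_densities, 1e-100)
  lam <- 10 - 50  # clamped at the floor -> host collapses too
  expect_equal(s1$N, 1e-9 * 500 * 1, tolerance = 1e-6)
})

test_that("one two-species step equals an independent spreadsheet-style composition", {
  h <- lb_host(); p <- lb_parasitoid(Gamma_p = 0.01, kappa = 0.5)
  st <- make_state(N = 720, P = 10, nb = 1, pb = 0.9)
  s1 <- step_two_species(st, h, p)
  ora <- oracle_two_species_step(720, 10, 1, 0.9, h, p)
  expect_equal(s1$N, ora$N, tolerance = 1e-10)
  expect_equal(s1$parasitoid_densities, ora$P, tolerance = 1e-10)
  expect_equal(s1$n_bar, ora$n_bar, tolerance = 1e-10)
  expect_equal(s1$characters, ora$p_bar, tolerance = 1e-10)
})

test_that("the three-species step with an absent second parasitoid is the two-species step", {
  h <- lb_host(); p <- lb_parasitoid(Gamma_p = 0.01)
  p2 <- lb_parasitoid(Gamma_p = 0.1)
  st2 <- make_state(N = 650, P = 12, nb = 1.1, pb = 0.95)
  st3 <- system_state(t = 0, N = 650, parasitoid_densities = c(12, 0),
                      n_bar = 1.1, characters = c(0.95, 0.9))
  a <- step_two_species(st2, h, p)
  b <- step_three_species(st3, h, p, p2)
  expect_identical(a$N, b$N)
  expect_identical(a$parasitoid_densities, b$parasitoid_densities[1])
  expect_identical(a$n_bar, b$n_bar)
  expect_identical(a$characters, b$characters[1])
  expect_identical(b$parasitoid_densities[2], 0)
})

test_that("two identical parasitoids stay identical forever", {
  h <- lb_host(); p <- lb_parasitoid(Gamma_p = 0.01)
  st <- system_state(t = 0, N = 720, parasitoid_densities = c(10, 10),
                     n_bar = 1, characters = c(0.9, 0.9))
  for (i in 1:100) st <- step_three_species(st, h, p, p)
  expect_identical(st$parasitoid_densities[1], st$parasitoid_densities[2])
  expect_identical(st$characters[1], st$characters[2])
  expect_identical(st$parasitism_rate[1], st$parasitism_rate[2])
})

test_that("a one-generation simulation is the composition of one step", {
  h <- lb_host(); p <- lb_parasitoid(Gamma_p = 0.01)
  tr <- simulate_coevolution(h, p, sim_config(generations = 1))
  expect_equal(nrow(tr$states), 2)
  st <- system_state(t = 0, N = h$N0, parasitoid_densities = p$P0,
                     n_bar = h$n0, characters = p$p0)
  s1 <- step_two_species(st, h, p)
  expect_equal(tr$states$N[2], s1$N, tolerance = 1e-12)
  expect_equal(tr$states$P[2], s1$parasitoid_densities, tolerance = 1e-12)
})

test_that("an asexual parasitoid's parasitism declines monotonically after the transient", {
  b <- baseline_params(Gamma_p = 0)
  tr <- simulate_coevolution(b$host, b$parasitoid, sim_config(generations = 300))
  r <- tr$states$rate_p
  expect_true(all(diff(r[75:301]) <= 1e-12))
  expect_lt(r[301], 0.10)
})

test_that("a sexual parasitoid with host-matched AGV stabilizes at an intermediate rate", {
  b <- baseline_params(Gamma_p = 0.01)
  tr <- simulate_coevolution(b$host, b$parasitoid, sim_config(generations = 400))
  r <- tr$states$rate_p
  expect_lt(stats::sd(r[300:401]), 0.01)
  expect_gt(mean(r[300:401]), 0.2)
  expect_lt(mean(r[300:401]), 0.9)
})

test_that("trajectory bookkeeping: introduction events, tidy export, outcome", {
  b <- baseline_params(Gamma_p = 0)
  p2 <- lb_parasitoid(Gamma_p = 0.01)
  p2$introduction_generation <- 30
  tr <- simulate_coevolution(b$host, list(b$parasitoid, p2),
                             sim_config(generations = 60))
  expect_true(any(tr$events$event == "introduction" &
                  tr$events$generation == 30))
  expect_true(is.na(tr$states$Y[tr$states$generation == 29]))
  expect_equal(tr$states$Y[tr$states$generation == 30], 10)
  d <- as.data.frame(tr)
  expect_setequal(unique(d$species), c("host", "parasitoid_1", "parasitoid_2"))
  expect_true(all(d$parasitism_rate >= 0 & d$parasitism_rate <= 1, na.rm = TRUE))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  expect_equal(nrow(utils::read.csv(path)), nrow(d))

  oc <- classify_outcome(tr)
  expect_true(oc$parasitoid_1$persisted)
  expect_named(oc$parasitoid_2,
               c("persisted", "final_density", "final_parasitism",
                 "final_resistance"))
})

test_that("a sexual challenger drives an asexual incumbent extinct and takes over", {
  b <- baseline_params()
  p1 <- lb_parasitoid(Gamma_p = 0, eta_star = 84, kappa = 0.3)   # asexual, doubled eta
  p1$C_p <- 1
  p2 <- lb_parasitoid(Gamma_p = 0.01, kappa = 0.3)
  p2$introduction_generation <- 500
  b$host$lambda_star <- 12
  tr <- simulate_coevolution(b$host, list(p1, p2), sim_config(generations = 2000))
  oc <- tr$outcome
  expect_false(oc$parasitoid_1$persisted)
  expect_true(oc$parasitoid_2$persisted)
  expect_gt(oc$parasitoid_2$final_parasitism, 0.3)
})

test_that("densities stay in bounds and parasitism rates account correctly", {
  set.seed(11)
  for (i in 1:8) {
    h <- host_params(runif(1, 2, 40), runif(1, 100, 800), C_n = runif(1, 0, 2),
                     Gamma_n = runif(1, 0, 0.1), N0 = runif(1, 50, 800),
                     n0 = runif(1, 0.5, 1.5))
    p <- parasitoid_params(runif(1, 20, 64), runif(1, 0.5, 1), runif(1, 1, 8),
                           runif(1, 0.1, 0.9), C_p = runif(1, 0, 2),
                           Gamma_p = runif(1, 0, 0.1), P0 = runif(1, 1, 100),
                           p0 = runif(1, 0.5, 1.5))
    tr <- simulate_coevolution(h, p, sim_config(generations = 120))
    s <- tr$states
    expect_true(all(s$N >= 0 & s$P >= 0))
    bound <- max(h$N0, h$K * h$lambda_star / (h$lambda_star - 1)) * (1 + 1e-12)
    expect_true(all(s$N <= bound))
    expect_true(all(s$rate_p >= 0 & s$rate_p <= 1))
    expect_true(all(s$alpha_p >= 0 & s$alpha_p < 1))
  }
})

test_that("with frozen characters the ecological fixed point satisfies the map equations", {
  h <- host_params(10, 720, C_n = 0, Gamma_n = 0)
  p <- lb_parasitoid(Gamma_p = 0, kappa = 0.5)
  tr <- simulate_coevolution(h, p, sim_config(generations = 4000))
  Nf <- utils::tail(tr$states$N, 1)
  Pf <- utils::tail(tr$states$P, 1)
  # independent root-finder on a straight-line transcription of the map
  resid <- function(z) {
    N <- z[1]; P <- z[2]
    al <- 1 - exp(-(1 - 0.9)^2)
    g <- (1 + N * 9 / 720)^-1
    f <- (1 + 4.14 * P / (0.5 * (1 + 4.14 * N * g * (1 - al) / 41.1)))^-0.5
    c(10 * N * g * (al + (1 - al) * f) - N,
      0.92 * N * g * (1 - al) * (1 - f) - P)
  }
  sol <- stats::optim(c(Nf, Pf), function(z) sum(resid(z)^2),
                      method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(sol$value, 1e-8)
  expect_equal(sol$par[1], Nf, tolerance = 1e-3)
  expect_equal(sol$par[2], Pf, tolerance = 1e-3)
})
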