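# The simulators: synchronous one-generation maps for the two- and
# three-species systems, a trajectory runner with mid-run introduction of a
# second parasitoid, and outcome classification.

.engine_state_from_system <- function(state) {
  two <- length(state$parasitoid_densities) > 1
  list(N = state$N, P = state$parasitoid_densities[1],
       Y = if (two) state$parasitoid_densities[2] else 0,
       nb = state$n_bar, pb = state$characters[1],
       yb = if (two) state$characters[2] else 0)
}

#' One generation of the two-species model
#'
#' Synchronous update of host density, parasitoid density and both mean
#' characters:
#' `N[t+1] = lambda_t N g (alpha + (1 - alpha) f)`,
#' `P[t+1] = c N g (1 - alpha)(1 - f)`,
#' with the characters advanced by their fitness gradients evaluated at the
#' generation-t state. The realized parasitism rate is recorded as
#' `(1 - alpha)(1 - f)`.
#'
#' @param state A [system_state()] with one parasitoid.
#' @param host A [host_params()] object.
#' @param parasitoid A [parasitoid_params()] object.
#' @param config A [sim_config()].
#' @return The [system_state()] at generation t+1 (derived quantities are
#'   those of the *new* state).
#' @export
step_two_species <- function(state, host, parasitoid, config = sim_config()) {
  st <- .engine_state_from_system(state)
  st$Y <- 0; st$yb <- 0
  H <- .engine_host(host)
  A <- .engine_parasitoid(parasitoid)
  B <- .engine_parasitoid(NULL)
  s <- .step_core(st, H, A, B, h = config$gradient_step,
                  rate_floor = config$rate_floor)
  new <- list(N = s$N, P = s$P, Y = 0, nb = s$nb, pb = s$pb, yb = 0)
  if (config$zero_on_extinction) {
    if (new$N < config$extinction_threshold) new$N <- 0
    if (new$P < config$extinction_threshold) new$P <- 0
  }
  d <- .step_core(new, H, A, B, h = config$gradient_step,
                  rate_floor = config$rate_floor)
  system_state(t = state$t + 1L, N = new$N, parasitoid_densities = new$P,
               n_bar = new$nb, characters = new$pb,
               alpha = d$alpha_p, lambda_t = d$lambda_t, eta_t = d$eta_p,
               escape = d$f, parasitism_rate = d$rate_p)
}

#' One generation of the three-species model
#'
#' Two parasitoids attack the same host simultaneously and independently
#' (no multiparasitism): the host escapes both, each parasitoid recruits
#' from hosts it attacks that escape the competitor, and all three mean
#' characters advance by their fitness gradients. A second parasitoid with
#' density 0 makes this identical to [step_two_species()].
#'
#' @param state A [system_state()] with two parasitoids.
#' @param host A [host_params()] object.
#' @param parasitoid_p,parasitoid_y The first / second parasitoid's
#'   [parasitoid_params()].
#' @param config A [sim_config()].
#' @return The [system_state()] at generation t+1.
#' @export
step_three_species <- function(state, host, parasitoid_p, parasitoid_y,
                               config = sim_config()) {
  st <- .engine_state_from_system(state)
  H <- .engine_host(host)
  A <- .engine_parasitoid(parasitoid_p)
  B <- .engine_parasitoid(parasitoid_y)
  s <- .step_core(st, H, A, B, h = config$gradient_step,
                  rate_floor = config$rate_floor)
  new <- list(N = s$N, P = s$P, Y = s$Y, nb = s$nb, pb = s$pb, yb = s$yb)
  if (config$zero_on_extinction) {
    if (new$N < config$extinction_threshold) new$N <- 0
    if (new$P < config$extinction_threshold) new$P <- 0
    if (new$Y < config$extinction_threshold) new$Y <- 0
  }
  d <- .step_core(new, H, A, B, h = config$gradient_step,
                  rate_floor = config$rate_floor)
  system_state(t = state$t + 1L, N = new$N,
               parasitoid_densities = c(new$P, new$Y),
               n_bar = new$nb, characters = c(new$pb, new$yb),
               alpha = c(d$alpha_p, d$alpha_y), lambda_t = d$lambda_t,
               eta_t = c(d$eta_p, d$eta_y), escape = c(d$f, d$h),
               parasitism_rate = c(d$rate_p, d$rate_y))
}

#' Simulate the coupled eco-evolutionary dynamics
#'
#' Iterates the system from generation 0 to `config$generations`. With one
#' parasitoid this is the two-species model; with two, the second parasitoid
#' enters at its `introduction_generation` with density `P0` and character
#' `p0` (the character the first parasitoid had when introduced), while the
#' host character at that moment is whatever coevolution produced.
#'
#' @param host A [host_params()] object.
#' @param parasitoids One [parasitoid_params()] or a list of one or two.
#' @param config A [sim_config()].
#' @return An object of class `trajectory`: a list with `states` (one row per
#'   generation: densities, characters, resistant proportions, escape
#'   probabilities, parasitism rates), `events` (introductions, extinctions,
#'   rate clamps), and `outcome` (see [classify_outcome()]).
#' @examples
#' h <- host_params(12, 720)
#' p <- parasitoid_params(42, 0.92, 4.14, 0.3, Gamma_p = 0.01)
#' tr <- simulate_coevolution(h, p, sim_config(generations = 50))
#' utils::tail(tr$states, 3)
#' @export
simulate_coevolution <- function(host, parasitoids, config = sim_config()) {
  if (inherits(parasitoids, "parasitoid_params")) parasitoids <- list(parasitoids)
  if (!length(parasitoids) %in% 1:2) stop("1 or 2 parasitoids are required")
  two <- length(parasitoids) == 2
  p1 <- parasitoids[[1]]
  p2 <- if (two) parasitoids[[2]]
  if (p1$introduction_generation != 0)
    stop("the first parasitoid must be present from generation 0")
  if (two && p2$introduction_generation >= config$generations)
    stop("the second parasitoid's introduction_generation must be < generations")
  intro <- if (two) p2$introduction_generation else Inf

  H <- .engine_host(host)
  A <- .engine_parasitoid(p1)
  B <- .engine_parasitoid(p2)
  st <- list(N = host$N0, P = p1$P0, Y = 0, nb = host$n0, pb = p1$p0, yb = 0)
  gens <- config$generations
  thr <- config$extinction_threshold

  cols <- c("generation", "N", "P", "Y", "n_bar", "p_bar", "y_bar",
            "alpha_p", "alpha_y", "lambda_t", "eta_p", "eta_y",
            "escape_p", "escape_y", "rate_p", "rate_y")
  out <- matrix(NA_real_, nrow = gens + 1L, ncol = length(cols),
                dimnames = list(NULL, cols))
  events <- list()
  seen <- character()
  note <- function(gen, event, species) {
    key <- paste(event, species)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      events[[length(events) + 1L]] <<-
        data.frame(generation = gen, event = event, species = species)
    }
  }

  record <- function(i, gen, st, d) {
    y_on <- gen >= intro
    out[i, ] <<- c(gen, st$N, st$P, if (y_on) st$Y else NA, st$nb, st$pb,
                   if (y_on) st$yb else NA,
                   d$alpha_p, if (y_on) d$alpha_y else NA,
                   d$lambda_t, d$eta_p, if (y_on) d$eta_y else NA,
                   d$f, if (y_on) d$h else NA,
                   d$rate_p, if (y_on) d$rate_y else NA)
  }

  d0 <- .step_core(st, H, A, B, h = config$gradient_step,
                   rate_floor = config$rate_floor)
  record(1L, 0, st, d0)
  for (t in seq_len(gens)) {
    if (t - 1L == intro) {
      st$Y <- p2$P0
      st$yb <- p2$p0
      note(t - 1L, "introduction", "parasitoid_2")
      d0 <- .step_core(st, H, A, B, h = config$gradient_step,
                       rate_floor = config$rate_floor)
      record(t, t - 1L, st, d0)   # re-record the introduction generation
    }
    s <- .step_core(st, H, A, B, h = config$gradient_step,
                    rate_floor = config$rate_floor)
    if (s$lambda_clamped) note(t, "rate_clamp", "host")
    if (s$eta_p_clamped) note(t, "rate_clamp", "parasitoid_1")
    if (s$eta_y_clamped) note(t, "rate_clamp", "parasitoid_2")
    st$N <- s$N; st$P <- s$P; st$Y <- s$Y
    st$nb <- s$nb; st$pb <- s$pb; st$yb <- s$yb
    if (config$zero_on_extinction) {
      if (st$N < thr) st$N <- 0
      if (st$P < thr) st$P <- 0
      if (st$Y < thr && t - 1L >= intro) st$Y <- 0
    }
    if (st$N < thr) note(t, "extinction", "host")
    if (st$P < thr) note(t, "extinction", "parasitoid_1")
    if (st$Y < thr && t - 1L >= intro) note(t, "extinction", "parasitoid_2")
    d <- .step_core(st, H, A, B, h = config$gradient_step,
                    rate_floor = config$rate_floor)
    record(t + 1L, t, st, d)
  }

  states <- as.data.frame(out)
  traj <- structure(list(
    states = states,
    events = if (length(events)) do.call(rbind, events)
             else data.frame(generation = integer(), event = character(),
                             species = character()),
    host = host, parasitoids = parasitoids, config = config),
    class = "trajectory")
  traj$outcome <- classify_outcome(traj)
  traj
}

#' Classify the outcome of a trajectory
#'
#' Per-parasitoid persistence flags plus final-window summaries. A parasitoid
#' is classified extinct when its final density lies below the configured
#' extinction threshold; final parasitism rates and resistant proportions are
#' means over the last `window` generations.
#'
#' @param traj A `trajectory` from [simulate_coevolution()].
#' @param window Number of trailing generations to average (default 50).
#' @return List with elements `host` and `parasitoid_1` (and `parasitoid_2`
#'   when present), each containing `persisted`, `final_density`,
#'   `final_parasitism` and `final_resistance`.
#' @export
classify_outcome <- function(traj, window = 50) {
  s <- traj$states
  thr <- traj$config$extinction_threshold
  n <- nrow(s)
  idx <- seq.int(max(1L, n - window + 1L), n)
  last <- s[n, ]
  res <- list(host = list(persisted = last$N >= thr, final_density = last$N))
  res$parasitoid_1 <- list(
    persisted = last$P >= thr, final_density = last$P,
    final_parasitism = mean(s$rate_p[idx], na.rm = TRUE),
    final_resistance = mean(s$alpha_p[idx], na.rm = TRUE))
  if (length(traj$parasitoids) > 1) {
    intro <- traj$parasitoids[[2]]$introduction_generation
    idx2 <- idx[s$generation[idx] > intro]
    res$parasitoid_2 <- list(
      persisted = !is.na(last$Y) && last$Y >= thr,
      final_density = last$Y,
      final_parasitism = mean(s$rate_y[idx2], na.rm = TRUE),
      final_resistance = mean(s$alpha_y[idx2], na.rm = TRUE))
  }
  res
}

#' @export
print.trajectory <- function(x, ...) {
  np <- length(x$parasitoids)
  cat(sprintf("<trajectory> %d generations, %d parasitoid%s\n",
              nrow(x$states) - 1L, np, if (np > 1) "s" else ""))
  oc <- x$outcome
  for (nm in setdiff(names(oc), "host")) {
    o <- oc[[nm]]
    cat(sprintf("  %s: %s, final parasitism %.3f, final resistance %.3f\n",
                nm, if (o$persisted) "persisted" else "extinct",
                o$final_parasitism, o$final_resistance))
  }
  invisible(x)
}

#' Tidy long format of a trajectory
#'
#' One row per generation and species, with density, mean character,
#' resistant proportion (towards that parasitoid) and parasitism rate.
#'
#' @param x A `trajectory`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame with columns `generation`, `species`, `density`,
#'   `character`, `alpha`, `parasitism_rate`.
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  s <- x$states
  pieces <- list(
    data.frame(generation = s$generation, species = "host", density = s$N,
               character = s$n_bar, alpha = NA_real_,
               parasitism_rate = NA_real_),
    data.frame(generation = s$generation, species = "parasitoid_1",
               density = s$P, character = s$p_bar, alpha = s$alpha_p,
               parasitism_rate = s$rate_p))
  if (length(x$parasitoids) > 1) {
    keep <- !is.na(s$Y)
    pieces[[3]] <- data.frame(generation = s$generation[keep],
                              species = "parasitoid_2", density = s$Y[keep],
                              character = s$y_bar[keep],
                              alpha = s$alpha_y[keep],
                              parasitism_rate = s$rate_y[keep])
  }
  out <- do.call(rbind, pieces)
  out[order(out$generation, out$species), , drop = FALSE]
}

#' Write a trajectory to CSV
#'
#' Writes the tidy long format of [as.data.frame.trajectory()].
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
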