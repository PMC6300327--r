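#' Fitness context
#'
#' Fixes a generation-t state together with the parameter sets and names the
#' focal species whose mean character will be perturbed. Log fitness and its
#' gradient are then functions of a single character value, with all densities
#' and the other species' characters held at their generation-t values.
#'
#' @param state A [system_state()] at generation t.
#' @param host A [host_params()] object.
#' @param parasitoids A list of one or two [parasitoid_params()] objects.
#' @param focal `"host"`, or the index (1 or 2) of a parasitoid, or
#'   `"parasitoid_1"` / `"parasitoid_2"`.
#' @param rate_floor Floor for cost-adjusted rates (see [sim_config()]).
#' @return An object of class `fitness_context`.
#' @export
fitness_context <- function(state, host, parasitoids, focal,
                            rate_floor = 1e-9) {
  if (inherits(parasitoids, "parasitoid_params")) parasitoids <- list(parasitoids)
  focal <- switch(as.character(focal),
                  host = "host", parasitoid_1 = 1L, parasitoid_2 = 2L,
                  `1` = 1L, `2` = 2L,
                  stop("`focal` must be 'host', 1 or 2"))
  if (is.numeric(focal) && focal > length(parasitoids))
    stop("focal parasitoid not present in the system")
  structure(list(state = state, host = host, parasitoids = parasitoids,
                 focal = focal, rate_floor = rate_floor),
            class = "fitness_context")
}

# Build the log per-capita growth function of the focal species as a function
# of its mean character, mirroring the simulator's update rule exactly.
.log_fitness_fn <- function(ctx) {
  st <- ctx$state
  N <- st$N
  P <- st$parasitoid_densities[1]
  Y <- if (length(st$parasitoid_densities) > 1) st$parasitoid_densities[2] else 0
  nb <- st$n_bar
  pb <- st$characters[1]
  yb <- if (length(st$characters) > 1) st$characters[2] else 0
  H <- .engine_host(ctx$host)
  A <- .engine_parasitoid(ctx$parasitoids[[1]])
  B <- .engine_parasitoid(if (length(ctx$parasitoids) > 1) ctx$parasitoids[[2]])
  fl <- ctx$rate_floor
  y_on <- Y > 0

  pieces <- function(nb., pb., yb.) {
    lam <- pmax(H$lam - H$Cn * nb., fl)
    g <- 1 / (1 + N * (pmax(lam, 1) - 1) / H$K)
    ep <- pmax(A$eta - A$Cp * pb., fl)
    ey <- pmax(B$eta - B$Cp * yb., fl)
    list(lam = lam, g = g,
         e1 = .escape_pieces(N, P, A$a, A$kap, ep, nb. - pb., g),
         e2 = .escape_pieces(N, Y, B$a, B$kap, ey, nb. - yb., g))
  }
  if (identical(ctx$focal, "host")) {
    if (N <= 0) stop("fitness undefined: focal species has density 0")
    function(x) {
      q <- pieces(x, pb, yb)
      log(q$lam) + log(q$g) + .ln_host_surv(x - pb, q$e1$lnf) +
        if (y_on) .ln_host_surv(x - yb, q$e2$lnf) else 0
    }
  } else if (ctx$focal == 1L) {
    if (P <= 0) stop("fitness undefined: focal species has density 0")
    function(x) {
      q <- pieces(nb, x, yb)
      log(A$c * N * q$g) - (nb - x)^2 + q$e1$lnomf +
        (if (y_on) q$e2$lnf else 0) - log(P)
    }
  } else {
    if (Y <= 0) stop("fitness undefined: focal species has density 0")
    function(x) {
      q <- pieces(nb, pb, x)
      log(B$c * N * q$g) - (nb - x)^2 + q$e2$lnomf + q$e1$lnf - log(Y)
    }
  }
}

#' Log per-capita fitness of the focal species
#'
#' Composes one generation of the population map into the log per-capita
#' growth `ln W` of the focal species (`W_n = N[t+1]/N[t]` for the host,
#' `W_p = P[t+1]/P[t]` for a parasitoid), with the focal species' mean
#' character replaced by `character_value`. Cost and resistance functions are
#' re-evaluated at the perturbed character; densities and the other species'
#' characters stay at their generation-t values.
#'
#' @param ctx A [fitness_context()].
#' @param character_value Character value at which to evaluate.
#' @return `ln W` (possibly `-Inf`, with a warning, when the composed growth
#'   factor underflows to zero).
#' @export
log_fitness <- function(ctx, character_value) {
  v <- .log_fitness_fn(ctx)(character_value)
  if (!is.finite(v)) warning("log fitness is -Inf (zero growth factor)")
  v
}

#' Fitness gradient with respect to the focal mean character
#'
#' Central finite difference
#' `[ln W(x + h) - ln W(x - h)] / (2 h)` evaluated at the focal species'
#' current mean character. This is the selection differential that, scaled by
#' the additive genetic variance, advances the mean character each
#' generation.
#'
#' @param ctx A [fitness_context()].
#' @param h Finite-difference step (character units).
#' @return Gradient (per character unit), or `NA` with a warning when either
#'   evaluation point lies outside the log domain.
#' @export
fitness_gradient <- function(ctx, h = 1e-5) {
  if (h <= 0) stop("`h` must be > 0")
  fn <- .log_fitness_fn(ctx)
  x <- if (identical(ctx$focal, "host")) ctx$state$n_bar
       else ctx$state$characters[ctx$focal]
  gv <- (fn(x + h) - fn(x - h)) / (2 * h)
  if (!is.finite(gv)) {
    warning("gradient undefined (log-domain failure); returning NA")
    return(NA_real_)
  }
  gv
}

#' Advance all mean characters by one generation
#'
#' Each present species' mean character moves by its additive genetic
#' variance times its fitness gradient (evaluated at the generation-t state,
#' before densities update). Species with zero additive genetic variance keep
#' their character exactly; absent (density 0) species' characters are
#' frozen; an undefined gradient contributes zero change.
#'
#' @param state A [system_state()].
#' @param host A [host_params()] object.
#' @param parasitoids List of one or two [parasitoid_params()] objects.
#' @param config A [sim_config()].
#' @return List with `n_bar` and `characters` (vector parallel to
#'   `parasitoids`) at generation t+1.
#' @export
update_characters <- function(state, host, parasitoids, config = sim_config()) {
  if (inherits(parasitoids, "parasitoid_params")) parasitoids <- list(parasitoids)
  h <- config$gradient_step
  n_new <- state$n_bar
  if (host$Gamma_n > 0 && state$N > 0) {
    ctx <- fitness_context(state, host, parasitoids, "host", config$rate_floor)
    gv <- suppressWarnings(fitness_gradient(ctx, h))
    if (is.finite(gv)) n_new <- state$n_bar + host$Gamma_n * gv
  }
  chars <- state$characters
  for (i in seq_along(parasitoids)) {
    p <- parasitoids[[i]]
    if (p$Gamma_p > 0 && state$parasitoid_densities[i] > 0) {
      ctx <- fitness_context(state, host, parasitoids, i, config$rate_floor)
      gv <- suppressWarnings(fitness_gradient(ctx, h))
      if (is.finite(gv)) chars[i] <- state$characters[i] + p$Gamma_p * gv
    }
  }
  list(n_bar = n_new, characters = chars)
}
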