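# Structured configuration files: one block per species mirroring the
# parameter-table field names, plus an optional simulation block.

#' Read a model configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration with blocks
#' `host`, `parasitoids` (a list of one or two blocks) and optional
#' `simulation`, and returns validated parameter objects. Field names follow
#' the parameter table: `lambda_star`/`lambda`, `K`, `C_n`, `Gamma_n`, `N0`,
#' `n0` for the host; `eta_star`/`eta`, `c`, `a`, `kappa`, `C_p`, `Gamma_p`,
#' `P0`, `p0`, `introduction_generation` for each parasitoid.
#'
#' @param path Path to the configuration file.
#' @return List with `host` ([host_params()]), `parasitoids` (list of
#'   [parasitoid_params()]) and `config` ([sim_config()]).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$host) || is.null(cfg$parasitoids))
    stop("configuration must contain `host` and `parasitoids` blocks")
  hb <- cfg$host
  host <- host_params(
    lambda_star = hb$lambda_star %||% hb$lambda,
    K = hb$K,
    C_n = hb$C_n %||% 1,
    Gamma_n = hb$Gamma_n %||% 0.01,
    N0 = hb$N0 %||% hb$K,
    n0 = hb$n0 %||% 1)
  ps <- lapply(cfg$parasitoids, function(pb)
    parasitoid_params(
      eta_star = pb$eta_star %||% pb$eta,
      c = pb$c, a = pb$a, kappa = pb$kappa,
      C_p = pb$C_p %||% 1,
      Gamma_p = pb$Gamma_p %||% 0,
      P0 = pb$P0 %||% 10,
      p0 = pb$p0 %||% 0.9,
      introduction_generation = pb$introduction_generation %||% 0))
  sb <- cfg$simulation %||% list()
  config <- sim_config(
    generations = sb$generations %||% 300,
    gradient_step = sb$gradient_step %||% 1e-5,
    extinction_threshold = sb$extinction_threshold %||% 1e-6,
    rate_floor = sb$rate_floor %||% 1e-9,
    zero_on_extinction = sb$zero_on_extinction %||% FALSE,
    seed = sb$seed)
  list(host = host, parasitoids = ps, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
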