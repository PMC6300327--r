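# Global sensitivity analysis of the two-species model: Latin hypercube
# sampling over the documented parameter ranges, partial rank correlation
# coefficients against the resistant proportion at a chosen generation, and
# bootstrap confidence intervals.

#' Default parameter ranges for the sensitivity analysis
#'
#' The uniform sampling ranges for the 14 model parameters (growth rate,
#' carrying capacity, attack rate, larval survival, spatial heterogeneity,
#' searching efficiency, both additive genetic variances, both character
#' costs, both initial densities and both initial characters), as shipped in
#' the packaged parameter table.
#'
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
parameter_ranges <- function() {
  tab <- utils::read.csv(system.file("extdata", "table1_parameters.csv",
                                     package = "coevoBC"))
  data.frame(name = tab$parameter, low = tab$range_low, high = tab$range_high)
}

#' Latin hypercube sample over parameter ranges
#'
#' Each parameter's range is stratified into `n` equal-probability intervals
#' with exactly one uniform draw per interval, and strata are randomly
#' permuted per column (via [lhs::randomLHS()]).
#'
#' @param ranges Data frame with columns `name`, `low`, `high`
#'   (default [parameter_ranges()]).
#' @param n Number of samples (>= 2).
#' @param seed Optional integer seed; a fixed seed reproduces the matrix.
#' @return `n` x `nrow(ranges)` numeric matrix with parameter names as
#'   column names.
#' @export
latin_hypercube_sample <- function(ranges = parameter_ranges(), n, seed = NULL) {
  if (n < 2) stop("`n` must be >= 2")
  if (any(!is.finite(ranges$low)) || any(!is.finite(ranges$high)) ||
      any(ranges$low >= ranges$high))
    stop("invalid parameter range: `low` must be < `high`")
  if (!is.null(seed)) set.seed(seed)
  U <- lhs::randomLHS(n, nrow(ranges))
  X <- sweep(sweep(U, 2, ranges$high - ranges$low, "*"), 2, ranges$low, "+")
  colnames(X) <- ranges$name
  X
}

# Midranked copy of a matrix/vector, column-wise.
.colranks <- function(x) apply(as.matrix(x), 2, rank)

#' Partial rank correlation coefficients
#'
#' For each parameter, the correlation between the residuals of the ranked
#' parameter regressed on all other ranked parameters and the residuals of
#' the ranked response regressed on the same set: a monotone-association
#' measure with the linear (on ranks) influence of the other inputs removed.
#' P-values use the t-transform of the partial correlation with
#' `n - n_params - 1` degrees of freedom. Ties receive midranks. Linear
#' dependence among the ranked parameter columns is reported as a
#' collinearity error.
#'
#' @param samples Numeric matrix (`n` x `k`) of parameter samples with column
#'   names.
#' @param response Numeric vector of length `n`.
#' @return Object of class `prcc_result`: a data frame with columns
#'   `parameter`, `coefficient`, `p_value`, plus attributes `n` and `df`.
#' @export
prcc <- function(samples, response) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  k <- ncol(samples)
  if (n <= k + 2) stop("need more samples than parameters (+2)")
  if (any(apply(samples, 2, stats::sd) == 0) || stats::sd(response) == 0)
    stop("constant column: PRCC undefined")
  R <- .colranks(cbind(samples, .response = response))
  if (qr(cbind(1, R[, seq_len(k), drop = FALSE]))$rank < k + 1L)
    stop("collinear design: ranked parameter columns are linearly dependent")
  coefs <- vapply(seq_len(k), function(j) {
    others <- cbind(1, R[, setdiff(seq_len(k), j), drop = FALSE])
    rx <- stats::residuals(stats::lm.fit(others, R[, j]))
    ry <- stats::residuals(stats::lm.fit(others, R[, k + 1L]))
    stats::cor(rx, ry)
  }, numeric(1))
  df <- n - k - 1L
  tstat <- coefs * sqrt(df / pmax(1 - coefs^2, .Machine$double.eps))
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  structure(data.frame(parameter = colnames(samples), coefficient = coefs,
                       p_value = pval, row.names = NULL),
            class = c("prcc_result", "data.frame"), n = n, df = df)
}

#' Bootstrap confidence intervals for PRCCs
#'
#' Resamples design rows with replacement, recomputes the PRCCs, and reports
#' empirical percentile intervals. A degenerate resample (constant column) is
#' redrawn with a warning.
#'
#' @param samples,response As in [prcc()].
#' @param n_boot Number of bootstrap replicates (default 50).
#' @param seed Optional integer seed.
#' @param level Confidence level (default 0.95).
#' @return A `prcc_result` data frame with additional columns `ci_lower`,
#'   `ci_upper`; attribute `n_boot`.
#' @export
bootstrap_prcc <- function(samples, response, n_boot = 50, seed = NULL,
                           level = 0.95) {
  if (n_boot < 2) stop("`n_boot` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  samples <- as.matrix(samples)
  point <- prcc(samples, response)
  n <- nrow(samples)
  reps <- matrix(NA_real_, n_boot, ncol(samples))
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- tryCatch(prcc(samples[idx, , drop = FALSE], response[idx]),
                  error = function(e) NULL)
    if (is.null(r)) {
      warning("degenerate bootstrap resample skipped and redrawn")
      next
    }
    reps[b, ] <- r$coefficient
    b <- b + 1L
  }
  qs <- apply(reps, 2, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  point$ci_lower <- pmin(qs[1, ], point$coefficient)
  point$ci_upper <- pmax(qs[2, ], point$coefficient)
  attr(point, "n_boot") <- n_boot
  point
}

#' @export
print.prcc_result <- function(x, ...) {
  cat(sprintf("Partial rank correlation coefficients (n = %d, df = %d)\n",
              attr(x, "n"), attr(x, "df")))
  print.data.frame(x[order(-abs(x$coefficient)), , drop = FALSE],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full sensitivity analysis
#'
#' Draws a Latin hypercube sample over the parameter ranges, runs the
#' two-species model for each parameter combination, records the resistant
#' proportion at generation `t_eval` as the response, and computes PRCCs with
#' bootstrap confidence intervals. Runs in which the host collapses keep
#' their last defined resistant proportion (characters freeze when a
#' population is gone), so no rows are dropped.
#'
#' @param ranges Parameter ranges (default [parameter_ranges()]).
#' @param n_samples Number of LHS samples (default 6000).
#' @param t_eval Generation at which the response is read (default 300).
#' @param n_boot Bootstrap replicates (default 50).
#' @param seed Optional integer seed for the design and the bootstrap.
#' @return List of class `sensitivity_result` with `design` (the sample
#'   matrix), `response` (alpha at `t_eval`), and `result` (the
#'   `prcc_result` with confidence intervals).
#' @export
run_sensitivity <- function(ranges = parameter_ranges(), n_samples = 6000,
                            t_eval = 300, n_boot = 50, seed = NULL) {
  X <- latin_hypercube_sample(ranges, n_samples, seed = seed)
  need <- c("lambda", "K", "eta", "c", "kappa", "a", "Gamma_n", "Gamma_p",
            "C_n", "C_p", "N0", "P0", "n0", "p0")
  missing <- setdiff(need, colnames(X))
  if (length(missing))
    stop("ranges must cover: ", paste(missing, collapse = ", "))
  d <- as.data.frame(X)
  fin <- .batch_two_species(lam = d$lambda, K = d$K, eta = d$eta, c = d$c,
                            kap = d$kappa, a = d$a, Gn = d$Gamma_n,
                            Gp = d$Gamma_p, Cn = d$C_n, Cp = d$C_p,
                            N0 = d$N0, P0 = d$P0, n0 = d$n0, p0 = d$p0,
                            gens = t_eval)
  res <- bootstrap_prcc(X, fin$alpha, n_boot = n_boot, seed = seed)
  structure(list(design = X, response = fin$alpha, result = res,
                 t_eval = t_eval),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d LHS samples, response = resistant proportion at t = %d\n",
              nrow(x$design), x$t_eval))
  print(x$result)
  invisible(x)
}
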