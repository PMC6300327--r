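# Synthetic site-by-year field parasitism observations: a beta-binomial
# stand-in for published nationwide dissection surveys, so the
# model-versus-field comparison machinery is fully testable offline.

#' Generate synthetic field parasitism data
#'
#' Site-level true parasitism rates are drawn from a beta distribution with
#' mean `true_mean` and intra-class correlation `dispersion` (the fraction of
#' maximal between-site variance: site variance equals
#' `dispersion * true_mean * (1 - true_mean)`). Observed proportions are
#' binomial draws of `n_per_site` dissected weevils at each site's true rate.
#'
#' @param true_mean Population-level mean parasitism proportion in \[0, 1\].
#' @param dispersion Between-site spread in (0, 1); values near 0 make all
#'   sites share the mean.
#' @param n_sites Number of sites.
#' @param n_per_site Weevils dissected per site (>= 1).
#' @param year Year index stored with each record (default 1).
#' @param seed Optional integer seed.
#' @return Data frame of class `field_dataset` with columns `site`, `year`,
#'   `parasitism`, `n`.
#' @export
generate_field_data <- function(true_mean, dispersion, n_sites, n_per_site,
                                year = 1, seed = NULL) {
  if (true_mean < 0 || true_mean > 1) stop("`true_mean` must be in [0, 1]")
  if (dispersion <= 0 || dispersion >= 1)
    stop("invalid dispersion: must lie strictly between 0 and 1")
  if (n_sites < 1 || n_per_site < 1) stop("`n_sites` and `n_per_site` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (true_mean == 0 || true_mean == 1) {
    p_site <- rep(true_mean, n_sites)       # degenerate beta
  } else {
    phi <- (1 - dispersion) / dispersion    # beta precision
    p_site <- stats::rbeta(n_sites, true_mean * phi, (1 - true_mean) * phi)
  }
  obs <- stats::rbinom(n_sites, n_per_site, p_site) / n_per_site
  structure(data.frame(site = seq_len(n_sites), year = year,
                       parasitism = obs, n = n_per_site),
            class = c("field_dataset", "data.frame"))
}

.validate_field <- function(d) {
  need <- c("site", "year", "parasitism", "n")
  if (!all(need %in% names(d)))
    stop("field data must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(d$parasitism) | d$parasitism < 0 | d$parasitism > 1)
  if (length(bad))
    stop("parasitism proportion out of [0, 1] in row(s): ",
         paste(bad, collapse = ", "))
  bad_n <- which(!is.finite(d$n) | d$n < 1)
  if (length(bad_n))
    stop("sample size < 1 in row(s): ", paste(bad_n, collapse = ", "))
  structure(d, class = c("field_dataset", "data.frame"))
}

#' Read / write site-level field parasitism CSV
#'
#' The CSV carries one row per site and year with columns
#' `site, year, parasitism, n`. Reading validates every row (proportions in
#' \[0, 1\], sample sizes >= 1) and reports offending row numbers; an empty
#' file yields an empty dataset with a warning. Writing then reading returns
#' an identical dataset.
#'
#' @param path CSV file path.
#' @return A `field_dataset` data frame.
#' @export
read_field_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty field-data file: returning an empty dataset")
    return(structure(data.frame(site = integer(), year = integer(),
                                parasitism = numeric(), n = numeric()),
                     class = c("field_dataset", "data.frame")))
  }
  d <- utils::read.csv(path)
  .validate_field(d)
}

#' @rdname read_field_csv
#' @param dataset A `field_dataset` (or compatible data frame).
#' @export
write_field_csv <- function(dataset, path) {
  dataset <- .validate_field(as.data.frame(dataset))
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}
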