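#' Fluctuation-assay experiment
#'
#' Resistant-colony counts from parallel cultures grown from small inocula
#' and plated on selective medium. Under the classical assumptions (constant
#' mutation rate per cell division, deterministic doubling of mutant clones,
#' no differential fitness) the counts follow the heavy-tailed
#' Luria-Delbruck distribution, parameterised by m, the expected number of
#' mutational events per culture.
#'
#' @param counts Non-negative integer resistant-colony counts, one per
#'   culture (at least 2 cultures).
#' @param n_final Cells per culture at plating (N_t), positive.
#' @param plating_fraction Fraction of each culture plated, in (0, 1].
#' @return An object of class `FluctuationExperiment`.
#' @export
fluctuation_experiment <- function(counts, n_final, plating_fraction = 1) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop2("need at least 2 cultures")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop2("counts must be non-negative integers")
  }
  if (!is.finite(n_final) || n_final <= 0) stop2("n_final must be positive")
  if (plating_fraction <= 0 || plating_fraction > 1) {
    stop2("plating_fraction must be in (0, 1]")
  }
  structure(list(counts = counts, n_final = as.numeric(n_final),
                 plating_fraction = as.numeric(plating_fraction)),
            class = "FluctuationExperiment")
}

# Lower-median convention: for an even number of cultures take the lower of
# the two central order statistics, so the median is always an observed count.
lower_median <- function(x) sort(x)[floor((length(x) + 1) / 2)]

# Invert the Lea-Coulson median equation r/m - ln(m) = 1.24 for a given
# median count r. The residual is strictly decreasing in m, so the root is
# unique; solved by uniroot to ~1e-12.
.m_from_median <- function(r_med) {
  g <- function(m) r_med / m - log(m) - 1.24
  upper <- max(10, 10 * r_med)
  while (g(upper) > 0) upper <- upper * 10
  stats::uniroot(g, c(1e-12, upper), tol = 1e-12)$root
}

#' Estimate mutations per culture by the method of the median
#'
#' Solves the Lea-Coulson median equation `r/m - ln(m) = 1.24` for m, where
#' r is the (lower) median resistant-colony count. Requires a positive
#' median; when most cultures carry no mutants use [estimate_m_p0()].
#'
#' @param experiment A [fluctuation_experiment()].
#' @return m, the estimated expected number of mutational events per culture.
#' @examples
#' expt <- fluctuation_experiment(c(0, 1, 5, 5, 7, 30), n_final = 1e7)
#' estimate_m_median(expt)
#' @export
estimate_m_median <- function(experiment) {
  stopifnot(inherits(experiment, "FluctuationExperiment"))
  r_med <- lower_median(experiment$counts)
  if (r_med <= 0) {
    stop2("median count is 0: the median method is undefined; use estimate_m_p0()")
  }
  m <- .m_from_median(r_med)
  ms_log("median method: r_med=%g -> m=%.6g", r_med, m)
  m
}

#' Estimate mutations per culture from the zero-count fraction
#'
#' The p0 method: under the Luria-Delbruck model the probability that a
#' culture acquires no mutation is `exp(-m)`, so `m = -ln(p0)` with p0 the
#' observed fraction of cultures with zero resistant colonies.
#'
#' @inheritParams estimate_m_median
#' @return m.
#' @export
estimate_m_p0 <- function(experiment) {
  stopifnot(inherits(experiment, "FluctuationExperiment"))
  p0 <- mean(experiment$counts == 0)
  if (p0 == 0) {
    stop2("no zero-count cultures: the p0 method is undefined; use estimate_m_median()")
  }
  -log(p0)
}

#' Convert m to a mutation rate per locus per generation
#'
#' Divides m by the number of cell divisions represented by one culture,
#' `mu = m / N_t` with N_t the final population (the plating fraction, if
#' below 1, scales N_t up to the full culture). The alternative divisor
#' `2 * N_t` is available behind `per_division`. The returned rate and its
#' confidence limits are carried on the x1e-7 scale.
#'
#' @param m Estimated mutations per culture (from [estimate_m_median()] or
#'   [estimate_m_p0()]).
#' @param experiment The [fluctuation_experiment()] m was estimated from.
#' @param method `"median"` or `"p0"`; used to pick the confidence-interval
#'   construction and recorded in the estimate.
#' @param per_division If `TRUE`, divide by `2 * N_t` instead of `N_t`.
#' @param level Confidence level for the interval.
#' @return An object of class `RateEstimate` with fields `m`, `rate`,
#'   `ci_low`, `ci_high` (all rates x1e-7 per locus per generation) and
#'   `method`.
#' @export
rate_from_m <- function(m, experiment, method = c("median", "p0"),
                        per_division = FALSE, level = 0.95) {
  stopifnot(inherits(experiment, "FluctuationExperiment"), m >= 0)
  method <- match.arg(method)
  n_eff <- experiment$n_final / experiment$plating_fraction
  if (per_division) n_eff <- 2 * n_eff
  rate <- m / n_eff * 1e7
  if (m == 0) {
    ci <- c(0, 0)
    up <- tryCatch(rate_confidence_interval(experiment, method, level,
                                            per_division = per_division),
                   error = function(e) NULL)
    if (!is.null(up)) ci <- c(0, up[2])
  } else {
    ci <- rate_confidence_interval(experiment, method, level,
                                   per_division = per_division)
  }
  structure(list(m = m, rate = rate, ci_low = min(ci[1], rate),
                 ci_high = max(ci[2], rate), method = method),
            class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
  cat(sprintf("Mutation rate %.3g x1e-7 per locus per generation (95%% CI %.3g-%.3g), m=%.3g, %s method\n",
              x$rate, x$ci_low, x$ci_high, x$m, x$method))
  invisible(x)
}

#' Estimate the mutation rate from a fluctuation experiment
#'
#' Convenience wrapper: chooses the median method when the median count is
#' positive, otherwise the p0 method, and returns a full `RateEstimate`.
#'
#' @inheritParams estimate_m_median
#' @inheritParams rate_from_m
#' @export
estimate_rate <- function(experiment, method = NULL, per_division = FALSE,
                          level = 0.95) {
  if (is.null(method)) {
    method <- if (lower_median(experiment$counts) > 0) "median" else "p0"
  }
  m <- switch(method,
              median = estimate_m_median(experiment),
              p0 = estimate_m_p0(experiment),
              stop2("unknown method '%s'", method))
  rate_from_m(m, experiment, method, per_division, level)
}

#' Confidence interval for the mutation rate
#'
#' Nonparametric interval, free of distributional assumptions beyond the
#' Luria-Delbruck model itself. For the median method the interval is built
#' from exact order-statistic bounds on the population median count
#' (binomial argument at p = 1/2), transformed through the strictly
#' monotone median estimator; for the p0 method it is the Clopper-Pearson
#' interval for the zero-count probability transformed through `-ln`.
#' With fewer than 5 cultures the order-statistic bounds degenerate to the
#' sample range and a warning is issued.
#'
#' @inheritParams rate_from_m
#' @param experiment A [fluctuation_experiment()].
#' @return `c(ci_low, ci_high)` on the x1e-7 rate scale.
#' @export
rate_confidence_interval <- function(experiment, method = c("median", "p0"),
                                     level = 0.95, per_division = FALSE) {
  stopifnot(inherits(experiment, "FluctuationExperiment"))
  method <- match.arg(method)
  counts <- experiment$counts
  n <- length(counts)
  alpha <- 1 - level
  if (method == "median") {
    srt <- sort(counts)
    if (n < 5) {
      warning("fewer than 5 cultures: widening to the sample range")
      r_lo <- srt[1]; r_hi <- srt[n]
    } else {
      k_lo <- stats::qbinom(alpha / 2, n, 0.5)
      k_hi <- stats::qbinom(1 - alpha / 2, n, 0.5) + 1L
      r_lo <- srt[max(1L, k_lo)]
      r_hi <- srt[min(n, k_hi)]
    }
    m_lo <- if (r_lo > 0) .m_from_median(r_lo) else 0
    m_hi <- if (r_hi > 0) .m_from_median(r_hi) else 0
  } else {
    n0 <- sum(counts == 0)
    if (n0 == 0) stop2("p0 interval undefined: no zero-count cultures")
    ci_p <- stats::binom.test(n0, n)$conf.int
    m_lo <- -log(min(ci_p[2], 1))
    m_hi <- -log(ci_p[1])
  }
  n_eff <- experiment$n_final / experiment$plating_fraction
  if (per_division) n_eff <- 2 * n_eff
  c(m_lo, m_hi) / n_eff * 1e7
}

#' Read culture counts for fluctuation experiments
#'
#' Reads a TSV with columns `experiment_id, count` and returns a named list
#' of [fluctuation_experiment()] objects, one per experiment id. Culture
#' metadata (final population, plating fraction) is supplied by the caller,
#' matching the convention that plating details live in configuration, not
#' in the counts file.
#'
#' @param tsv_path Path to the counts file.
#' @inheritParams fluctuation_experiment
#' @return Named list of `FluctuationExperiment`s.
#' @export
read_culture_counts <- function(tsv_path, n_final, plating_fraction = 1) {
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  if (!all(c("experiment_id", "count") %in% names(tab))) {
    stop2("%s must have columns experiment_id, count", tsv_path)
  }
  lapply(split(tab$count, tab$experiment_id), fluctuation_experiment,
         n_final = n_final, plating_fraction = plating_fraction)
}
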