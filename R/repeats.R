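#' Annotate homopolymer runs in a sequence
#'
#' Finds all maximal runs of identical bases of at least `min_len`
#' consecutive copies, on the coding strand. A run and its complementary
#' run on the other strand are the same physical site and are reported once
#' with the coding-strand base. Runs of length >= 2 are stored so that
#' thresholds (the slippage analyses use >= 3) remain analysis-time
#' choices.
#'
#' @param sequence ACGT string (coding strand).
#' @param min_len Minimum run length to report (default 2).
#' @return data.frame with columns `start` (1-based), `end`, `length`,
#'   `base`, sorted by start.
#' @examples
#' annotate_runs("GAAAG")          # one A-run, 2-4
#' annotate_runs("ACGT")           # no runs at min_len 2
#' @export
annotate_runs <- function(sequence, min_len = 2) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) stop2("sequence must be non-empty ACGT")
  r <- rle(strsplit(sequence, "", fixed = TRUE)[[1]])
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$lengths >= min_len
  data.frame(start = start[keep], end = end[keep],
             length = r$lengths[keep], base = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Fraction of single-base indels falling in homopolymer runs
#'
#' Computes k/n where n is the number of single-base indel events in the
#' dataset and k the number of those lying inside a run of at least
#' `min_len` identical bases (default 3, the threshold used for the
#' headline slippage fraction). The fraction is non-increasing in
#' `min_len`.
#'
#' @param dataset A [spectrum_dataset()].
#' @param runs Run annotation from [annotate_runs()]; recomputed if `NULL`.
#' @param min_len Minimum run length counted as a mononucleotide repeat.
#' @return List with `k`, `n`, `fraction` (NA when `n == 0`).
#' @export
fraction_in_runs <- function(dataset, runs = NULL, min_len = 3) {
  stopifnot(inherits(dataset, "SpectrumDataset"))
  if (is.null(runs)) runs <- annotate_runs(dataset$locus$coding_sequence, min_len = 2)
  runs <- runs[runs$length >= min_len, , drop = FALSE]
  ev <- dataset$events[dataset$events$klass == "single_base_indel", , drop = FALSE]
  n <- nrow(ev)
  if (n == 0L) return(list(k = 0L, n = 0L, fraction = NA_real_))
  in_run <- vapply(seq_len(n), function(i) {
    base <- if (nchar(ev$ref[i])) ev$ref[i] else ev$alt[i]
    any(runs$base == base & runs$start <= ev$position[i] & runs$end >= ev$position[i])
  }, logical(1))
  k <- sum(in_run)
  list(k = k, n = n, fraction = k / n)
}

#' Relate indel site rates to homopolymer run length
#'
#' Aggregates single-base-indel site rates by the length of the run they
#' occur in and fits `ln(rate)` against run length by least squares — the
#' slippage model predicts an exponential increase of rate with run length,
#' i.e. a positive slope (reported, not enforced). Aggregation is the sum
#' of site rates per length by default (`"mean"` available).
#'
#' @param site_rate_table Output of [site_rates()].
#' @param runs Run annotation from [annotate_runs()].
#' @param aggregate `"sum"` (default) or `"mean"` of site rates per length.
#' @return List with `table` (run_length, rate, n_sites), `slope`,
#'   `intercept`, and the `lm` `fit`.
#' @export
run_length_rate_relation <- function(site_rate_table, runs,
                                     aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  ind <- site_rate_table[site_rate_table$klass == "single_base_indel", ,
                         drop = FALSE]
  if (!nrow(ind)) stop2("no single-base indel sites to relate to run length")
  idx <- match(paste(ind$start, ind$end), paste(runs$start, runs$end))
  ind$run_length <- ifelse(is.na(idx), ind$end - ind$start + 1L, runs$length[idx])
  agg_fun <- if (aggregate == "sum") sum else mean
  tab <- stats::aggregate(rate ~ run_length, data = ind, FUN = agg_fun)
  tab$n_sites <- stats::aggregate(rate ~ run_length, data = ind, FUN = length)$rate
  tab <- tab[tab$rate > 0, , drop = FALSE]
  if (length(unique(tab$run_length)) < 2L) {
    stop2("need >= 2 distinct run lengths with nonzero rates for a fit")
  }
  fit <- stats::lm(log(rate) ~ run_length, data = tab)
  list(table = tab, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit = fit)
}

#' Base composition of a sequence
#'
#' @param sequence ACGT string.
#' @return data.frame with columns `base`, `count`, `fraction`; counts sum
#'   to the sequence length.
#' @export
base_composition <- function(sequence) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) stop2("sequence must be non-empty ACGT")
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(bases, function(b)
    sum(strsplit(sequence, "", fixed = TRUE)[[1]] == b), integer(1))
  data.frame(base = bases, count = unname(cnt),
             fraction = unname(cnt) / nchar(sequence),
             stringsAsFactors = FALSE)
}
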