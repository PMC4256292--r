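#' Mismatch-repair correction factor
#'
#' The correction factor (CF) for a site or mutation class is the ratio of
#' its mutation rate in the repair-deficient (msh2-null) background to the
#' rate in the repair-proficient background: `CF = rate(MMR-) / rate(MMR+)`.
#' A CF of 32 means 31 of 32 errors are corrected by MMR. A side with zero
#' observed events contributes its one-event upper bound and the CF becomes
#' a one-sided bound: zero events on the MMR+ side (denominator) makes the
#' CF a lower bound, zero on the MMR- side an upper bound; zero on both
#' sides is indeterminate and no number is reported.
#'
#' @param dataset_mmr_minus [spectrum_dataset()] for the MMR-deficient
#'   strain.
#' @param dataset_mmr_plus [spectrum_dataset()] for the MMR-proficient
#'   strain (same locus, same pool background).
#' @param klass Mutation class (`"substitution"`, `"single_base_indel"`,
#'   `"complex"`), or one of the indel categories `"indel_AT"` /
#'   `"indel_GC"` (single-base indels gaining/losing an A or T vs a G or
#'   C), or `NULL` when scoring a site.
#' @param site Site key as produced by [site_rates()] (e.g. `"648:C>A"` or
#'   `"757-760:-G"`), or `NULL` when scoring a class.
#' @return An object of class `CorrectionFactor`: list with `scope`, `cf`,
#'   `bound` (`"exact"`, `"lower_bound"`, `"upper_bound"`,
#'   `"indeterminate"`), numerator/denominator rates (x1e-7), bound flags
#'   and event counts.
#' @examples
#' \dontrun{
#' correction_factor(ds_double, ds_rnr1, klass = "single_base_indel")
#' }
#' @export
correction_factor <- function(dataset_mmr_minus, dataset_mmr_plus,
                              klass = NULL, site = NULL) {
  stopifnot(inherits(dataset_mmr_minus, "SpectrumDataset"),
            inherits(dataset_mmr_plus, "SpectrumDataset"))
  if (dataset_mmr_minus$locus$coding_sequence !=
      dataset_mmr_plus$locus$coding_sequence) {
    stop2("datasets are not on the same locus")
  }
  if (!dataset_mmr_minus$background$mmr_deficient) {
    stop2("dataset_mmr_minus must be flagged mmr_deficient")
  }
  if (dataset_mmr_plus$background$mmr_deficient) {
    stop2("dataset_mmr_plus must not be flagged mmr_deficient")
  }
  if (is.null(klass) == is.null(site)) {
    stop2("supply exactly one of klass or site")
  }
  side <- function(ds) {
    if (!is.null(klass)) {
      ev <- ds$events
      if (klass %in% c("indel_AT", "indel_GC")) {
        want <- if (klass == "indel_AT") c("A", "T") else c("G", "C")
        base <- ifelse(nchar(ev$ref) > 0, ev$ref, ev$alt)
        cnt <- sum(ev$klass == "single_base_indel" & base %in% want)
      } else {
        cnt <- sum(ev$klass == klass)
      }
      rate <- if (cnt > 0) cnt / ds$n_isolates * ds$overall_rate
              else one_event_bound(ds)
      list(count = cnt, rate = rate, is_bound = cnt == 0)
    } else {
      lk <- .site_rate_lookup(ds, site)
      list(count = lk$count, rate = lk$rate, is_bound = lk$is_bound)
    }
  }
  num <- side(dataset_mmr_minus)
  den <- side(dataset_mmr_plus)
  bound <- if (num$is_bound && den$is_bound) "indeterminate"
           else if (den$is_bound) "lower_bound"
           else if (num$is_bound) "upper_bound"
           else "exact"
  cf <- if (bound == "indeterminate") NA_real_ else num$rate / den$rate
  structure(
    list(scope = if (!is.null(klass)) klass else site, cf = cf, bound = bound,
         numerator_rate = num$rate, numerator_bound = num$is_bound,
         numerator_count = num$count,
         denominator_rate = den$rate, denominator_bound = den$is_bound,
         denominator_count = den$count),
    class = "CorrectionFactor"
  )
}

#' @export
print.CorrectionFactor <- function(x, ...) {
  pfx <- switch(x$bound, exact = "", lower_bound = ">", upper_bound = "<",
                indeterminate = "indeterminate")
  cat(sprintf("MMR correction factor [%s]: %s%s (MMR- %.3g vs MMR+ %.3g x1e-7)\n",
              x$scope,
              if (x$bound == "indeterminate") "" else pfx,
              if (is.na(x$cf)) "no events on either side" else sprintf("%.3g", x$cf),
              x$numerator_rate, x$denominator_rate))
  invisible(x)
}

#' Per-site correction factors over the union of observed sites
#'
#' @inheritParams correction_factor
#' @param sites Site keys to score; defaults to the union of sites observed
#'   in either dataset.
#' @return data.frame with one row per site: `site, cf, bound,
#'   rate_mmr_minus, rate_mmr_plus, count_mmr_minus, count_mmr_plus`.
#' @export
site_correction_factors <- function(dataset_mmr_minus, dataset_mmr_plus,
                                    sites = NULL) {
  if (is.null(sites)) {
    sites <- union(site_rates(dataset_mmr_minus)$site,
                   site_rates(dataset_mmr_plus)$site)
  }
  num <- .site_rate_lookup(dataset_mmr_minus, sites,
                           sr = site_rates(dataset_mmr_minus))
  den <- .site_rate_lookup(dataset_mmr_plus, sites,
                           sr = site_rates(dataset_mmr_plus))
  bound <- ifelse(num$is_bound & den$is_bound, "indeterminate",
           ifelse(den$is_bound, "lower_bound",
           ifelse(num$is_bound, "upper_bound", "exact")))
  data.frame(site = sites,
             cf = ifelse(bound == "indeterminate", NA_real_,
                         num$rate / den$rate),
             bound = bound,
             rate_mmr_minus = num$rate, rate_mmr_plus = den$rate,
             count_mmr_minus = num$count, count_mmr_plus = den$count,
             stringsAsFactors = FALSE)
}

#' Ratio of correction factors between two backgrounds
#'
#' Compares MMR efficiency on the same scope across genetic backgrounds
#' (e.g. normal vs imbalanced dNTP pools). The ratio carries the weaker of
#' the two bound flags: it is `"exact"` only when both CFs are exact.
#'
#' @param cf_a,cf_b [correction_factor()] objects with the same scope.
#' @return List with `ratio` (cf_a / cf_b) and `bound`.
#' @export
cf_ratio <- function(cf_a, cf_b) {
  stopifnot(inherits(cf_a, "CorrectionFactor"), inherits(cf_b, "CorrectionFactor"))
  if (cf_a$bound == "indeterminate" || cf_b$bound == "indeterminate") {
    return(list(ratio = NA_real_, bound = "indeterminate"))
  }
  bound <- if (cf_a$bound == "exact" && cf_b$bound == "exact") "exact"
           else if (cf_a$bound != "exact") cf_a$bound
           else if (cf_b$bound == "lower_bound") "upper_bound" else "lower_bound"
  list(ratio = cf_a$cf / cf_b$cf, bound = bound)
}

#' Classify the origin of a double-mutant hotspot
#'
#' Hotspots of the pool-imbalance + MMR-null double mutant are classified by
#' which single mutant already shows them: sites hot only in the MMR-null
#' single are pre-existing repair-sensitive sites further enhanced by the
#' pool imbalance (`"pool_driven"`); sites hot only in the pool-imbalance
#' single are misinsertion sites further enhanced by loss of repair
#' (`"mmr_driven"`); sites hot in both singles are `"synergistic"`. Sites
#' that are not hotspots in the double mutant are excluded (`NA`).
#'
#' @param in_pool_single,in_mmr_single,in_double Logical vectors: is the
#'   site a hotspot in the pool-imbalance single mutant, the MMR-null
#'   single mutant, the double mutant?
#' @return Character vector: `"pool_driven"`, `"mmr_driven"`,
#'   `"synergistic"`, or `NA` (excluded: not a double-mutant hotspot, or a
#'   double-only hotspot seen in neither single).
#' @export
classify_hotspot_origin <- function(in_pool_single, in_mmr_single, in_double) {
  n <- length(in_double)
  stopifnot(length(in_pool_single) == n, length(in_mmr_single) == n)
  out <- rep(NA_character_, n)
  elig <- in_double
  if (any(!elig)) {
    ms_log("hotspot origin: %d site(s) excluded (not hotspots in the double mutant)",
           sum(!elig))
  }
  out[elig & in_mmr_single & !in_pool_single] <- "pool_driven"
  out[elig & !in_mmr_single & in_pool_single] <- "mmr_driven"
  out[elig & in_mmr_single & in_pool_single] <- "synergistic"
  out
}

#' Hotspot origin classification table for three mutant strains
#'
#' @param hot_pool,hot_mmr,hot_double Hotspot tables from
#'   [detect_hotspots()] for the pool-imbalance single, the MMR-null single
#'   and the double mutant.
#' @return data.frame over the double mutant's hotspot sites with logical
#'   presence columns and the `origin` classification.
#' @export
hotspot_origin_table <- function(hot_pool, hot_mmr, hot_double) {
  sites <- hot_double$site
  in_pool <- sites %in% hot_pool$site
  in_mmr <- sites %in% hot_mmr$site
  data.frame(site = sites, in_pool_single = in_pool, in_mmr_single = in_mmr,
             origin = classify_hotspot_origin(in_pool, in_mmr,
                                              rep(TRUE, length(sites))),
             stringsAsFactors = FALSE)
}
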