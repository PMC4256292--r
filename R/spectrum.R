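#' Classify a mutation event
#'
#' A single-base substitution is `|ref| = |alt| = 1`, `ref != alt`, with
#' subtype transition (purine to purine / pyrimidine to pyrimidine) or
#' transversion. A single-base indel has one empty side and one base on the
#' other (subtype insertion or deletion). Everything else — multi-base
#' insertions, deletions or replacements — is complex/other.
#'
#' @param ref,alt Reference and alternate strings over ACGT; `""` (or `"."`)
#'   for the empty side of an indel.
#' @return `classify_event()`: list with `klass` and `subtype`.
#' @examples
#' classify_event("C", "A")   # substitution / transversion
#' classify_event("G", "A")   # substitution / transition
#' classify_event("A", "")    # single_base_indel / deletion
#' @export
classify_event <- function(ref, alt) {
  out <- classify_events(ref, alt)
  list(klass = out$klass[1], subtype = out$subtype[1])
}

#' @rdname classify_event
#' @return `classify_events()`: data.frame with columns `klass`, `subtype`
#'   (vectorised over `ref`, `alt`).
#' @export
classify_events <- function(ref, alt) {
  ref <- toupper(ifelse(is.na(ref) | ref == ".", "", ref))
  alt <- toupper(ifelse(is.na(alt) | alt == ".", "", alt))
  ok <- grepl("^[ACGT]*$", ref) & grepl("^[ACGT]*$", alt)
  if (any(!ok)) stop2("ref/alt must be strings over ACGT (or empty)")
  if (any(ref == alt)) stop2("ref equals alt ('%s'): not a mutation", ref[ref == alt][1])
  nr <- nchar(ref); na_ <- nchar(alt)
  klass <- ifelse(nr == 1L & na_ == 1L, "substitution",
           ifelse(abs(nr - na_) == 1L & pmin(nr, na_) == 0L,
                  "single_base_indel", "complex"))
  subtype <- rep("other", length(ref))
  is_sub <- klass == "substitution"
  subtype[is_sub] <- ifelse(is_purine(ref[is_sub]) == is_purine(alt[is_sub]),
                            "transition", "transversion")
  is_ind <- klass == "single_base_indel"
  subtype[is_ind] <- ifelse(na_[is_ind] > nr[is_ind], "insertion", "deletion")
  data.frame(klass = klass, subtype = subtype, stringsAsFactors = FALSE)
}

#' Class-specific mutation rate
#'
#' The rate attributed to one mutation class is the fraction of sequenced
#' isolates carrying an event of that class times the strain's overall
#' mutation rate: `rate = (events of class / n_isolates) * overall_rate`.
#' The denominator is the number of isolates sequenced, not the total event
#' count; with the published per-strain counts this reproduces the printed
#' class rates (e.g. wild-type single-base indels 11/93 * 4.2 = 0.5 x1e-7).
#'
#' @param dataset A [spectrum_dataset()].
#' @param klass `"substitution"`, `"single_base_indel"` or `"complex"`.
#' @return Rate on the x1e-7 scale.
#' @export
class_rate <- function(dataset, klass = c("substitution", "single_base_indel",
                                          "complex")) {
  stopifnot(inherits(dataset, "SpectrumDataset"), dataset$n_isolates > 0)
  klass <- match.arg(klass)
  n_ev <- sum(dataset$events$klass == klass)
  n_ev / dataset$n_isolates * dataset$overall_rate
}

#' One-event upper-bound rate
#'
#' The rate a single observed event would imply for this dataset,
#' `overall_rate / n_isolates`. Used as a conservative stand-in whenever a
#' site or class with zero observed events enters a ratio, and reported with
#' an explicit bound flag rather than folded silently into the number.
#'
#' @inheritParams class_rate
#' @return Rate on the x1e-7 scale.
#' @export
one_event_bound <- function(dataset) {
  stopifnot(inherits(dataset, "SpectrumDataset"))
  dataset$overall_rate / dataset$n_isolates
}

# Site key for an event: substitutions and complex events keep their own
# position and change; a single-base indel inside a homopolymer run is
# pooled over the whole run (slippage makes positions within a run
# indistinguishable), keyed by the run span and the gained/lost base.
.site_keys <- function(events, locus) {
  runs <- annotate_runs(locus$coding_sequence, min_len = 2)
  run_at <- integer(length(locus))           # position -> run row (0 = none)
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) run_at[runs$start[i]:runs$end[i]] <- i
  }
  p <- events$position; ref <- events$ref; alt <- events$alt
  is_ind <- events$klass == "single_base_indel"
  base <- ifelse(nchar(ref) > 0, ref, alt)
  hit <- ifelse(is_ind, run_at[p], 0L)
  hit[hit > 0 & runs$base[pmax(hit, 1L)] != base] <- 0L
  start <- ifelse(is_ind & hit > 0, runs$start[pmax(hit, 1L)], p)
  end <- ifelse(is_ind & hit > 0, runs$end[pmax(hit, 1L)],
                ifelse(is_ind, p, p + pmax(0L, nchar(ref) - 1L)))
  change <- ifelse(is_ind,
                   paste0(ifelse(nchar(alt) > nchar(ref), "+", "-"), base),
                   paste0(ifelse(nchar(ref) > 0, ref, "."), ">",
                          ifelse(nchar(alt) > 0, alt, ".")))
  key <- ifelse(is_ind, sprintf("%d-%d:%s", start, end, change),
                sprintf("%d:%s", p, change))
  data.frame(site = key, start = as.integer(start), end = as.integer(end),
             change = change, klass = events$klass, stringsAsFactors = FALSE)
}

#' Site-specific mutation rates
#'
#' One row per distinct mutated site: substitutions keyed by position and
#' base change, single-base indels pooled over the homopolymer run they fall
#' in (reported with the run's coordinate span, e.g. 757-760). The site rate
#' is `(events at site / n_isolates) * overall_rate`.
#'
#' @inheritParams class_rate
#' @return data.frame with columns `site, start, end, change, klass, count,
#'   rate, is_bound`, sorted by position. `is_bound` is always `FALSE` here
#'   (every row has at least one observed event); zero-event sites enter
#'   comparisons through [one_event_bound()].
#' @export
site_rates <- function(dataset) {
  stopifnot(inherits(dataset, "SpectrumDataset"))
  ev <- dataset$events
  if (!nrow(ev)) {
    return(data.frame(site = character(0), start = integer(0), end = integer(0),
                      change = character(0), klass = character(0),
                      count = integer(0), rate = numeric(0),
                      is_bound = logical(0), stringsAsFactors = FALSE))
  }
  keys <- .site_keys(ev, dataset$locus)
  agg <- stats::aggregate(list(count = seq_len(nrow(keys))), by = keys, FUN = length)
  agg$rate <- agg$count / dataset$n_isolates * dataset$overall_rate
  agg$is_bound <- FALSE
  agg <- agg[order(agg$start, agg$end, agg$change), ]
  rownames(agg) <- NULL
  agg[, c("site", "start", "end", "change", "klass", "count", "rate", "is_bound")]
}

# Rate at the given site keys, falling back to the one-event bound (flagged)
# where the dataset has no events at a site.
.site_rate_lookup <- function(dataset, sites, sr = NULL) {
  if (is.null(sr)) sr <- site_rates(dataset)
  idx <- match(sites, sr$site)
  rate <- ifelse(is.na(idx), one_event_bound(dataset), sr$rate[idx])
  data.frame(site = sites, rate = rate, count = ifelse(is.na(idx), 0L, sr$count[idx]),
             is_bound = is.na(idx), stringsAsFactors = FALSE)
}

#' Detect mutation hotspots against a wild-type baseline
#'
#' A hotspot is a site whose mutation rate is at least `fold_threshold`
#' times the wild-type rate at the same site (default 10, inclusive). Where
#' the wild type has no observed event at the site, the wild-type one-event
#' upper bound is used as the denominator, which is conservative: the true
#' fold enrichment can only be larger.
#'
#' @param dataset Mutant-strain [spectrum_dataset()].
#' @param wt_dataset Wild-type [spectrum_dataset()] on the same locus.
#' @param fold_threshold Minimum fold enrichment over wild type (inclusive).
#' @return data.frame of hotspot sites: the [site_rates()] columns plus
#'   `wt_rate`, `wt_is_bound`, `fold_over_wt`, `strain`.
#' @export
detect_hotspots <- function(dataset, wt_dataset, fold_threshold = 10) {
  stopifnot(inherits(dataset, "SpectrumDataset"),
            inherits(wt_dataset, "SpectrumDataset"))
  if (dataset$locus$coding_sequence != wt_dataset$locus$coding_sequence) {
    stop2("datasets are not on the same locus")
  }
  sr <- site_rates(dataset)
  wt <- .site_rate_lookup(wt_dataset, sr$site)
  sr$wt_rate <- wt$rate
  sr$wt_is_bound <- wt$is_bound
  sr$fold_over_wt <- sr$rate / sr$wt_rate
  sr$strain <- dataset$strain
  out <- sr[sr$fold_over_wt >= fold_threshold, , drop = FALSE]
  ms_log("hotspots: %d of %d sites at >=%g-fold over wt in '%s'",
         nrow(out), nrow(sr), fold_threshold, dataset$strain)
  rownames(out) <- NULL
  out
}

#' Compare site rates between the two gene orientations
#'
#' Builds the union of hotspot sites (or of all observed sites when no
#' wild-type baseline is given) across the natural (OR1) and reversed (OR2)
#' orientation strains and reports both rates side by side. A side with no
#' observed events carries its one-event upper bound with `bound_* = TRUE`;
#' the fold difference is then a one-sided bound, reported in `fold_cmp`
#' (`"ge"` when the unseen side is the smaller, `"le"` when it is the
#' larger, `"eq"` when both sides are observed).
#'
#' @param dataset_or1,dataset_or2 [spectrum_dataset()]s on the same locus in
#'   opposite orientations.
#' @param wt_dataset Optional wild-type baseline; when supplied only sites
#'   that are hotspots in at least one orientation are compared.
#' @param fold_threshold Hotspot threshold passed to [detect_hotspots()].
#' @return data.frame with one row per site: `site, change, klass, rate_or1,
#'   bound_or1, rate_or2, bound_or2, higher, fold, fold_cmp` (fold is the
#'   larger rate over the smaller, >= 1).
#' @export
compare_orientations <- function(dataset_or1, dataset_or2, wt_dataset = NULL,
                                 fold_threshold = 10) {
  if (dataset_or1$locus$coding_sequence != dataset_or2$locus$coding_sequence) {
    stop2("datasets are not on the same locus")
  }
  if (dataset_or1$locus$orientation == dataset_or2$locus$orientation) {
    stop2("datasets have the same orientation; expected OR1 vs OR2")
  }
  pick <- function(ds) {
    if (is.null(wt_dataset)) site_rates(ds)
    else detect_hotspots(ds, wt_dataset, fold_threshold)
  }
  s1 <- pick(dataset_or1); s2 <- pick(dataset_or2)
  sites <- unique(rbind(s1[, c("site", "change", "klass")],
                        s2[, c("site", "change", "klass")]))
  l1 <- .site_rate_lookup(dataset_or1, sites$site)
  l2 <- .site_rate_lookup(dataset_or2, sites$site)
  hi <- ifelse(l1$rate >= l2$rate, "OR1", "OR2")
  fold <- pmax(l1$rate, l2$rate) / pmin(l1$rate, l2$rate)
  fold_cmp <- ifelse(!l1$is_bound & !l2$is_bound, "eq",
              ifelse((hi == "OR1" & l2$is_bound) | (hi == "OR2" & l1$is_bound),
                     "ge", "le"))
  out <- data.frame(sites, rate_or1 = l1$rate, bound_or1 = l1$is_bound,
                    rate_or2 = l2$rate, bound_or2 = l2$is_bound,
                    higher = hi, fold = fold, fold_cmp = fold_cmp,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$site), ]
}
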