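#' Construct a spectrum dataset
#'
#' A `SpectrumDataset` bundles a strain's observed mutation events with the
#' number of independent mutant isolates sequenced and the strain's overall
#' mutation rate at the locus. The number of events may exceed the number of
#' isolates (some isolates carry more than one mutation). Rates are carried
#' on the x1e-7 per locus per generation scale throughout.
#'
#' @param strain Strain identifier.
#' @param locus A [reporter_locus()].
#' @param events A data.frame with columns `strain, isolate, position, ref,
#'   alt` (and optionally `klass, subtype`, recomputed if absent). Empty
#'   ref/alt (insertions/deletions) are `""`.
#' @param n_isolates Number of independent mutant isolates sequenced.
#' @param overall_rate Overall mutation rate per locus per generation, on the
#'   x1e-7 scale (so 4.2 means 4.2e-7).
#' @param pool_imbalanced,mmr_deficient Background flags.
#' @return An object of class `SpectrumDataset`.
#' @export
spectrum_dataset <- function(strain, locus, events, n_isolates, overall_rate,
                             pool_imbalanced = FALSE, mmr_deficient = FALSE) {
  stopifnot(inherits(locus, "ReporterLocus"))
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  needed <- c("strain", "isolate", "position", "ref", "alt")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols)) {
    stop2("events table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  events$position <- as.integer(events$position)
  events$ref <- toupper(ifelse(is.na(events$ref) | events$ref == ".", "", events$ref))
  events$alt <- toupper(ifelse(is.na(events$alt) | events$alt == ".", "", events$alt))
  if (nrow(events)) {
    cls <- classify_events(events$ref, events$alt)
    events$klass <- cls$klass
    events$subtype <- cls$subtype
    bad_pos <- which(events$position < 1L | events$position > length(locus))
    if (length(bad_pos)) {
      stop2("event %d: position %d outside locus 1..%d",
            bad_pos[1], events$position[bad_pos[1]], length(locus))
    }
    has_ref <- nchar(events$ref) > 0L
    ref_here <- substring(locus$coding_sequence, events$position,
                          events$position + nchar(events$ref) - 1L)
    bad_ref <- which(has_ref & ref_here != events$ref)
    if (length(bad_ref)) {
      i <- bad_ref[1]
      stop2("event %d: ref '%s' does not match reference '%s' at position %d",
            i, events$ref[i], ref_here[i], events$position[i])
    }
  } else {
    events$klass <- character(0)
    events$subtype <- character(0)
  }
  n_isolates <- as.integer(n_isolates)
  n_distinct <- length(unique(events$isolate))
  if (n_isolates < n_distinct) {
    stop2("n_isolates (%d) is smaller than the number of distinct isolates (%d)",
          n_isolates, n_distinct)
  }
  structure(
    list(strain = as.character(strain),
         background = list(pool_imbalanced = isTRUE(pool_imbalanced),
                           mmr_deficient = isTRUE(mmr_deficient)),
         locus = locus, events = events,
         n_isolates = n_isolates, overall_rate = as.numeric(overall_rate)),
    class = "SpectrumDataset"
  )
}

#' @export
print.SpectrumDataset <- function(x, ...) {
  cat(sprintf(
    "SpectrumDataset '%s': %d events in %d isolates; overall rate %.3g x1e-7%s%s\n",
    x$strain, nrow(x$events), x$n_isolates, x$overall_rate,
    if (x$background$pool_imbalanced) "; imbalanced pools" else "",
    if (x$background$mmr_deficient) "; MMR-deficient" else ""))
  invisible(x)
}

#' Read per-isolate mutation calls from a delimited file
#'
#' Expects a tab-separated file with header columns `strain, isolate,
#' position, ref, alt`; `"."` denotes an empty ref (insertion) or alt
#' (deletion). Every row is validated against the locus: out-of-range
#' positions and reference mismatches are hard errors reporting the
#' offending line.
#'
#' @param tsv_path Path to the events file.
#' @param locus A [reporter_locus()].
#' @inheritParams spectrum_dataset
#' @return A [spectrum_dataset()].
#' @export
read_events <- function(tsv_path, locus, n_isolates, overall_rate,
                        strain = NULL, pool_imbalanced = FALSE,
                        mmr_deficient = FALSE) {
  if (!file.exists(tsv_path)) stop2("events file not found: %s", tsv_path)
  tab <- tryCatch(
    utils::read.delim(tsv_path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop2("cannot parse %s: %s", tsv_path, conditionMessage(e)))
  needed <- c("strain", "isolate", "position", "ref", "alt")
  if (!all(needed %in% names(tab))) {
    stop2("%s must have header columns %s", tsv_path, paste(needed, collapse = ", "))
  }
  if (nrow(tab)) {
    pos <- suppressWarnings(as.integer(tab$position))
    bad <- which(is.na(pos))
    if (length(bad)) stop2("%s line %d: unparsable position '%s'",
                           tsv_path, bad[1] + 1L, tab$position[bad[1]])
    tab$position <- pos
  }
  if (is.null(strain)) strain <- if (nrow(tab)) tab$strain[1] else "unknown"
  ds <- tryCatch(
    spectrum_dataset(strain, locus, tab, n_isolates, overall_rate,
                     pool_imbalanced, mmr_deficient),
    error = function(e) stop2("%s: %s", tsv_path, conditionMessage(e)))
  ms_log("read %d events (%d isolates) for strain '%s' from %s",
         nrow(ds$events), ds$n_isolates, ds$strain, tsv_path)
  ds
}

#' Write / read an artifact table
#'
#' All tabular artifacts (events, site rates, hotspots, strand calls,
#' correction factors, runs) are written as delimited text with a header.
#' `read_table()` inverts `write_table()` exactly, so every table
#' round-trips: `read_table(write_table(x, p), p)` equals `x`.
#'
#' @param records A data.frame.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `write_table()`: `path`, invisibly. `read_table()`: a data.frame.
#' @export
write_table <- function(records, path, format = c("tsv", "csv")) {
  if (is.character(format) && length(format) == 1 && !format %in% c("tsv", "csv")) {
    stop2("unsupported table format '%s'", format)
  }
  format <- match.arg(format)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  utils::write.table(records, path, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, format = c("tsv", "csv")) {
  if (is.character(format) && length(format) == 1 && !format %in% c("tsv", "csv")) {
    stop2("unsupported table format '%s'", format)
  }
  format <- match.arg(format)
  utils::read.delim(path, sep = if (format == "tsv") "\t" else ",",
                    stringsAsFactors = FALSE)
}

#' Published per-strain mutation counts and rates
#'
#' Returns the per-strain summary used throughout the worked examples: the
#' overall mutation rate (x1e-7 per locus per generation, with 95% CI), the
#' number of canavanine-resistant mutants sequenced, and the observed event
#' counts by class (base substitutions, single-base indels, other/complex
#' events) for the wild type, the two orientations of the pool-imbalanced
#' mutant, the MMR-deficient single mutant, and the double mutant.
#'
#' @param path Optional path to an alternative summary TSV with the same
#'   columns; defaults to the table shipped with the package.
#' @return A data.frame, one row per strain.
#' @export
strain_summary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "can1_strain_summary.tsv",
                        package = "mutspectra", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("strain", "rate_1e7", "ci_low_1e7", "ci_high_1e7", "n_isolates",
              "base_substitutions", "single_base_indels", "others",
              "total_mutations")
  if (!all(needed %in% names(tab))) {
    stop2("strain summary must have columns %s", paste(needed, collapse = ", "))
  }
  tab
}
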