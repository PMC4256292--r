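#' Reporter locus with replication-fork metadata
#'
#' A reporter gene (e.g. the yeast arginine permease gene used as a forward
#' mutation target) is described by its coding-strand sequence together with
#' two pieces of replication geometry: the orientation of the gene relative
#' to its natural arrangement (`"OR1"` natural, `"OR2"` reversed) and which
#' coding-strand end lies nearest the replication origin in the natural
#' arrangement (`fork_entry`). Together these determine which strand serves
#' as template for leading-strand synthesis (see [template_roles()]).
#'
#' All positions everywhere in the package are 1-based coordinates on the
#' coding strand.
#'
#' @param name Identifier for the locus.
#' @param coding_sequence Coding-strand nucleotide string (A/C/G/T; lower
#'   case accepted and upper-cased).
#' @param orientation `"OR1"` (natural) or `"OR2"` (reversed).
#' @param fork_entry `"5prime"` or `"3prime"`: the coding-strand end nearest
#'   the replication origin in the natural (OR1) arrangement.
#' @return An object of class `ReporterLocus`.
#' @examples
#' reporter_locus("toy", "ATGCCCGTA", "OR1", "5prime")
#' @export
reporter_locus <- function(name, coding_sequence, orientation = c("OR1", "OR2"),
                           fork_entry = c("5prime", "3prime")) {
  orientation <- match.arg(orientation)
  fork_entry <- match.arg(fork_entry)
  seq <- toupper(as.character(coding_sequence))
  if (nchar(seq) == 0L) stop2("coding_sequence must be non-empty")
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!bases %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    stop2("non-ACGT character '%s' at position %d in locus '%s'",
          bases[bad[1]], bad[1], name)
  }
  structure(
    list(name = as.character(name), coding_sequence = seq,
         orientation = orientation, fork_entry = fork_entry),
    class = "ReporterLocus"
  )
}

#' @export
print.ReporterLocus <- function(x, ...) {
  cat(sprintf("ReporterLocus '%s': %d bp, orientation %s, origin at coding %s end\n",
              x$name, nchar(x$coding_sequence), x$orientation,
              sub("prime", "'", x$fork_entry)))
  invisible(x)
}

#' @export
length.ReporterLocus <- function(x) nchar(x$coding_sequence)

locus_base <- function(locus, position) {
  substr(locus$coding_sequence, position, position)
}

#' Read a reporter locus from a single-record FASTA file
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @inheritParams reporter_locus
#' @return A [reporter_locus()] object; the sequence is upper-cased and all
#'   downstream coordinates are 1-based on this coding strand.
#' @export
read_locus <- function(fasta_path, orientation = c("OR1", "OR2"),
                       fork_entry = c("5prime", "3prime")) {
  if (!file.exists(fasta_path)) stop2("FASTA file not found: %s", fasta_path)
  recs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(recs) != 1L) {
    stop2("expected a single-record FASTA, got %d records in %s",
          length(recs), fasta_path)
  }
  locus <- reporter_locus(names(recs)[1], as.character(recs[[1]]),
                          orientation, fork_entry)
  ms_log("read locus '%s' (%d bp) from %s", locus$name, length(locus), fasta_path)
  locus
}

#' Flip the orientation of a locus
#'
#' Returns the same physical locus with the opposite orientation label,
#' modelling a strain in which the reporter has been inverted relative to the
#' replication origin. The coding sequence and coordinates are unchanged:
#' inversion swaps which strand is the leading-strand template, not the
#' coordinate system the mutation calls are reported in.
#'
#' @param locus A `ReporterLocus`.
#' @return A `ReporterLocus` with orientation OR1 <-> OR2.
#' @export
flip_orientation <- function(locus) {
  locus$orientation <- if (locus$orientation == "OR1") "OR2" else "OR1"
  locus
}
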