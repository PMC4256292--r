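# Shared fixtures built in code.

# Small locus with hand-placed features:
#   pos: 123456789012345678901234
#        ATGCCCGTAAAAGCTTTGGGCATC
# runs (min_len 2): CCC 4-6, AAAA 9-12, TT 15-16 (TTT 15-17), GGG 18-20
toy_seq <- "ATGCCCGTAAAAGCTTTGGGCATC"

toy_locus <- function(orientation = "OR1") {
  reporter_locus("toy", toy_seq, orientation, "5prime")
}

# Fabricate a dataset with the given number of events per class, all placed
# at fixed valid positions of the toy locus.
counts_dataset <- function(n_sub = 0, n_indel = 0, n_complex = 0,
                           n_isolates, overall_rate, strain = "s",
                           locus = toy_locus(), mmr_deficient = FALSE,
                           pool_imbalanced = FALSE) {
  rows <- list()
  if (n_sub > 0) {
    rows$sub <- data.frame(position = 4L, ref = "C", alt = "A")[rep(1, n_sub), ]
  }
  if (n_indel > 0) {
    rows$ind <- data.frame(position = 9L, ref = "A", alt = "")[rep(1, n_indel), ]
  }
  if (n_complex > 0) {
    rows$cpx <- data.frame(position = 1L, ref = "AT", alt = "")[rep(1, n_complex), ]
  }
  ev <- do.call(rbind, rows)
  n <- if (is.null(ev)) 0 else nrow(ev)
  iso <- sprintf("i%03d", ((seq_len(n) - 1L) %% n_isolates) + 1L)
  ev <- data.frame(strain = rep(strain, n), isolate = iso,
                   ev, stringsAsFactors = FALSE)
  spectrum_dataset(strain, locus, ev, n_isolates, overall_rate,
                   pool_imbalanced = pool_imbalanced,
                   mmr_deficient = mmr_deficient)
}

events_df <- function(position, ref, alt, strain = "s",
                      isolate = sprintf("i%03d", seq_along(position))) {
  data.frame(strain = rep(strain, length(position)), isolate = isolate,
             position = position, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# Independent brute-force scanner for homopolymer runs.
naive_runs <- function(sequence, min_len = 2) {
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- data.frame(start = integer(0), end = integer(0),
                    length = integer(0), base = character(0),
                    stringsAsFactors = FALSE)
  i <- 1
  while (i <= length(b)) {
    j <- i
    while (j < length(b) && b[j + 1] == b[i]) j <- j + 1
    if (j - i + 1 >= min_len) {
      out <- rbind(out, data.frame(start = i, end = j, length = j - i + 1,
                                   base = b[i], stringsAsFactors = FALSE))
    }
    i <- j + 1
  }
  out
}

# Independent oracle for substitution strand assignment: enumerate every
# (template strand, misinserted base in E) mismatch, resolve it through a
# second replication round to a coding-strand change, and see which template
# strands can produce the observed change.
oracle_templates <- function(ref, alt, E) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- character(0)
  for (b in E) {
    # coding strand as template: nascent (noncoding) strand carries b,
    # which templates comp(b) on the coding strand next round
    if (unname(comp[b]) == alt && b != unname(comp[ref])) hits <- c(hits, "coding")
    # noncoding as template: nascent coding strand carries b directly
    if (b == alt && b != ref) hits <- c(hits, "noncoding")
  }
  unique(hits)
}
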