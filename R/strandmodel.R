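#' Which physical strand templates leading vs lagging synthesis
#'
#' The replication fork enters the locus from the origin side and moves
#' through the gene; the leading-strand polymerase copies the template it
#' reads 3' to 5' in the direction of fork movement. If the fork enters at
#' the coding strand's 5' end, the strand presenting its 3' end to the
#' incoming fork is the non-coding strand, which therefore templates leading
#' strand synthesis while the coding strand templates lagging-strand
#' synthesis; entering at the 3' end swaps the roles. Reversing the gene
#' (OR2) relative to a fixed origin flips the effective entry end, so the
#' roles derive from `fork_entry` and `orientation` jointly rather than from
#' a lookup table.
#'
#' For the natural arrangement of the reporter used here (origin on the
#' coding 5' side, OR1) the coding strand is the lagging-strand template;
#' in OR2 it is the leading-strand template.
#'
#' @param locus A [reporter_locus()].
#' @return Named list mapping `coding` and `noncoding` to
#'   `"leading_template"` / `"lagging_template"`.
#' @examples
#' or1 <- reporter_locus("toy", "ACGT", "OR1", "5prime")
#' template_roles(or1)$coding            # "lagging_template"
#' template_roles(flip_orientation(or1))$coding  # "leading_template"
#' @export
template_roles <- function(locus) {
  stopifnot(inherits(locus, "ReporterLocus"))
  entry <- locus$fork_entry
  if (locus$orientation == "OR2") {
    entry <- if (entry == "5prime") "3prime" else "5prime"
  }
  if (entry == "5prime") {
    list(coding = "lagging_template", noncoding = "leading_template")
  } else {
    list(coding = "leading_template", noncoding = "lagging_template")
  }
}

.role_of <- function(locus, template_strand) {
  sub("_template$", "", template_roles(locus)[[template_strand]])
}

#' Candidate misinsertion events explaining a substitution
#'
#' A coding-strand substitution X to Y can arise on either template strand:
#' with the coding strand as template the polymerase misinserted the
#' complement of Y opposite template X; with the non-coding strand as
#' template it misinserted Y itself opposite the complement of X (the
#' mismatch is fixed as a full substitution in the next replication round).
#'
#' @param ref,alt Single bases, the coding-strand substitution X to Y.
#' @return data.frame with two rows: `template_strand`, `template_base`,
#'   `misinserted` (the base of the misinserted dNTP).
#' @examples
#' substitution_candidates("C", "A")
#' # coding template: misinserted T opposite C; noncoding: A opposite G
#' @export
substitution_candidates <- function(ref, alt) {
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt ||
      !all(c(ref, alt) %in% c("A", "C", "G", "T"))) {
    stop2("substitution_candidates() needs a single-base substitution")
  }
  data.frame(
    template_strand = c("coding", "noncoding"),
    template_base = c(ref, comp_base(ref)),
    misinserted = c(comp_base(alt), alt),
    stringsAsFactors = FALSE
  )
}

.strand_call <- function(call, template_strand = NA_character_,
                         implicated = NA_character_, rationale = "") {
  list(call = call, template_strand = template_strand,
       implicated_dNTP = implicated, rationale = rationale)
}

#' Assign a substitution to leading or lagging strand synthesis
#'
#' Of the two candidate misinsertions ([substitution_candidates()]), keep
#' those whose misinserted dNTP is in the excess set of the pool imbalance;
#' a unique survivor identifies the template strand the error was made on,
#' and [template_roles()] converts that to a leading or lagging call. Zero
#' or two survivors give `"unassigned"` — a first-class result, not an
#' error.
#'
#' With a strictly pyrimidine excess set every substitution is uniquely
#' assignable, because complementation maps pyrimidines to purines so
#' exactly one candidate's misinserted dNTP is a pyrimidine.
#'
#' @param ref,alt The substitution, coding-strand bases.
#' @param locus A [reporter_locus()] (supplies orientation/fork geometry).
#' @param pools A [dntp_pools()].
#' @return List with `call` (`"leading"`, `"lagging"`, `"unassigned"`),
#'   `template_strand`, `implicated_dNTP` (the misinserted base), and a
#'   human-readable `rationale`.
#' @examples
#' or1 <- reporter_locus("toy", strrep("ACGT", 200), "OR1", "5prime")
#' assign_substitution("C", "A", or1, dntp_pools())$call  # "lagging"
#' @export
assign_substitution <- function(ref, alt, locus, pools) {
  cand <- substitution_candidates(ref, alt)
  E <- excess_set(pools)
  keep <- cand[cand$misinserted %in% E, , drop = FALSE]
  if (nrow(keep) != 1L) {
    why <- if (nrow(keep) == 0L) "no candidate misinserted dNTP in excess set"
           else "both candidate misinserted dNTPs in excess set"
    return(.strand_call("unassigned", rationale = why))
  }
  role <- .role_of(locus, keep$template_strand)
  .strand_call(role, keep$template_strand, keep$misinserted,
               sprintf("d%sTP (excess) misinserted opposite template %s on the %s strand (%s-strand template in %s)",
                       keep$misinserted, keep$template_base,
                       keep$template_strand, keep$template_strand,
                       locus$orientation))
}

#' Assign a homopolymer-run indel to a strand by the next-nucleotide rule
#'
#' A slippage intermediate in a homopolymer run is fixed when the polymerase
#' rapidly incorporates the next nucleotide past the run, sealing the
#' unpaired base in place. For each template strand the "next" template base
#' is the one the polymerase reaches after copying the run — the base on the
#' run's 5' flank of that template strand — and the stabilising dNTP is its
#' complement. Strands whose stabilising dNTP is in the excess set qualify;
#' a unique qualifier gives the call, zero or two give `"unassigned"`.
#'
#' For a run spanning coding positions `start..end`: with the coding strand
#' as template the next template base is `coding[start - 1]`; with the
#' non-coding strand as template it is the complement of `coding[end + 1]`.
#'
#' @param position 1-based coding position of the indel (must lie in a run).
#' @param ref,alt The single-base indel (`""` on the empty side).
#' @param locus A [reporter_locus()].
#' @param pools A [dntp_pools()].
#' @param runs Run annotation from [annotate_runs()]; recomputed if `NULL`.
#' @return A strand-call list as in [assign_substitution()], with the
#'   implicated dNTP being the next incorporated (stabilising) nucleotide.
#' @export
assign_run_indel <- function(position, ref, alt, locus, pools, runs = NULL) {
  cls <- classify_event(ref, alt)
  if (cls$klass != "single_base_indel") {
    stop2("assign_run_indel() needs a single-base indel")
  }
  if (is.null(runs)) runs <- annotate_runs(locus$coding_sequence, min_len = 2)
  base <- if (nchar(ref)) toupper(ref) else toupper(alt)
  hit <- runs[runs$base == base & runs$start <= position & runs$end >= position,
              , drop = FALSE]
  if (!nrow(hit)) {
    return(.strand_call("unassigned", rationale = "no run context"))
  }
  E <- excess_set(pools)
  s <- hit$start[1]; e <- hit$end[1]
  next_dntp <- c(coding = NA_character_, noncoding = NA_character_)
  if (s > 1L) next_dntp["coding"] <- comp_base(locus_base(locus, s - 1L))
  if (e < length(locus)) next_dntp["noncoding"] <- locus_base(locus, e + 1L)
  qual <- names(next_dntp)[!is.na(next_dntp) & next_dntp %in% E]
  if (length(qual) != 1L) {
    why <- if (length(qual) == 0L) "no flanking next-nucleotide dNTP in excess set"
           else "both strands' next-nucleotide dNTPs in excess set"
    return(.strand_call("unassigned", rationale = why))
  }
  role <- .role_of(locus, qual)
  .strand_call(role, qual, next_dntp[[qual]],
               sprintf("run %d-%d (%s): next incorporated d%sTP (excess) stabilises slippage on the %s-strand template",
                       s, e, base, next_dntp[[qual]], qual))
}

#' Strand-assign every event in a dataset
#'
#' Applies [assign_substitution()] to substitutions and
#' [assign_run_indel()] to single-base indels; complex events are always
#' unassigned.
#'
#' @param dataset A [spectrum_dataset()].
#' @param pools A [dntp_pools()].
#' @return data.frame with one row per event: the event columns plus
#'   `call`, `template_strand`, `implicated_dNTP`, `rationale`.
#' @export
assign_strand <- function(dataset, pools) {
  stopifnot(inherits(dataset, "SpectrumDataset"))
  ev <- dataset$events
  runs <- annotate_runs(dataset$locus$coding_sequence, min_len = 2)
  calls <- lapply(seq_len(nrow(ev)), function(i) {
    switch(ev$klass[i],
      substitution = assign_substitution(ev$ref[i], ev$alt[i], dataset$locus, pools),
      single_base_indel = assign_run_indel(ev$position[i], ev$ref[i], ev$alt[i],
                                           dataset$locus, pools, runs),
      .strand_call("unassigned", rationale = "complex event"))
  })
  out <- cbind(ev, do.call(rbind, lapply(calls, function(x) {
    data.frame(call = x$call, template_strand = x$template_strand,
               implicated_dNTP = x$implicated_dNTP, rationale = x$rationale,
               stringsAsFactors = FALSE)
  })))
  ms_log("strand calls for '%s': %d leading, %d lagging, %d unassigned",
         dataset$strain, sum(out$call == "leading"), sum(out$call == "lagging"),
         sum(out$call == "unassigned"))
  out
}

#' Summarise strand calls per strain
#'
#' @param calls Output of [assign_strand()].
#' @return One-row data.frame with counts of leading, lagging and unassigned
#'   events.
#' @export
strand_summary <- function(calls) {
  data.frame(leading = sum(calls$call == "leading"),
             lagging = sum(calls$call == "lagging"),
             unassigned = sum(calls$call == "unassigned"))
}

#' Exhaustive strand-assignment audit over all substitution types
#'
#' Enumerates the 12 ordered base substitutions and records which template
#' strand (if any) each is attributed to under the given pools. With a
#' strictly pyrimidine (or strictly purine) excess set every type maps to
#' exactly one template strand; with an empty or full excess set none do.
#'
#' @param pools A [dntp_pools()].
#' @return data.frame with columns `ref, alt, template_strand, misinserted,
#'   assigned`.
#' @export
assignment_table <- function(pools) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  E <- excess_set(pools)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cand <- substitution_candidates(grid$ref[i], grid$alt[i])
    keep <- cand[cand$misinserted %in% E, , drop = FALSE]
    if (nrow(keep) == 1L) {
      data.frame(ref = grid$ref[i], alt = grid$alt[i],
                 template_strand = keep$template_strand,
                 misinserted = keep$misinserted, assigned = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(ref = grid$ref[i], alt = grid$alt[i],
                 template_strand = NA_character_, misinserted = NA_character_,
                 assigned = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$ref, out$alt), ]
}
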