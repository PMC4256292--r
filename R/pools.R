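#' dNTP pool table
#'
#' Holds the fold-change of each dNTP concentration over wild type, plus the
#' threshold above which a nucleotide counts as "in excess". The default
#' pools describe the ribonucleotide-reductase allosteric mutant used
#' throughout: dCTP about 26-fold and dTTP about 14-fold over wild type,
#' dATP roughly doubled, dGTP unchanged. With the default threshold of 5 the
#' derived excess set is the pyrimidines \{dCTP, dTTP\}: it captures the two
#' strongly elevated nucleotides and excludes the mildly elevated dATP.
#'
#' @param dATP,dCTP,dGTP,dTTP Positive fold-over-wild-type concentrations.
#' @param excess_threshold Positive fold-change at or above which a dNTP is
#'   a member of the excess set.
#' @return An object of class `DNTPPools`.
#' @examples
#' pools <- dntp_pools()          # the imbalanced-pool mutant
#' excess_set(pools)              # "C" "T"
#' excess_set(dntp_pools(1, 1, 1, 1))  # character(0): balanced pools
#' @export
dntp_pools <- function(dATP = 2, dCTP = 26, dGTP = 1, dTTP = 14,
                       excess_threshold = 5) {
  fold <- c(A = dATP, C = dCTP, G = dGTP, T = dTTP)
  if (any(!is.finite(fold)) || any(fold <= 0)) stop2("fold changes must be positive")
  if (!is.finite(excess_threshold) || excess_threshold <= 0) {
    stop2("excess_threshold must be positive")
  }
  structure(list(fold_over_wt = fold, excess_threshold = excess_threshold),
            class = "DNTPPools")
}

#' @rdname dntp_pools
#' @param pools A `DNTPPools` object.
#' @return `excess_set()`: the bases (as `"A"`,`"C"`,`"G"`,`"T"`, meaning the
#'   corresponding dNTP) whose fold-change is at or above the threshold.
#' @export
excess_set <- function(pools) {
  stopifnot(inherits(pools, "DNTPPools"))
  names(pools$fold_over_wt)[pools$fold_over_wt >= pools$excess_threshold]
}

#' @export
print.DNTPPools <- function(x, ...) {
  cat("dNTP pools (fold over wt): ",
      paste(sprintf("d%sTP=%g", names(x$fold_over_wt), x$fold_over_wt),
            collapse = ", "),
      "\nexcess set (>= ", x$excess_threshold, "x): ",
      if (length(excess_set(x))) paste0("d", excess_set(x), "TP", collapse = ", ")
      else "(empty)", "\n", sep = "")
  invisible(x)
}
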