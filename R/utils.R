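#' @keywords internal
"_PACKAGE"

# Watson-Crick complement, coding-strand alphabet only.
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

comp_base <- function(x) {
  stopifnot(all(is.na(x) | x %in% names(.COMPLEMENT)))
  out <- unname(.COMPLEMENT[x])
  out[is.na(x)] <- NA_character_
  out
}

comp_seq <- function(s) {
  paste(comp_base(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

is_purine <- function(x) x %in% c("A", "G")

#' Toggle progress/diagnostic messages
#'
#' All stages log input counts, filter decisions and derived thresholds via
#' [message()] when `options(mutspectra.verbose = TRUE)` is set (default off).
#'
#' @param ... passed to [sprintf()].
#' @return Invisibly, the formatted message (emitted only when verbose).
#' @keywords internal
ms_log <- function(...) {
  msg <- sprintf(...)
  if (isTRUE(getOption("mutspectra.verbose", FALSE))) message("[mutspectra] ", msg)
  invisible(msg)
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
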