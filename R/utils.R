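## Shared helpers: logging, superfamily nomenclature, small numeric utilities.

#' @keywords internal
rs_log <- function(...) {
  if (isTRUE(getOption("repeatscape.verbose", TRUE))) {
    message("[repeatscape] ", sprintf(...))
  }
  invisible(NULL)
}

## Three-letter superfamily codes (Wicker nomenclature) accepted in family
## names, and the field names used for grouping.
.SUPERFAMILY_CODES <- c(
  RLC = "Copia", RLG = "Gypsy", RLX = "LTR_unknown",
  RIX = "LINE", RSX = "SINE",
  DTC = "CACTA", DTT = "Mariner", DTH = "Harbinger", DHH = "Helitron",
  XXX = "unknown"
)

#' Superfamily name from a family name prefix
#'
#' Family names carry a three-letter superfamily code prefix (e.g.
#' `RLG_Sabrina` is a Gypsy LTR retrotransposon). Unknown prefixes error.
#'
#' @param family character vector of family names.
#' @return character vector of superfamily names.
#' @export
superfamily_of <- function(family) {
  code <- toupper(substr(family, 1L, 3L))
  bad <- !code %in% names(.SUPERFAMILY_CODES)
  if (any(bad)) {
    stop("invalid three-letter superfamily code in family name(s): ",
         paste(unique(family[bad]), collapse = ", "))
  }
  unname(.SUPERFAMILY_CODES[code])
}

#' @keywords internal
te_class_of <- function(family) {
  code <- toupper(substr(family, 1L, 1L))
  ifelse(code == "R", 1L, ifelse(code == "D", 2L, NA_integer_))
}

## round half away from zero (base round() is banker's rounding)
#' @keywords internal
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' @keywords internal
interval_midpoint <- function(start, end) floor((start + end) / 2)

## overlap width of interval pairs, 0 if disjoint (1-based closed)
#' @keywords internal
overlap_width <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## complement lookup used by the simulators (N-safe)
#' @keywords internal
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @keywords internal
assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %s", name, min))
  }
  invisible(TRUE)
}
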