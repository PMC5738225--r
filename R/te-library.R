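## Reference TE library container: consensus sequences plus per-family
## metadata keyed by the three-letter superfamily code in the name.

#' Construct a TE reference library
#'
#' @param seqs named character vector or DNAStringSet of consensus sequences;
#'   names must carry a valid three-letter superfamily code prefix (RLC, RLG,
#'   RLX, RIX, RSX, DTC, DTT, DTH, DHH, XXX).
#' @param autonomous optional logical vector (per family) flagging families
#'   whose consensus encodes intact transposition machinery.
#' @return object of class `te_library`: list with `entries` (data.table:
#'   family, superfamily, class, length, autonomous) and `seq` (DNAStringSet).
#' @export
te_library <- function(seqs, autonomous = NA) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || is.null(names(seqs))) {
    stop("'seqs' must be a named character vector or DNAStringSet")
  }
  if (anyDuplicated(names(seqs))) stop("duplicated family names")
  seqs <- toupper(seqs)
  fam <- names(seqs)
  entries <- data.table::data.table(
    family = fam,
    superfamily = superfamily_of(fam),   # validates the prefix
    class = te_class_of(fam),
    length = nchar(seqs),
    autonomous = rep_len(autonomous, length(fam))
  )
  structure(list(entries = entries, seq = Biostrings::DNAStringSet(seqs)),
            class = "te_library")
}

#' @export
print.te_library <- function(x, ...) {
  cat(sprintf("te_library: %d family(ies), lengths %d..%d bp\n",
              nrow(x$entries), min(x$entries$length), max(x$entries$length)))
  invisible(x)
}

#' Read a TE library from FASTA
#'
#' @param path FASTA file of consensus sequences with coded names.
#' @export
read_te_library <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  names(set) <- sub("\\s.*$", "", names(set))
  te_library(set)
}

#' Write a TE library to FASTA
#'
#' @param library a `te_library`.
#' @param path output path.
#' @export
write_te_library <- function(library, path) {
  Biostrings::writeXStringSet(library$seq, path)
  invisible(path)
}

#' @keywords internal
library_lengths <- function(library) {
  setNames(library$entries$length, library$entries$family)
}
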