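## Genome assembly container and FASTA I/O (sequence parsing bought from
## Biostrings; this file adds canonicalisation, N-gap bookkeeping and
## line-level diagnostics on malformed input).

#' Construct a genome assembly object
#'
#' Canonicalises sequences to uppercase A/C/G/T/N (other ambiguity codes are
#' mapped to N with a warning) and records assembly gaps, i.e. maximal runs
#' of N, as 1-based closed intervals.
#'
#' @param seqs a named character vector or [Biostrings::DNAStringSet].
#' @return an object of class `genome_assembly`: list with elements `seq`
#'   (DNAStringSet), `lengths` (named integer) and `gaps` (data.table with
#'   columns chrom/start/end).
#' @export
genome_assembly <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs) || is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("'seqs' must be a named character vector or DNAStringSet")
  }
  if (anyDuplicated(names(seqs))) stop("duplicated chromosome names")
  seqs <- toupper(seqs)
  n_other <- sum(vapply(seqs, function(s)
    nchar(gsub("[ACGTN]", "", s)), numeric(1)))
  if (n_other > 0) {
    warning(sprintf("%d non-ACGTN characters mapped to N", n_other))
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  gaps <- data.table::rbindlist(lapply(names(seqs), function(ch) {
    m <- gregexpr("N+", seqs[[ch]], perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.table::data.table(chrom = ch, start = as.integer(m),
                           end = as.integer(m) + attr(m, "match.length") - 1L)
  }))
  if (nrow(gaps) == 0L) {
    gaps <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer())
  }
  structure(list(
    seq = Biostrings::DNAStringSet(seqs),
    lengths = setNames(nchar(seqs), names(seqs)),
    gaps = gaps
  ), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d chromosome(s), %.3f Mb, %d assembly gap(s)\n",
              length(x$lengths), sum(x$lengths) / 1e6, nrow(x$gaps)))
  invisible(x)
}

#' @keywords internal
.diagnose_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("no records in FASTA file '", path, "'")
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("FASTA parse error at line %d of '%s': expected '>' header",
                 nonblank[1], path))
  }
  for (i in nonblank) {
    l <- trimws(lines[i])
    if (startsWith(l, ">")) next
    if (grepl("[^A-Za-z]", l)) {
      stop(sprintf("FASTA parse error at line %d of '%s': invalid sequence characters",
                   i, path))
    }
  }
  invisible(TRUE)
}

#' Read a genome assembly from FASTA
#'
#' @param path path to a FASTA file.
#' @return a [genome_assembly()] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("no records in FASTA file '", path, "'")
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    .diagnose_fasta(path)
                    stop("FASTA parse error in '", path, "': ",
                         conditionMessage(e))
                  })
  if (length(set) == 0L) stop("no records in FASTA file '", path, "'")
  ## keep first whitespace-delimited token of the header as the name
  names(set) <- sub("\\s.*$", "", names(set))
  asm <- genome_assembly(set)
  rs_log("read_fasta: %d record(s) from %s", length(set), path)
  asm
}

#' Write a genome assembly (or named sequences) to FASTA
#'
#' @param assembly a `genome_assembly`, DNAStringSet or named character vector.
#' @param path output path.
#' @param width line width.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  seqs <- if (inherits(assembly, "genome_assembly")) assembly$seq
          else if (inherits(assembly, "DNAStringSet")) assembly
          else Biostrings::DNAStringSet(assembly)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}
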