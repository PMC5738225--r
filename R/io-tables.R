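## Tab-separated I/O: per-cytosine methylation calls, BED intervals, and the
## flat key=value config format used by the CLI.
##
## Methylation dialect (documented in the README): TSV with header columns
##   chrom  pos  strand  context  meth  total
## where pos is 1-based, context is CG/CHG/CHH, meth is the methylated read
## count (#C) and total the total read count (#C + #T). Rows with total = 0
## are retained; downstream windowing treats them as uncovered sites.

#' Read per-cytosine methylation calls
#'
#' @param path TSV file (with or without the canonical header line).
#' @return data.table with columns chrom, pos, strand, context, meth, total
#'   and a derived unmeth = total - meth.
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cols <- c("chrom", "pos", "strand", "context", "meth", "total")
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("^chrom\t", first)
  if (length(first) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  meth = integer(), total = integer(),
                                  unmeth = integer()))
  }
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          col.names = cols)
  bad_ctx <- !dt$context %in% c("CG", "CHG", "CHH")
  if (any(bad_ctx)) {
    stop("unknown methylation context at row ", which(bad_ctx)[1], ": '",
         dt$context[which(bad_ctx)[1]], "'")
  }
  if (any(dt$meth < 0L | dt$total < 0L)) {
    stop("negative count at row ", which(dt$meth < 0L | dt$total < 0L)[1])
  }
  if (any(dt$meth > dt$total)) {
    stop("methylated count exceeds total at row ",
         which(dt$meth > dt$total)[1])
  }
  dt[, unmeth := total - meth]
  rs_log("read_methylation_table: %d call(s) from %s", nrow(dt), path)
  dt[]
}

#' Write per-cytosine methylation calls
#'
#' @param calls methylation call table.
#' @param path output path.
#' @export
write_methylation_table <- function(calls, path) {
  data.table::fwrite(
    data.table::as.data.table(calls)[, .(chrom, pos, strand, context, meth, total)],
    path, sep = "\t")
  invisible(path)
}

#' Convert a methratio-style extractor file to the package dialect
#'
#' Converter stub for the common bisulfite "methratio" output shape
#' (chr, pos, strand, context, ratio, eff_CT, C_count, CT_count, ...): keeps
#' chr/pos/strand, maps the context string to CG/CHG/CHH by its first
#' characters, and takes meth = C_count, total = CT_count.
#'
#' @param path_in methratio-style file (with header).
#' @param path_out output path in the package dialect.
#' @export
convert_methratio <- function(path_in, path_out) {
  dt <- data.table::fread(path_in)
  if (ncol(dt) < 8L) stop("methratio-style input needs >= 8 columns")
  data.table::setnames(dt, 1:8, c("chrom", "pos", "strand", "context",
                                  "ratio", "eff_ct", "c_count", "ct_count"))
  ctx <- toupper(dt$context)
  ctx <- ifelse(grepl("^CG", ctx), "CG",
                ifelse(grepl("^C[ACT]G", ctx), "CHG", "CHH"))
  out <- data.table::data.table(chrom = dt$chrom, pos = as.integer(dt$pos),
                                strand = dt$strand, context = ctx,
                                meth = as.integer(dt$c_count),
                                total = as.integer(dt$ct_count))
  write_methylation_table(out, path_out)
}

#' Read a BED file (0-based half-open on disk) into 1-based closed intervals
#'
#' @param path BED3+ file.
#' @return data.table chrom/start/end plus name/score/strand when present.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)), nm[seq_len(min(ncol(dt), 6L))])
  dt[, start := as.integer(start) + 1L]
  dt[, end := as.integer(end)]
  dt[]
}

#' Write 1-based closed intervals as BED (0-based half-open)
#'
#' @param dt data.table with chrom/start/end and optional name/score/strand.
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  dt <- data.table::as.data.table(dt)
  out <- data.table::data.table(chrom = dt$chrom, start = dt$start - 1L,
                                end = dt$end)
  for (col in c("name", "score", "strand")) {
    if (col %in% names(dt)) out[, (col) := dt[[col]]] else break
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are coerced
#' to logical/numeric where possible, and comma-separated values become
#' vectors. `name:value` pairs inside a comma list become named vectors.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    if (!grepl("=", l, fixed = TRUE)) stop("config parse error: '", l, "'")
    key <- trimws(sub("=.*$", "", l))
    val <- trimws(sub("^[^=]*=", "", l))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nms <- NULL
    if (all(grepl(":", parts, fixed = TRUE))) {
      nms <- trimws(sub(":.*$", "", parts))
      parts <- trimws(sub("^[^:]*:", "", parts))
    }
    suppressWarnings(num <- as.numeric(parts))
    v <- if (!anyNA(num)) num
         else if (all(parts %in% c("TRUE", "FALSE", "true", "false"))) {
           toupper(parts) == "TRUE"
         } else parts
    if (!is.null(nms)) names(v) <- nms
    out[[key]] <- v
  }
  out
}

#' Write a flat key=value configuration file
#'
#' @param config named list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  fmt1 <- function(v) {
    s <- as.character(v)
    if (!is.null(names(v))) s <- paste0(names(v), ":", s)
    paste(s, collapse = ",")
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt1, character(1))), path)
  invisible(path)
}
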