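## GFF3 readers/writers for gene models and TE annotations. GFF3 is 1-based
## inclusive on disk, which is also the package's in-memory convention, so no
## coordinate shifting happens here. Parsing is deliberately strict: a record
## with end < start is a parse error, a record without strand is dropped with
## a warning (counts are logged for filter audits).

#' @keywords internal
.parse_gff3_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]*)"), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' @keywords internal
.read_gff3_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      col.names = c("chrom", "source", "type", "start", "end",
                                    "score", "strand", "phase", "attributes"),
                      colClasses = list(character = c(1:3, 6:9)),
                      skip = "\t", blank.lines.skip = TRUE),
    error = function(e) stop("GFF3 parse error in '", path, "': ",
                             conditionMessage(e)))
  dt <- dt[!startsWith(chrom, "#")]
  if (nrow(dt) && (anyNA(dt$start) || anyNA(dt$end))) {
    stop("GFF3 parse error in '", path, "': non-numeric coordinates")
  }
  if (nrow(dt) && any(dt$end < dt$start)) {
    stop("GFF3 parse error in '", path, "': end < start at record ",
         which(dt$end < dt$start)[1])
  }
  dt
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features. Records without a strand are rejected with a
#' warning; `end < start` is a parse error. TSS is the start coordinate on
#' `+` genes and the end coordinate on `-` genes; TES is the opposite
#' terminus.
#'
#' @param path GFF3 file.
#' @param feature feature type(s) to keep (default "gene").
#' @return data.table with columns gene_id, chrom, start, end, strand,
#'   confidence, tss, tes.
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  dt <- .read_gff3_table(path)
  dt <- dt[type %in% feature]
  n_in <- nrow(dt)
  bad <- !dt$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sprintf("dropping %d gene record(s) without strand", sum(bad)))
    dt <- dt[!bad]
  }
  id <- .parse_gff3_attr(dt$attributes, "ID")
  id[is.na(id)] <- sprintf("gene%06d", which(is.na(id)))
  genes <- data.table::data.table(
    gene_id = id, chrom = dt$chrom,
    start = as.integer(dt$start), end = as.integer(dt$end),
    strand = dt$strand,
    confidence = .parse_gff3_attr(dt$attributes, "confidence")
  )
  genes <- add_tss_tes(genes)
  rs_log("read_gff3_genes: %d in, %d kept from %s", n_in, nrow(genes), path)
  genes[]
}

#' Add TSS/TES columns derived from strand
#'
#' @param genes data.table with start/end/strand.
#' @return the same table with `tss` and `tes` columns.
#' @export
add_tss_tes <- function(genes) {
  genes <- data.table::as.data.table(genes)
  genes[, tss := ifelse(strand == "+", start, end)]
  genes[, tes := ifelse(strand == "+", end, start)]
  genes[]
}

#' Write gene models to GFF3
#'
#' @param genes gene table (see [read_gff3_genes()]).
#' @param path output path.
#' @export
write_gff3_genes <- function(genes, path) {
  attrs <- sprintf("ID=%s%s", genes$gene_id,
                   ifelse(is.na(genes$confidence), "",
                          paste0(";confidence=", genes$confidence)))
  lines <- sprintf("%s\trepeatscape\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$chrom, genes$start, genes$end, genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write TE annotations to GFF3
#'
#' Family, superfamily, alignment identity and end-intactness flags are
#' stored as attributes and survive a read/write round trip.
#'
#' @param annotations TE annotation table (chrom/start/end/family/
#'   superfamily/strand/identity and optional intactness flags).
#' @param path output path.
#' @export
write_gff3_te <- function(annotations, path) {
  a <- data.table::as.data.table(annotations)
  if (!"five_prime_intact" %in% names(a)) a[, five_prime_intact := NA]
  if (!"three_prime_intact" %in% names(a)) a[, three_prime_intact := NA]
  if (!"identity" %in% names(a)) a[, identity := NA_real_]
  attrs <- sprintf(
    "ID=te%06d;family=%s;superfamily=%s;identity=%s;five_prime_intact=%s;three_prime_intact=%s",
    seq_len(nrow(a)), a$family, a$superfamily,
    ifelse(is.na(a$identity), ".", sprintf("%.1f", a$identity)),
    ifelse(is.na(a$five_prime_intact), ".", a$five_prime_intact),
    ifelse(is.na(a$three_prime_intact), ".", a$three_prime_intact))
  lines <- sprintf("%s\trepeatscape\trepeat_region\t%d\t%d\t.\t%s\t.\t%s",
                   a$chrom, a$start, a$end, a$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read TE annotations from GFF3
#'
#' @param path GFF3 file written by [write_gff3_te()] (or compatible).
#' @return TE annotation data.table.
#' @export
read_gff3_te <- function(path) {
  dt <- .read_gff3_table(path)
  dt <- dt[type %in% c("repeat_region", "transposable_element", "match")]
  fam <- .parse_gff3_attr(dt$attributes, "family")
  id5 <- .parse_gff3_attr(dt$attributes, "five_prime_intact")
  id3 <- .parse_gff3_attr(dt$attributes, "three_prime_intact")
  ident <- .parse_gff3_attr(dt$attributes, "identity")
  out <- data.table::data.table(
    chrom = dt$chrom, start = as.integer(dt$start), end = as.integer(dt$end),
    family = fam,
    superfamily = .parse_gff3_attr(dt$attributes, "superfamily"),
    strand = dt$strand,
    identity = suppressWarnings(as.numeric(ident)),
    five_prime_intact = ifelse(id5 %in% c("TRUE", "FALSE"),
                               as.logical(id5), NA),
    three_prime_intact = ifelse(id3 %in% c("TRUE", "FALSE"),
                                as.logical(id3), NA)
  )
  out[, complete := five_prime_intact & three_prime_intact]
  rs_log("read_gff3_te: %d record(s) from %s", nrow(out), path)
  out[]
}
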