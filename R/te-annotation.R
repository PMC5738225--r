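## Segment-based homology annotation of TEs.
##
## The genome is tiled into short segments (default 180 bp) which are searched
## against the reference library; segment-level local alignments ("hits") are
## then combined into TE annotations by three rules:
##   1. overlapping/adjacent hits of the same family and orientation are
##      unioned;
##   2. gaps of fewer than `bridge_gap` (default 100) intervening bases
##      between same-family same-orientation hits are bridged, unless a hit
##      of another family (or the opposite orientation) lies in the gap;
##   3. an annotation within `gap_extend` (default 80) bases of an assembly
##      N-gap is extended to the gap edge.
## Gap sizes count intervening bases (with 1-based closed intervals:
## next.start - prev.end - 1); "less than" is strict, so a 99-base gap is
## bridged and a 100-base gap is not.

#' Tile a genome into consecutive non-overlapping segments
#'
#' @param assembly a [genome_assembly()].
#' @param segment_length segment size in bp (>= 20); the final partial
#'   segment of each chromosome is retained.
#' @return data.table with chrom, seg_index, start, end.
#' @export
segment_genome <- function(assembly, segment_length = 180L) {
  if (segment_length < 20L) stop("'segment_length' must be >= 20")
  segs <- data.table::rbindlist(lapply(names(assembly$lengths), function(ch) {
    L <- assembly$lengths[[ch]]
    if (L < 1L) return(NULL)
    starts <- seq.int(1L, L, by = segment_length)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + segment_length - 1L, L))
  }))
  if (nrow(segs) == 0L) {
    return(data.table::data.table(chrom = character(), seg_index = integer(),
                                  start = integer(), end = integer()))
  }
  segs[, seg_index := .I]
  data.table::setcolorder(segs, c("chrom", "seg_index", "start", "end"))
  segs[]
}

#' Search genome segments against a TE library
#'
#' Default backend is the built-in seed-and-extend local aligner (compiled);
#' every reported hit satisfies the identity and length thresholds and
#' carries its strand and its interval on the (forward) consensus.
#'
#' @param assembly a [genome_assembly()].
#' @param library a [te_library()].
#' @param segments optional precomputed [segment_genome()] table.
#' @param min_identity minimum percent identity (default 80).
#' @param min_hit_length minimum alignment length in bp (default 50).
#' @param segment_length used when `segments` is NULL.
#' @param k seed k-mer size of the built-in aligner.
#' @param xdrop x-drop termination threshold of the ungapped extension.
#' @return data.table of segment hits: chrom, start, end (genome), family,
#'   superfamily, strand, identity, length, cons_start, cons_end, seg_index.
#' @export
search_segments <- function(assembly, library, segments = NULL,
                            min_identity = 80, min_hit_length = 50L,
                            segment_length = 180L, k = 11L, xdrop = 15L) {
  if (nrow(library$entries) == 0L) stop("empty TE library")
  if (is.null(segments)) segments <- segment_genome(assembly, segment_length)
  if (nrow(segments) == 0L) return(.empty_hits())
  segments <- segments[order(match(chrom, names(assembly$lengths)), start)]
  seg_seqs <- unlist(lapply(names(assembly$lengths), function(ch) {
    s <- segments[chrom == ch]
    if (nrow(s) == 0L) return(character())
    substring(as.character(assembly$seq[[ch]]), s$start, s$end)
  }))
  ## segments are generated per chromosome in order, matching seg_seqs order
  res <- cpp_search_segments(seg_seqs, as.character(library$seq),
                             k = k, min_identity = min_identity,
                             min_len = min_hit_length, xdrop = xdrop)
  res <- data.table::as.data.table(res)
  if (nrow(res) == 0L) return(.empty_hits())
  fam <- library$entries$family
  hits <- data.table::data.table(
    chrom = segments$chrom[res$seg],
    start = segments$start[res$seg] + res$qstart - 1L,
    end = segments$start[res$seg] + res$qend - 1L,
    family = fam[res$lib],
    superfamily = library$entries$superfamily[res$lib],
    strand = res$strand,
    identity = res$identity,
    length = res$length,
    cons_start = res$sstart,
    cons_end = res$send,
    seg_index = segments$seg_index[res$seg]
  )
  rs_log("search_segments: %d segment(s) -> %d hit(s)", nrow(segments),
         nrow(hits))
  hits[]
}

#' @keywords internal
.empty_hits <- function() {
  data.table::data.table(chrom = character(), start = integer(),
                         end = integer(), family = character(),
                         superfamily = character(), strand = character(),
                         identity = numeric(), length = integer(),
                         cons_start = integer(), cons_end = integer(),
                         seg_index = integer())
}

#' Read hits from an external aligner's tabular output
#'
#' Adapter for BLAST-style `-outfmt 6` files where the query is a whole
#' chromosome (qseqid = chromosome name, qstart/qend genome coordinates).
#' Minus-strand hits are recognised by sstart > send and reported on the
#' forward consensus.
#'
#' @param path tabular hits file.
#' @param library a [te_library()]; subject ids must be family names.
#' @param min_identity,min_hit_length filtering thresholds.
#' @return hit table as from [search_segments()].
#' @export
read_external_hits <- function(path, library, min_identity = 80,
                               min_hit_length = 50L) {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      col.names = c("qseqid", "sseqid", "pident", "length",
                                    "mismatch", "gapopen", "qstart", "qend",
                                    "sstart", "send", "evalue", "bitscore")[1:12]),
    error = function(e) stop("hits file parse error in '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dt) < 10L || !is.numeric(dt$pident) || !is.numeric(dt$qstart)) {
    stop("hits file parse error in '", path,
         "': expected >= 10 tabular columns with numeric coordinates")
  }
  bad <- !dt$sseqid %in% library$entries$family
  if (any(bad)) {
    stop("hits file names unknown families: ",
         paste(unique(dt$sseqid[bad]), collapse = ", "))
  }
  minus <- dt$sstart > dt$send
  hits <- data.table::data.table(
    chrom = dt$qseqid,
    start = as.integer(pmin(dt$qstart, dt$qend)),
    end = as.integer(pmax(dt$qstart, dt$qend)),
    family = dt$sseqid,
    superfamily = superfamily_of(dt$sseqid),
    strand = ifelse(minus, "-", "+"),
    identity = dt$pident,
    length = as.integer(dt$length),
    cons_start = as.integer(pmin(dt$sstart, dt$send)),
    cons_end = as.integer(pmax(dt$sstart, dt$send)),
    seg_index = NA_integer_
  )
  hits <- hits[identity >= min_identity & length >= min_hit_length]
  rs_log("read_external_hits: %d hit(s) kept from %s", nrow(hits), path)
  hits[]
}

#' Merge and bridge segment hits into TE annotations
#'
#' Applies the union, gap-bridging and assembly-gap extension rules described
#' above. Bridging across a hit of a different family (or the opposite
#' strand) is not allowed. Idempotent: applying it to its own output changes
#' nothing.
#'
#' @param hits hit table ([search_segments()] output or compatible).
#' @param assembly_gaps optional data.table chrom/start/end of assembly
#'   N-gaps (e.g. `assembly$gaps`).
#' @param bridge_gap bridge gaps with fewer than this many intervening bases.
#' @param gap_extend extend annotations separated from an assembly gap by
#'   fewer than this many bases.
#' @return annotation data.table: chrom, start, end, family, superfamily,
#'   strand, identity (best supporting hit), n_hits, cons_min, cons_max.
#' @export
merge_and_bridge <- function(hits, assembly_gaps = NULL, bridge_gap = 100L,
                             gap_extend = 80L) {
  h <- data.table::as.data.table(hits)
  if (nrow(h) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), family = character(),
                                  superfamily = character(),
                                  strand = character(), identity = numeric(),
                                  n_hits = integer(), cons_min = integer(),
                                  cons_max = integer()))
  }
  if (!"cons_start" %in% names(h)) h[, cons_start := NA_integer_]
  if (!"cons_end" %in% names(h)) h[, cons_end := NA_integer_]
  if (!"superfamily" %in% names(h)) h[, superfamily := superfamily_of(family)]
  if (!"n_hits" %in% names(h)) h[, n_hits := 1L]
  n_in <- nrow(h)
  ## merge/bridge and N-gap extension interact (an extension can pull two
  ## annotations within bridge distance), so iterate to a fixpoint; this
  ## makes the operation idempotent.
  for (pass in 1:10) {
    out <- .merge_pass(h, bridge_gap)
    out <- .extend_pass(out, assembly_gaps, gap_extend)
    stable <- nrow(out) == nrow(h) &&
      isTRUE(all.equal(out$start, h$start)) && isTRUE(all.equal(out$end, h$end))
    h <- out
    if (stable) break
  }
  data.table::setnames(h, c("cons_start", "cons_end"),
                       c("cons_min", "cons_max"))
  data.table::setorder(h, chrom, start, end, family)
  rs_log("merge_and_bridge: %d hit(s) -> %d annotation(s)", n_in, nrow(h))
  return(h[])
}

#' @keywords internal
.merge_pass <- function(h, bridge_gap) {
  data.table::setorder(h, chrom, family, strand, start, end)
  h[, row_id := .I]
  h[, prev_end := shift(cummax(end)), by = .(chrom, family, strand)]
  h[, gap := start - prev_end - 1L]

  ## blocking: a hit of another family/strand inside a candidate bridge gap
  h[, blocked := FALSE]
  cand <- h[!is.na(gap) & gap > 0L & gap < bridge_gap,
            .(chrom, gs = prev_end + 1L, ge = start - 1L, family, strand,
              row_id)]
  if (nrow(cand) > 0L) {
    y <- h[, .(chrom, start, end, yfam = family, ystr = strand)]
    data.table::setkey(y, chrom, start, end)
    ov <- data.table::foverlaps(
      cand[, .(chrom, start = gs, end = ge, family, strand, row_id)],
      y, type = "any", nomatch = NULL)
    blocked_ids <- unique(ov[yfam != family | ystr != strand, row_id])
    h[row_id %in% blocked_ids, blocked := TRUE]
  }

  h[, new_ann := is.na(gap) | gap >= bridge_gap | (gap > 0L & blocked)]
  h[, cluster := cumsum(new_ann), by = .(chrom, family, strand)]
  ann <- h[, .(start = min(start), end = max(end),
               identity = max(identity), n_hits = sum(n_hits),
               cons_min = suppressWarnings(min(cons_start, na.rm = TRUE)),
               cons_max = suppressWarnings(max(cons_end, na.rm = TRUE))),
           by = .(chrom, family, superfamily, strand, cluster)]
  ann[, cluster := NULL]
  ann[!is.finite(cons_min), cons_min := NA_integer_]
  ann[!is.finite(cons_max), cons_max := NA_integer_]
  ## keep the column shape stable across passes
  data.table::setnames(ann, c("cons_min", "cons_max"),
                       c("cons_start", "cons_end"))
  ann[]
}

#' @keywords internal
.extend_pass <- function(ann, assembly_gaps, gap_extend) {
  if (is.null(assembly_gaps) || nrow(assembly_gaps) == 0L) return(ann)
  gdt <- data.table::as.data.table(assembly_gaps)
  for (ch in unique(ann$chrom)) {
    g <- gdt[chrom == ch][order(start)]
    if (nrow(g) == 0L) next
    idx <- which(ann$chrom == ch)
    ## right side: first gap starting after the annotation end
    i_right <- findInterval(ann$end[idx], g$start) + 1L
    has_r <- i_right <= nrow(g)
    dist_r <- ifelse(has_r, g$start[pmin(i_right, nrow(g))] - ann$end[idx] - 1L,
                     NA_integer_)
    ext_r <- has_r & !is.na(dist_r) & dist_r >= 0L & dist_r < gap_extend
    ann$end[idx[ext_r]] <- g$start[i_right[ext_r]] - 1L
    ## left side: last gap ending before the annotation start
    i_left <- findInterval(ann$start[idx] - 1L, g$end)
    has_l <- i_left >= 1L
    dist_l <- ifelse(has_l, ann$start[idx] - g$end[pmax(i_left, 1L)] - 1L,
                     NA_integer_)
    ext_l <- has_l & !is.na(dist_l) & dist_l >= 0L & dist_l < gap_extend
    ann$start[idx[ext_l]] <- g$end[i_left[ext_l]] + 1L
  }
  ann
}

#' Flag annotations whose ends reach the consensus termini
#'
#' An annotation is 5'-intact when its supporting alignments reach within
#' `end_tolerance` bp of consensus position 1, and 3'-intact analogously at
#' the consensus length. Hits carry forward-consensus coordinates for both
#' strands, so the test is orientation-independent. Annotations without
#' consensus support information get NA flags.
#'
#' @param annotations [merge_and_bridge()] output.
#' @param library a [te_library()].
#' @param hits optional hit table to recompute consensus coverage from
#'   (otherwise the cons_min/cons_max carried on the annotations are used).
#' @param end_tolerance bp tolerance at each consensus end (default 20).
#' @return annotations with five_prime_intact, three_prime_intact, complete.
#' @export
detect_full_length <- function(annotations, library, hits = NULL,
                               end_tolerance = 20L) {
  ann <- data.table::as.data.table(annotations)
  if (!is.null(hits)) {
    h <- data.table::as.data.table(hits)[, .(chrom, start, end, family,
                                             strand, cons_start, cons_end)]
    data.table::setkey(h, chrom, start, end)
    ann[, ann_id := .I]
    ov <- data.table::foverlaps(
      ann[, .(chrom, start, end, family, strand, ann_id)], h,
      type = "any", nomatch = NULL)
    ov <- ov[family == i.family & strand == i.strand]
    cov <- ov[, .(cons_min = min(cons_start), cons_max = max(cons_end)),
              by = ann_id]
    ann[, c("cons_min", "cons_max") := NULL]
    ann <- merge(ann, cov, by = "ann_id", all.x = TRUE)
    ann[, ann_id := NULL]
  }
  L <- library_lengths(library)
  ann[, five_prime_intact := cons_min - 1L <= end_tolerance]
  ann[, three_prime_intact := L[family] - cons_max <= end_tolerance]
  ann[, complete := five_prime_intact & three_prime_intact]
  ann[]
}

#' Assign a sequence to a TE family by the 80/80 rule
#'
#' Two TE sequences belong to the same family when they are more than 80%
#' identical over more than 80% of the length of the shorter sequence. Among
#' families satisfying the rule the one with the highest identity wins (ties
#' by name). Both orientations are searched.
#'
#' @param sequence a single DNA sequence (character).
#' @param library a [te_library()].
#' @param min_identity identity threshold in percent (strict >).
#' @param min_coverage alignable-fraction threshold (strict >).
#' @param k seed size of the alignment backend.
#' @return the winning family name, or `"unassigned"`.
#' @export
assign_family_80_80 <- function(sequence, library, min_identity = 80,
                                min_coverage = 0.8, k = 11L) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("'sequence' must be a single non-empty string")
  }
  sequence <- toupper(sequence)
  ent <- library$entries
  libseq <- as.character(library$seq)
  best_fam <- "unassigned"; best_id <- -1
  for (i in seq_len(nrow(ent))) {
    hit <- cpp_best_diagonal_hit(sequence, libseq[[i]], k = k)
    need <- min_coverage * min(nchar(sequence), ent$length[i])
    if (hit$identity > min_identity && hit$length > need) {
      if (hit$identity > best_id ||
          (hit$identity == best_id && ent$family[i] < best_fam)) {
        best_id <- hit$identity
        best_fam <- ent$family[i]
      }
    }
  }
  best_fam
}

#' Build a family consensus from full-length copies
#'
#' Copies are multiple-aligned (mafft) and the consensus is called per
#' column: gap-majority columns are dropped; within a column the majority
#' nucleotide wins, ties broken by the nucleotide's frequency across the
#' whole alignment, then alphabetically.
#'
#' @param copies DNAStringSet or character vector of copy sequences.
#' @param min_copies minimum number of copies (default 3); fewer is an error.
#' @param max_copies use at most this many copies (the longest ones).
#' @return object of class `consensus_build`: list with n_copies,
#'   n_columns (alignment columns), consensus (character), column_support
#'   (per-consensus-column majority fraction among non-gap characters).
#' @export
build_consensus <- function(copies, min_copies = 3L, max_copies = 100L) {
  if (inherits(copies, "DNAStringSet")) copies <- as.character(copies)
  copies <- toupper(copies)
  if (length(copies) < min_copies) {
    stop(sprintf("consensus construction needs at least %d copies, got %d",
                 min_copies, length(copies)))
  }
  if (length(copies) > max_copies) {
    copies <- copies[order(-nchar(copies))][seq_len(max_copies)]
  }
  aln <- if (length(unique(nchar(copies))) == 1L && length(unique(copies)) == 1L) {
    copies  # identical copies need no alignment
  } else {
    .run_mafft(copies)
  }
  mat <- do.call(rbind, strsplit(aln, ""))
  n <- nrow(mat)
  global_freq <- table(factor(mat[mat %in% c("A", "C", "G", "T")],
                              levels = c("A", "C", "G", "T")))
  keep <- colSums(mat == "-") <= n / 2      # drop gap-majority columns
  cons <- character(0); support <- numeric(0)
  bases <- c("A", "C", "G", "T")
  for (j in which(keep)) {
    col <- mat[, j]
    cnt <- vapply(bases, function(b) sum(col == b), numeric(1))
    nongap <- sum(col != "-")
    if (all(cnt == 0)) { cons <- c(cons, "N"); support <- c(support, 0); next }
    top <- cnt == max(cnt)
    cand <- bases[top]
    if (length(cand) > 1L) {
      gf <- global_freq[cand]
      cand <- cand[gf == max(gf)]
      cand <- sort(cand)[1]                  # alphabetic last resort
    }
    cons <- c(cons, cand)
    support <- c(support, max(cnt) / nongap)
  }
  structure(list(n_copies = length(copies), n_columns = ncol(mat),
                 consensus = paste(cons, collapse = ""),
                 column_support = support),
            class = "consensus_build")
}

#' @export
print.consensus_build <- function(x, ...) {
  cat(sprintf("consensus_build: %d copies, %d alignment columns, %d bp consensus\n",
              x$n_copies, x$n_columns, nchar(x$consensus)))
  invisible(x)
}

#' @keywords internal
.run_mafft <- function(seqs) {
  mafft <- Sys.which("mafft")
  if (mafft == "") stop("mafft not found on PATH; required by build_consensus()")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">s", seq_along(seqs), "\n", seqs), fin)
  status <- system2(mafft, c("--quiet", "--retree", "2", "--maxiterate", "0",
                             shQuote(fin)), stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- Biostrings::readBStringSet(fout)
  toupper(as.character(aln))
}

#' Longest open reading frame over all six frames
#'
#' An ORF is an ATG-initiated, stop-free codon run; its length in codons
#' includes the ATG and excludes the stop. Runs reaching the end of the
#' sequence without a stop count too.
#'
#' @param sequence DNA sequence (character).
#' @return longest ORF length in codons (0 if none).
#' @export
longest_orf_codons <- function(sequence) {
  sequence <- toupper(sequence)
  best <- 0L
  for (s in c(sequence, revcomp_chr(sequence))) {
    n <- nchar(s)
    for (f in 1:3) {
      if (n - f + 1L < 3L) next
      starts <- seq.int(f, n - 2L, by = 3L)
      cods <- substring(s, starts, starts + 2L)
      is_stop <- cods %in% c("TAA", "TAG", "TGA")
      bounds <- c(0L, which(is_stop), length(cods) + 1L)
      for (i in seq_len(length(bounds) - 1L)) {
        lo <- bounds[i] + 1L; hi <- bounds[i + 1L] - 1L
        if (hi - lo + 1L <= best) next
        atg <- match("ATG", cods[lo:hi])
        if (!is.na(atg)) best <- max(best, hi - (lo + atg - 1L) + 1L)
      }
    }
  }
  best
}

#' Classify a consensus as autonomous or non-autonomous
#'
#' A family is autonomous when any of the six reading frames of its
#' consensus contains an uninterrupted ORF of at least `min_orf_codons`
#' codons; otherwise it is non-autonomous.
#'
#' @param consensus consensus sequence (character).
#' @param min_orf_codons ORF length threshold in codons (default 300).
#' @return `"autonomous"` or `"non-autonomous"`.
#' @export
classify_autonomy <- function(consensus, min_orf_codons = 300L) {
  if (!is.character(consensus) || length(consensus) != 1L || nchar(consensus) == 0L) {
    stop("'consensus' must be a single non-empty string")
  }
  if (longest_orf_codons(consensus) >= min_orf_codons) "autonomous"
  else "non-autonomous"
}

#' One-call annotation pipeline
#'
#' Segments the genome, searches the library, merges/bridges hits and flags
#' full-length copies.
#'
#' @inheritParams search_segments
#' @inheritParams merge_and_bridge
#' @inheritParams detect_full_length
#' @return list with `annotations` and `hits`.
#' @export
annotate_genome <- function(assembly, library, segment_length = 180L,
                            min_identity = 80, min_hit_length = 50L,
                            bridge_gap = 100L, gap_extend = 80L,
                            end_tolerance = 20L, k = 11L, xdrop = 15L) {
  hits <- search_segments(assembly, library, min_identity = min_identity,
                          min_hit_length = min_hit_length,
                          segment_length = segment_length, k = k,
                          xdrop = xdrop)
  ann <- merge_and_bridge(hits, assembly_gaps = assembly$gaps,
                          bridge_gap = bridge_gap, gap_extend = gap_extend)
  ann <- detect_full_length(ann, library, end_tolerance = end_tolerance)
  list(annotations = ann, hits = hits)
}
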