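## TSS/TES-anchored TE frequency profiles, Gypsy:Copia ratio curves, and
## target-site nucleotide composition around complete TE insertions.

#' TSS/TES-anchored TE frequency profiles
#'
#' For every gene, the strand-oriented flank upstream of the TSS and
#' downstream of the TES is sampled at every `step`-th base over `flank` bp
#' (500 offsets per side at the defaults). At each sampled position the
#' covering hit with the longest alignment wins (ties: higher identity, then
#' family name) and its group is recorded; frequencies are the fraction of
#' genes whose sampled position is covered by the group. Offsets of
#' minus-strand genes are reflected so "upstream" is biologically upstream.
#' Positions beyond chromosome ends are excluded from that offset's
#' denominator.
#'
#' @param genes gene table with strand.
#' @param hits hit or annotation table (chrom/start/end/family/strand, with
#'   length/identity used for tie-breaking when present).
#' @param chromosome_lengths named vector of chromosome lengths.
#' @param flank flank size in bp (default 10 kb); must be divisible by step.
#' @param step sampling step in bp (default 20); offset 0 (the anchor base
#'   itself) is excluded.
#' @param groups optional named vector mapping family -> group label;
#'   default groups by superfamily.
#' @return object of class `anchored_profile`: list with `upstream` and
#'   `downstream` data.tables (offset_bp, group, freq, n_genes), plus step,
#'   flank and the number of genes.
#' @export
build_anchor_profile <- function(genes, hits, chromosome_lengths,
                                 flank = 10000L, step = 20L, groups = NULL) {
  if (flank %% step != 0L) stop("'flank' must be divisible by 'step'")
  g <- add_tss_tes(data.table::as.data.table(genes))
  h <- data.table::as.data.table(hits)
  if (!"length" %in% names(h)) h[, length := end - start + 1L]
  if (!"identity" %in% names(h)) h[, identity := NA_real_]
  if (is.null(groups)) {
    if (!"superfamily" %in% names(h)) h[, superfamily := superfamily_of(family)]
    h[, group := superfamily]
  } else {
    h[, group := groups[family]]
  }
  offs <- seq.int(step, flank, by = step)       # 1..500 offsets x step
  n_off <- length(offs)
  sgn <- ifelse(g$strand == "+", 1L, -1L)
  ## genomic positions: upstream of TSS and downstream of TES, oriented
  pos_dt <- data.table::rbindlist(list(
    data.table::data.table(
      gene = rep(seq_len(nrow(g)), each = n_off),
      anchor = "upstream",
      offset_bp = rep(offs, times = nrow(g)),
      chrom = rep(g$chrom, each = n_off),
      pos = rep(g$tss, each = n_off) - rep(sgn, each = n_off) * rep(offs, times = nrow(g))),
    data.table::data.table(
      gene = rep(seq_len(nrow(g)), each = n_off),
      anchor = "downstream",
      offset_bp = rep(offs, times = nrow(g)),
      chrom = rep(g$chrom, each = n_off),
      pos = rep(g$tes, each = n_off) + rep(sgn, each = n_off) * rep(offs, times = nrow(g)))
  ))
  pos_dt[, valid := pos >= 1L & pos <= chromosome_lengths[chrom]]
  denom <- pos_dt[valid == TRUE, .(n_genes = .N), by = .(anchor, offset_bp)]
  q <- pos_dt[valid == TRUE, .(chrom, start = pos, end = pos, gene, anchor,
                               offset_bp)]
  hk <- h[, .(chrom, start, end, group, length, identity, family)]
  data.table::setkey(hk, chrom, start, end)
  ov <- data.table::foverlaps(q, hk, by.x = c("chrom", "start", "end"),
                              type = "any", nomatch = NULL)
  ## longest covering hit wins; ties by identity then family name
  data.table::setorder(ov, gene, anchor, offset_bp, -length, -identity, family,
                       na.last = TRUE)
  win <- ov[, .SD[1L], by = .(gene, anchor, offset_bp)]
  freq <- win[, .(n_covered = .N), by = .(anchor, offset_bp, group)]
  freq <- merge(freq, denom, by = c("anchor", "offset_bp"))
  freq[, freq := n_covered / n_genes]
  mk <- function(side) {
    out <- freq[anchor == side, .(offset_bp, group, freq, n_genes)]
    data.table::setorder(out, group, offset_bp)
    out[]
  }
  structure(list(upstream = mk("upstream"), downstream = mk("downstream"),
                 step = step, flank = flank, n_genes = nrow(g)),
            class = "anchored_profile")
}

#' @export
print.anchored_profile <- function(x, ...) {
  cat(sprintf("anchored_profile: %d genes, %d offsets per side (step %d bp, flank %d bp)\n",
              x$n_genes, x$flank %/% x$step, x$step, x$flank))
  invisible(x)
}

#' Gypsy:Copia frequency ratio along an anchored profile
#'
#' @param profile an [build_anchor_profile()] result grouped by superfamily.
#' @param gypsy,copia group labels.
#' @param smooth optional centered running-mean window (in offsets; 1 = none).
#' @return data.table: anchor, offset_bp, gypsy, copia, ratio (NA where the
#'   Copia frequency is zero).
#' @export
gypsy_copia_ratio <- function(profile, gypsy = "Gypsy", copia = "Copia",
                              smooth = 1L) {
  one <- function(dt, side) {
    gt <- dt[group == gypsy, .(offset_bp, gypsy = freq)]
    ct <- dt[group == copia, .(offset_bp, copia = freq)]
    if (nrow(gt) == 0L && nrow(ct) == 0L) {
      return(data.table::data.table(anchor = character(),
                                    offset_bp = integer(), gypsy = numeric(),
                                    copia = numeric(), ratio = numeric()))
    }
    m <- merge(gt, ct, by = "offset_bp", all = TRUE)
    m[is.na(gypsy), gypsy := 0]
    m[is.na(copia), copia := 0]
    if (smooth > 1L) {
      m[, gypsy := data.table::frollmean(gypsy, smooth, align = "center",
                                         na.rm = TRUE)]
      m[, copia := data.table::frollmean(copia, smooth, align = "center",
                                         na.rm = TRUE)]
    }
    m[, ratio := ifelse(copia > 0, gypsy / copia, NA_real_)]
    cbind(anchor = side, m)
  }
  out <- data.table::rbindlist(list(one(profile$upstream, "upstream"),
                                    one(profile$downstream, "downstream")))
  if (nrow(out) == 0L) {
    stop("profile contains neither '", gypsy, "' nor '", copia, "' group")
  }
  out
}

#' Nucleotide composition of the flanks of complete TE insertions
#'
#' Collects the `flank` bp on each side of complete (both-ends-intact)
#' copies, in the element's orientation (minus-strand copies are
#' reverse-complemented so position -1 is always immediately upstream of the
#' element's 5' end). Copies too close to a chromosome end are skipped and
#' logged. Ns are excluded from the per-position fractions and tracked
#' separately.
#'
#' @param annotations TE annotation table with a `complete` flag.
#' @param assembly a [genome_assembly()].
#' @param flank flank size in bp (default 30, the customary window).
#' @return object of class `target_site_matrix`: list with `positions`
#'   (-flank..-1, 1..flank), `counts` (4 x 2*flank matrix), `fractions`,
#'   `n_copies`, `n_N` (per-position N counts).
#' @export
target_site_matrix <- function(annotations, assembly, flank = 30L) {
  a <- data.table::as.data.table(annotations)
  a <- a[complete == TRUE]
  if (nrow(a) == 0L) stop("no usable copies: no complete annotations")
  lens <- assembly$lengths
  fits <- a$start - flank >= 1L & a$end + flank <= lens[a$chrom]
  if (any(!fits)) {
    rs_log("target_site_matrix: skipping %d copies too close to a chromosome end",
           sum(!fits))
  }
  a <- a[fits]
  if (nrow(a) == 0L) stop("no usable copies: all too close to chromosome ends")
  left <- character(nrow(a)); right <- character(nrow(a))
  for (ch in unique(a$chrom)) {
    idx <- which(a$chrom == ch)
    s <- as.character(assembly$seq[[ch]])
    left[idx] <- substring(s, a$start[idx] - flank, a$start[idx] - 1L)
    right[idx] <- substring(s, a$end[idx] + 1L, a$end[idx] + flank)
  }
  minus <- a$strand == "-"
  if (any(minus)) {
    rc <- function(x) as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x)))
    new_left <- left; new_right <- right
    new_left[minus] <- rc(right[minus])
    new_right[minus] <- rc(left[minus])
    left <- new_left; right <- new_right
  }
  flanks <- paste0(left, right)                  # 2*flank characters per copy
  mat <- do.call(rbind, strsplit(flanks, ""))
  positions <- c(seq.int(-flank, -1L), seq.int(1L, flank))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    vapply(bases, function(b) sum(col == b), numeric(1))
  }, numeric(4))
  rownames(counts) <- bases
  colnames(counts) <- positions
  n_N <- nrow(mat) - colSums(counts)
  fractions <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  structure(list(positions = positions, counts = counts,
                 fractions = fractions, n_copies = nrow(a), n_N = n_N),
            class = "target_site_matrix")
}

#' @export
print.target_site_matrix <- function(x, ...) {
  cat(sprintf("target_site_matrix: %d copies, positions %d..%d around the insertion site\n",
              x$n_copies, min(x$positions), max(x$positions)))
  invisible(x)
}

#' Call a degenerate consensus motif from a target-site matrix
#'
#' Per position: a single letter when its fraction reaches
#' `majority_threshold`; a two-letter class like `[T/A]` (letters in
#' decreasing frequency) when the best pair reaches the threshold; otherwise
#' `n`. The insertion point is marked `-`.
#'
#' @param matrix a [target_site_matrix()] result.
#' @param majority_threshold fraction threshold (default 0.8).
#' @return the motif as a single string.
#' @export
consensus_motif <- function(matrix, majority_threshold = 0.8) {
  fr <- matrix$fractions
  call1 <- function(j) {
    f <- sort(fr[, j], decreasing = TRUE)
    if (f[1] >= majority_threshold) return(names(f)[1])
    if (f[1] + f[2] >= majority_threshold) {
      return(sprintf("[%s/%s]", names(f)[1], names(f)[2]))
    }
    "n"
  }
  sym <- vapply(seq_along(matrix$positions), call1, character(1))
  at <- which(matrix$positions == 1L)           # insertion point before +1
  paste0(paste(sym[seq_len(at - 1L)], collapse = ""), "-",
         paste(sym[at:length(sym)], collapse = ""))
}
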