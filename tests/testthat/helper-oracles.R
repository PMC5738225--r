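## Independent oracles used by the tests. These deliberately avoid the
## package's own code paths: alignment via Biostrings::pairwiseAlignment,
## merge/bridge via a brute-force pairwise fixpoint, window levels via
## direct summation, and the placement null via exact enumeration of the
## sequential placement process.

## quadratic local-alignment oracle: percent identity and length of the
## best local alignment (match +1 / mismatch -1, affine-ish gaps)
sw_oracle <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 2)
  len <- Biostrings::nchar(Biostrings::alignedPattern(pa))
  list(identity = 100 * Biostrings::nmatch(pa) / len, length = len,
       score = Biostrings::score(pa))
}

## brute-force merge/bridge fixpoint: repeatedly apply
##   (1) union overlapping/adjacent same-family same-strand intervals,
##   (2) bridge 0 < gap < bridge_gap same-family same-strand pairs unless a
##       different family/strand interval overlaps the open gap,
##   (3) extend toward assembly gaps closer than gap_extend,
## until nothing changes.
merge_bridge_oracle <- function(hits, assembly_gaps = NULL,
                                bridge_gap = 100L, gap_extend = 80L) {
  df <- as.data.frame(hits)[, c("chrom", "start", "end", "family", "strand",
                                "identity")]
  gp <- if (is.null(assembly_gaps)) NULL else as.data.frame(assembly_gaps)
  repeat {
    changed <- FALSE
    ## rule 1 + 2: try to merge any pair
    n <- nrow(df)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i >= j || merged) next
        if (df$chrom[i] != df$chrom[j] || df$family[i] != df$family[j] ||
            df$strand[i] != df$strand[j]) next
        lo <- which.min(c(df$start[i], df$start[j]))
        a <- c(i, j)[lo]; b <- c(i, j)[-lo]
        gap <- df$start[b] - df$end[a] - 1L
        ok <- FALSE
        if (gap <= 0L) ok <- TRUE
        else if (gap < bridge_gap) {
          gs <- df$end[a] + 1L; ge <- df$start[b] - 1L
          block <- any(df$chrom == df$chrom[i] &
                         (df$family != df$family[i] |
                            df$strand != df$strand[i]) &
                         df$start <= ge & df$end >= gs)
          ok <- !block
        }
        if (ok) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df$identity[i] <- max(df$identity[i], df$identity[j])
          df <- df[-j, , drop = FALSE]
          merged <- TRUE; changed <- TRUE
        }
      }
    }
    ## rule 3: extension
    if (!merged && !is.null(gp) && nrow(gp) > 0L) {
      for (i in seq_len(nrow(df))) {
        gch <- gp[gp$chrom == df$chrom[i], , drop = FALSE]
        for (k in seq_len(nrow(gch))) {
          dr <- gch$start[k] - df$end[i] - 1L
          if (dr >= 0L && dr < gap_extend && gch$start[k] - 1L > df$end[i]) {
            df$end[i] <- gch$start[k] - 1L; changed <- TRUE
          }
          dl <- df$start[i] - gch$end[k] - 1L
          if (dl >= 0L && dl < gap_extend && gch$end[k] + 1L < df$start[i]) {
            df$start[i] <- gch$end[k] + 1L; changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  dt <- data.table::as.data.table(df)
  data.table::setorder(dt, chrom, start, end, family)
  dt
}

## pooled window level by direct summation
window_level_oracle <- function(calls, chrom_, wstart, window, context_) {
  x <- calls[calls$chrom == chrom_ & calls$context == context_ &
               calls$pos >= wstart & calls$pos <= wstart + window - 1L, ]
  if (sum(x$total) == 0L) return(NA_real_)
  sum(x$meth) / sum(x$total)
}

## exact expectation of the clustered fraction under the sequential uniform
## placement process (equal-length genes, one chromosome, discrete positions)
null_fraction_oracle <- function(n_genes, gene_len, L, max_gap) {
  positions <- seq_len(L - gene_len + 1L)
  recurse <- function(placed) {
    if (length(placed) == n_genes) {
      s <- sort(placed)
      e <- s + gene_len - 1L
      gaps <- s[-1L] - e[-length(e)] - 1L
      in_cluster <- logical(length(s))
      if (length(gaps)) {
        link <- gaps < max_gap
        in_cluster[-1L][link] <- TRUE
        in_cluster[-length(s)][link] <- TRUE
      }
      return(mean(in_cluster))
    }
    valid <- positions[vapply(positions, function(p) {
      all(p + gene_len - 1L < placed | p > placed + gene_len - 1L)
    }, logical(1))]
    if (length(valid) == 0L) stop("no valid position")
    mean(vapply(valid, function(p) recurse(c(placed, p)), numeric(1)))
  }
  recurse(integer(0))
}
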