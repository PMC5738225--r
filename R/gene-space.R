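## Gene-space analyses: single-linkage gene clustering with a random
## placement null, TE-to-gene distances and near-gene enrichment, gene-island
## vs intergenic TE composition, and TE orientation bias relative to genes.

#' Cluster genes separated by less than a maximum gap
#'
#' Single-linkage chaining per chromosome: consecutive genes whose
#' edge-to-edge gap (intervening bases) is strictly below `max_gap` join the
#' same cluster; a gap of exactly `max_gap` separates clusters. Overlapping
#' genes are treated as gap 0 (logged).
#'
#' @param genes gene table (chrom/start/end, any extra columns kept).
#' @param max_gap gap threshold in bp (default 20 kb).
#' @return object of class `gene_cluster_set`: list with `genes` (input plus
#'   cluster_id and cluster_size), `sizes` (cluster-size histogram) and
#'   `fraction_clustered` (fraction of genes in clusters of size >= 2).
#' @export
cluster_genes <- function(genes, max_gap = 20000L) {
  g <- data.table::as.data.table(genes)
  data.table::setorder(g, chrom, start, end)
  g[, prev_end := shift(cummax(end)), by = chrom]
  g[, gap := start - prev_end - 1L]
  n_overlap <- sum(g$gap < 0L, na.rm = TRUE)
  if (n_overlap > 0L) rs_log("cluster_genes: %d overlapping gene pair(s) treated as gap 0",
                             n_overlap)
  g[, new_cluster := is.na(gap) | gap >= max_gap]
  g[, cluster_local := cumsum(new_cluster), by = chrom]
  g[, cluster_id := .GRP, by = .(chrom, cluster_local)]
  g[, c("prev_end", "gap", "new_cluster", "cluster_local") := NULL]
  g[, cluster_size := .N, by = cluster_id]
  sizes <- g[, .(size = .N), by = cluster_id][, .(n_clusters = .N), by = size]
  data.table::setorder(sizes, size)
  structure(list(genes = g[], sizes = sizes[],
                 fraction_clustered = mean(g$cluster_size >= 2)),
            class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("gene_cluster_set: %d genes, %d clusters, %.1f%% of genes in clusters >= 2\n",
              nrow(x$genes), sum(x$sizes$n_clusters),
              100 * x$fraction_clustered))
  invisible(x)
}

#' @keywords internal
.place_random_genes <- function(gene_lengths, chromosome_lengths,
                                max_tries = 1000L) {
  chs <- names(chromosome_lengths)
  placed <- vector("list", length(chs))
  names(placed) <- chs
  for (ch in chs) placed[[ch]] <- list(starts = integer(), ends = integer())
  w <- as.numeric(chromosome_lengths) / sum(as.numeric(chromosome_lengths))
  out_ch <- character(length(gene_lengths))
  out_s <- integer(length(gene_lengths))
  for (i in seq_along(gene_lengths)) {
    len <- gene_lengths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chs, 1L, prob = w)
      Lc <- chromosome_lengths[[ch]]
      if (Lc < len) next
      s <- sample.int(Lc - len + 1L, 1L)
      e <- s + len - 1L
      p <- placed[[ch]]
      j <- findInterval(e, p$starts)
      if (j >= 1L && p$ends[j] >= s) next   # overlap
      placed[[ch]]$starts <- append(p$starts, s, after = j)
      placed[[ch]]$ends <- append(p$ends, e, after = j)
      out_ch[i] <- ch; out_s[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) stop("random placement failed: genes cannot fit")
  }
  data.table::data.table(chrom = out_ch, start = out_s,
                         end = out_s + gene_lengths - 1L)
}

#' Null distribution of the clustered-gene fraction under random placement
#'
#' Each replicate places the observed gene lengths uniformly at random
#' without overlap (genes keep their lengths), re-runs [cluster_genes()] and
#' records the fraction of genes in clusters of size >= 2.
#'
#' @param gene_lengths observed gene lengths in bp.
#' @param chromosome_lengths named vector of chromosome lengths.
#' @param max_gap clustering gap threshold.
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed.
#' @param observed_fraction optional observed clustered fraction; when given,
#'   an empirical p-value for enrichment is computed as
#'   (1 + #\{null >= observed\}) / (n_reps + 1).
#' @return list: fractions (per replicate), mean, sd, p_value (or NA).
#' @export
random_placement_null <- function(gene_lengths, chromosome_lengths,
                                  max_gap = 20000L, n_reps = 100L,
                                  seed = 1L, observed_fraction = NULL) {
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  set.seed(seed)
  fractions <- vapply(seq_len(n_reps), function(r) {
    g <- .place_random_genes(gene_lengths, chromosome_lengths)
    cluster_genes(g, max_gap = max_gap)$fraction_clustered
  }, numeric(1))
  p <- if (is.null(observed_fraction)) NA_real_
       else (1 + sum(fractions >= observed_fraction)) / (n_reps + 1)
  list(fractions = fractions, mean = mean(fractions),
       sd = stats::sd(fractions), p_value = p)
}

#' TE-to-gene distances and near-gene fractions
#'
#' Distance from each TE to the nearest gene on the same chromosome, by
#' midpoints (default) or edge-to-edge gap (0 when overlapping). TEs on
#' chromosomes without genes get NA. Summaries report the fraction of each
#' superfamily within 5 kb and 10 kb.
#'
#' @param te_annotations TE annotation table.
#' @param genes gene table.
#' @param mode "midpoint" or "edge".
#' @param breaks histogram breaks in bp (right-open bins).
#' @return list: per_te (TE table plus distance), summary (superfamily,
#'   n, frac_within_5kb, frac_within_10kb), histogram (superfamily, bin_lo,
#'   bin_hi, n).
#' @export
te_gene_distance <- function(te_annotations, genes,
                             mode = c("midpoint", "edge"),
                             breaks = seq(0, 50000, by = 1000)) {
  mode <- match.arg(mode)
  te <- data.table::as.data.table(te_annotations)
  g <- data.table::as.data.table(genes)
  te[, mid := interval_midpoint(start, end)]
  g[, mid := interval_midpoint(start, end)]
  te[, distance := NA_real_]
  for (ch in unique(te$chrom)) {
    gi <- g[chrom == ch][order(mid)]
    if (nrow(gi) == 0L) next
    ti <- which(te$chrom == ch)
    if (mode == "midpoint") {
      pos <- te$mid[ti]
      j <- findInterval(pos, gi$mid)
      d_lo <- ifelse(j >= 1L, pos - gi$mid[pmax(j, 1L)], Inf)
      d_hi <- ifelse(j < nrow(gi), gi$mid[pmin(j + 1L, nrow(gi))] - pos, Inf)
      te$distance[ti] <- pmin(d_lo, d_hi)
    } else {
      gi2 <- gi[order(start)]
      s <- te$start[ti]; e <- te$end[ti]
      j <- findInterval(e, gi2$start)
      d_lo <- ifelse(j >= 1L, pmax(0L, s - gi2$end[pmax(j, 1L)]), Inf)
      d_hi <- ifelse(j < nrow(gi2),
                     pmax(0L, gi2$start[pmin(j + 1L, nrow(gi2))] - e), Inf)
      ## a gene overlapping the TE gives distance 0 via d_lo/d_hi clamping,
      ## but check the gene containing/overlapping directly too
      ov <- j >= 1L & gi2$end[pmax(j, 1L)] >= s
      te$distance[ti] <- ifelse(ov, 0, pmin(d_lo, d_hi))
    }
  }
  summ <- te[!is.na(distance),
             .(n = .N,
               frac_within_5kb = mean(distance <= 5000),
               frac_within_10kb = mean(distance <= 10000)),
             by = superfamily]
  hist_dt <- te[!is.na(distance) & distance < max(breaks)]
  hist_dt[, bin := findInterval(distance, breaks)]
  histo <- hist_dt[, .N, by = .(superfamily, bin)]
  histo[, `:=`(bin_lo = breaks[bin], bin_hi = breaks[bin + 1L])]
  data.table::setorder(histo, superfamily, bin)
  list(per_te = te[], summary = summ[],
       histogram = histo[, .(superfamily, bin_lo, bin_hi, n = N)])
}

#' @keywords internal
.subtract_intervals <- function(from, minus) {
  ## both data.tables with start/end on ONE chromosome, sorted; returns
  ## 'from' with 'minus' removed
  if (nrow(minus) == 0L) return(from)
  out <- list()
  m <- minus[order(start)]
  for (i in seq_len(nrow(from))) {
    s <- from$start[i]; e <- from$end[i]
    mm <- m[end >= s & start <= e]
    cur <- s
    for (j in seq_len(nrow(mm))) {
      if (mm$start[j] > cur) {
        out[[length(out) + 1L]] <- data.table::data.table(
          start = cur, end = mm$start[j] - 1L)
      }
      cur <- max(cur, mm$end[j] + 1L)
    }
    if (cur <= e) out[[length(out) + 1L]] <- data.table::data.table(
      start = cur, end = e)
  }
  data.table::rbindlist(out)
}

#' TE composition of gene islands vs large intergenic regions
#'
#' Gene islands are cluster spans extended by `island_flank` on each side;
#' intergenic regions are gene-free stretches of at least `min_intergenic`
#' bp (island flanks excluded from their area). Per-superfamily occupied-bp
#' percentages are computed within each compartment.
#'
#' @param te_annotations TE annotation table.
#' @param genes gene table.
#' @param chromosome_lengths named vector of chromosome lengths.
#' @param min_intergenic minimum gene-free stretch length (default 200 kb).
#' @param island_flank flank added to cluster spans (default 5 kb).
#' @param max_gap clustering gap threshold passed to [cluster_genes()].
#' @return list: composition (compartment, superfamily, occupied_bp,
#'   percent), compartments (compartment, total_bp), islands, intergenic
#'   (interval tables).
#' @export
island_vs_intergenic_composition <- function(te_annotations, genes,
                                             chromosome_lengths,
                                             min_intergenic = 200000L,
                                             island_flank = 5000L,
                                             max_gap = 20000L) {
  te <- data.table::as.data.table(te_annotations)
  g <- data.table::as.data.table(genes)
  islands <- data.table::data.table(chrom = character(), start = integer(),
                                    end = integer())
  if (nrow(g) > 0L) {
    cl <- cluster_genes(g, max_gap = max_gap)
    spans <- cl$genes[, .(start = min(start), end = max(end)),
                      by = .(chrom, cluster_id)]
    spans[, `:=`(start = pmax(1L, start - island_flank),
                 end = pmin(chromosome_lengths[chrom], end + island_flank))]
    ## merge overlapping island spans
    data.table::setorder(spans, chrom, start)
    spans[, prev_end := shift(cummax(end)), by = chrom]
    spans[, grp := cumsum(is.na(prev_end) | start > prev_end + 1L), by = chrom]
    islands <- spans[, .(start = min(start), end = max(end)),
                     by = .(chrom, grp)][, grp := NULL][]
  }
  ## gene-free stretches >= min_intergenic, minus island flanks
  intergenic <- data.table::rbindlist(lapply(names(chromosome_lengths),
                                             function(ch) {
    L <- chromosome_lengths[[ch]]
    whole <- data.table::data.table(start = 1L, end = as.integer(L))
    gene_iv <- g[chrom == ch, .(start, end)]
    free <- .subtract_intervals(whole, gene_iv)
    free <- free[end - start + 1L >= min_intergenic]
    if (nrow(free) == 0L) return(NULL)
    free <- .subtract_intervals(free, islands[chrom == ch, .(start, end)])
    if (nrow(free) == 0L) return(NULL)
    cbind(chrom = ch, free)
  }))
  if (is.null(intergenic) || nrow(intergenic) == 0L) {
    intergenic <- data.table::data.table(chrom = character(),
                                         start = integer(), end = integer())
  }
  comp1 <- .compartment_composition(te, islands, "island")
  comp2 <- .compartment_composition(te, intergenic, "intergenic")
  comps <- data.table::data.table(
    compartment = c("island", "intergenic"),
    total_bp = c(sum(as.numeric(islands$end - islands$start + 1)),
                 sum(as.numeric(intergenic$end - intergenic$start + 1))))
  list(composition = data.table::rbindlist(list(comp1, comp2)),
       compartments = comps, islands = islands, intergenic = intergenic)
}

#' @keywords internal
.compartment_composition <- function(te, regions, label) {
  if (nrow(regions) == 0L || nrow(te) == 0L) {
    return(data.table::data.table(compartment = character(),
                                  superfamily = character(),
                                  occupied_bp = numeric(),
                                  percent = numeric()))
  }
  r <- data.table::copy(regions)
  data.table::setkey(r, chrom, start, end)
  ov <- data.table::foverlaps(te[, .(chrom, start, end, superfamily)], r,
                              by.x = c("chrom", "start", "end"),
                              type = "any", nomatch = NULL)
  ov[, occ := overlap_width(i.start, i.end, start, end)]
  tot <- sum(as.numeric(r$end - r$start + 1))
  out <- ov[, .(occupied_bp = sum(as.numeric(occ))), by = superfamily]
  out[, `:=`(compartment = label, percent = 100 * occupied_bp / tot)]
  out[, .(compartment, superfamily, occupied_bp, percent)]
}

#' TE orientation bias relative to nearby genes
#'
#' A TE is "forward" when its strand equals the strand of its nearest gene.
#' TEs whose midpoint falls in the stated window upstream of the TSS (or
#' downstream of the TES), strand-aware, are counted per superfamily and a
#' chi-square test (df = 1, no continuity correction) against 50:50 is
#' reported. In sliding mode, counts in 100-bp windows moved in 1-bp steps
#' across the region are emitted instead.
#'
#' @param te_annotations TE annotation table (strand required).
#' @param genes gene table (strand required).
#' @param window region size in bp (default 500).
#' @param side "upstream" (of the TSS) or "downstream" (of the TES).
#' @param sliding emit a per-offset series instead of a single table.
#' @param sliding_width width of the sliding window (default 100).
#' @return data.table: superfamily, forward, reverse, chisq, p_value (plus
#'   offset when sliding).
#' @export
orientation_bias <- function(te_annotations, genes, window = 500L,
                             side = c("upstream", "downstream"),
                             sliding = FALSE, sliding_width = 100L) {
  side <- match.arg(side)
  te <- data.table::as.data.table(te_annotations)
  g <- add_tss_tes(data.table::as.data.table(genes))
  te[, mid := interval_midpoint(start, end)]
  anchor_col <- if (side == "upstream") "tss" else "tes"
  ## nearest gene anchor per TE (same chromosome)
  res <- list()
  for (ch in unique(te$chrom)) {
    gi <- g[chrom == ch][order(get(anchor_col))]
    if (nrow(gi) == 0L) next
    anc <- gi[[anchor_col]]
    ti <- te[chrom == ch]
    j <- findInterval(ti$mid, anc)
    j_lo <- pmax(j, 1L); j_hi <- pmin(j + 1L, nrow(gi))
    d_lo <- abs(ti$mid - anc[j_lo]); d_hi <- abs(anc[j_hi] - ti$mid)
    pick <- ifelse(j < 1L, j_hi, ifelse(j >= nrow(gi), j_lo,
                                        ifelse(d_lo <= d_hi, j_lo, j_hi)))
    ti[, `:=`(anchor = anc[pick], gstrand = gi$strand[pick])]
    ## signed offset in gene orientation: positive = downstream of anchor
    ti[, offset := (mid - anchor) * ifelse(gstrand == "+", 1L, -1L)]
    ti[, forward := strand == gstrand]
    res[[ch]] <- ti
  }
  td <- data.table::rbindlist(res)
  if (nrow(td) == 0L) {
    return(data.table::data.table(superfamily = character(),
                                  forward = integer(), reverse = integer(),
                                  chisq = numeric(), p_value = numeric()))
  }
  in_region <- if (side == "upstream") {
    td$offset >= -window & td$offset <= -1L
  } else {
    td$offset >= 1L & td$offset <= window
  }
  td <- td[in_region]
  chi <- function(f, r) {
    n <- f + r
    ifelse(n == 0L, NA_real_, (f - r)^2 / n)
  }
  if (!sliding) {
    out <- td[, .(forward = sum(forward), reverse = sum(!forward)),
              by = superfamily]
    out[, chisq := chi(forward, reverse)]
    out[, p_value := ifelse(is.na(chisq), NA_real_,
                            stats::pchisq(chisq, df = 1, lower.tail = FALSE))]
    return(out[])
  }
  ## sliding mode: windows of sliding_width at 1-bp steps across the region
  offsets <- if (side == "upstream") seq.int(-window, -sliding_width)
             else seq.int(1L, window - sliding_width + 1L)
  out <- data.table::rbindlist(lapply(unique(td$superfamily), function(sf) {
    x <- td[superfamily == sf]
    rng <- range(c(x$offset, offsets, offsets + sliding_width - 1L))
    tabf <- tabulate(x[forward == TRUE, offset] - rng[1] + 1L,
                     nbins = rng[2] - rng[1] + 1L)
    tabr <- tabulate(x[forward == FALSE, offset] - rng[1] + 1L,
                     nbins = rng[2] - rng[1] + 1L)
    cf <- cumsum(tabf); cr <- cumsum(tabr)
    win_sum <- function(cs, lo, hi) {
      idx <- lo - rng[1]
      cs[hi - rng[1] + 1L] - ifelse(idx >= 1L, cs[pmax(idx, 1L)], 0)
    }
    f <- win_sum(cf, offsets, offsets + sliding_width - 1L)
    r <- win_sum(cr, offsets, offsets + sliding_width - 1L)
    data.table::data.table(superfamily = sf, offset = offsets,
                           forward = f, reverse = r)
  }))
  out[, chisq := chi(forward, reverse)]
  out[, p_value := ifelse(is.na(chisq), NA_real_,
                          stats::pchisq(chisq, df = 1, lower.tail = FALSE))]
  out[]
}
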