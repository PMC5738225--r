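## Windowed context-specific methylation levels, promoter TE classification,
## and TSS-anchored with/without-TE methylation ratio profiles.

#' Methylation levels in fixed non-overlapping windows
#'
#' Per window and context the level is #C / (#C + #T) pooled over the
#' window's sites (default), or the fraction of covered sites with
#' per-site ratio > 0.5 (`estimator = "site"`). No minimum-coverage filter
#' is applied by default; windows without covered sites of a context are
#' reported with level NA.
#'
#' @param calls methylation call table ([read_methylation_table()]).
#' @param window window size in bp (default 100, non-overlapping grid
#'   anchored at position 1).
#' @param estimator "pooled" or "site".
#' @param min_coverage optional per-site minimum total count (0 = keep all,
#'   the default).
#' @return data.table: chrom, start, end, context, level, covered_sites.
#' @export
window_methylation <- function(calls, window = 100L,
                               estimator = c("pooled", "site"),
                               min_coverage = 0L) {
  estimator <- match.arg(estimator)
  dt <- data.table::as.data.table(calls)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), context = character(),
                                  level = numeric(), covered_sites = integer()))
  }
  if (min_coverage > 0L) dt <- dt[total >= min_coverage]
  dt[, wstart := ((pos - 1L) %/% window) * window + 1L]
  if (estimator == "pooled") {
    out <- dt[, .(meth_sum = sum(meth), total_sum = sum(total),
                  covered_sites = sum(total > 0L)),
              by = .(chrom, wstart, context)]
    out[, level := ifelse(total_sum > 0L, meth_sum / total_sum, NA_real_)]
    out[, c("meth_sum", "total_sum") := NULL]
  } else {
    out <- dt[, .(level = {
      cov <- total > 0L
      if (any(cov)) mean(meth[cov] / total[cov] > 0.5) else NA_real_
    }, covered_sites = sum(total > 0L)),
    by = .(chrom, wstart, context)]
  }
  out[, `:=`(start = wstart, end = wstart + window - 1L, wstart = NULL)]
  data.table::setcolorder(out, c("chrom", "start", "end", "context", "level",
                                 "covered_sites"))
  data.table::setorder(out, chrom, start, context)
  out[]
}

#' Classify gene promoters by TE superfamily content
#'
#' The promoter is the strand-aware window from `upstream` bp before the TSS
#' to `downstream` bp after it (default -1500..+500, i.e. 2000 bp). Any bp
#' overlap of a TE annotation of a tracked superfamily sets that gene's
#' flag; genes can carry several flags. Genes with none of the tracked
#' superfamilies form the "no-TE" group.
#'
#' @param genes gene table with strand.
#' @param te_annotations TE annotation table.
#' @param upstream bp upstream of the TSS (default 1500).
#' @param downstream bp downstream of the TSS (default 500); the window
#'   covers TSS-upstream .. TSS+downstream-1 in gene orientation.
#' @param superfamilies tracked superfamilies (default Mariner, Harbinger,
#'   Helitron).
#' @return data.table: gene_id plus one logical `with_<superfamily>` column
#'   per tracked superfamily and a `no_te` flag.
#' @export
classify_promoters <- function(genes, te_annotations, upstream = 1500L,
                               downstream = 500L,
                               superfamilies = c("Mariner", "Harbinger",
                                                 "Helitron")) {
  g <- add_tss_tes(data.table::as.data.table(genes))
  te <- data.table::as.data.table(te_annotations)
  prom <- g[, .(gene_id, chrom,
                start = ifelse(strand == "+", tss - upstream,
                               tss - downstream + 1L),
                end = ifelse(strand == "+", tss + downstream - 1L,
                             tss + upstream))]
  out <- g[, .(gene_id)]
  te_sf <- te[superfamily %in% superfamilies,
              .(chrom, start, end, superfamily)]
  hit_genes <- if (nrow(te_sf) > 0L) {
    data.table::setkey(te_sf, chrom, start, end)
    ov <- data.table::foverlaps(prom, te_sf,
                                by.x = c("chrom", "start", "end"),
                                type = "any", nomatch = NULL)
    unique(ov[, .(gene_id, superfamily)])
  } else {
    data.table::data.table(gene_id = character(), superfamily = character())
  }
  for (sf in superfamilies) {
    col <- paste0("with_", sf)
    out[, (col) := gene_id %in% hit_genes[superfamily == sf, gene_id]]
  }
  out[, no_te := rowSums(as.matrix(.SD)) == 0L,
      .SDcols = paste0("with_", superfamilies)]
  rs_log("classify_promoters: %s; no-TE %d",
         paste(sprintf("%s %d", superfamilies,
                       colSums(as.matrix(out[, paste0("with_", superfamilies),
                                             with = FALSE]))),
               collapse = ", "),
         sum(out$no_te))
  out[]
}

#' TSS-anchored windowed methylation by promoter-TE group
#'
#' Maps 100-bp methylation windows into strand-oriented 1000-bp bins
#' spanning `span` around the TSS (12 bins at the defaults), averages window
#' levels per gene and bin, then averages genes within each group (each gene
#' weighted equally), and reports per-bin between-group ratios
#' (no-TE / with-TE and its inverse) for each tracked superfamily.
#'
#' @param genes gene table with strand.
#' @param windows [window_methylation()] output.
#' @param promoter_status [classify_promoters()] output.
#' @param span c(upstream, downstream) span around the TSS in bp
#'   (default c(-10000, 2000)).
#' @param bin bin size in bp (default 1000).
#' @param superfamilies tracked superfamilies to contrast against "no-TE".
#' @return object of class `methylation_ratio_profile`: list with `bins`
#'   (bin, bin_lo, bin_hi relative to TSS), `group_means` (bin, context,
#'   group, level, n_genes) and `ratios` (bin, context, superfamily,
#'   ratio_no_over_with, ratio_with_over_no).
#' @export
tss_anchored_methylation <- function(genes, windows, promoter_status,
                                     span = c(-10000L, 2000L), bin = 1000L,
                                     superfamilies = c("Mariner", "Harbinger",
                                                       "Helitron")) {
  g <- add_tss_tes(data.table::as.data.table(genes))
  w <- data.table::as.data.table(windows)
  n_bins <- (span[2] - span[1]) %/% bin
  ## windows whose midpoint falls into the oriented span of each gene
  w[, wmid := interval_midpoint(start, end)]
  region <- g[, .(gene_id, chrom, strand, tss,
                  start = ifelse(strand == "+", tss + span[1],
                                 tss - span[2] + 1L),
                  end = ifelse(strand == "+", tss + span[2] - 1L,
                               tss - span[1]))]
  wk <- w[, .(chrom, start = wmid, end = wmid, context, level)]
  data.table::setkey(wk, chrom, start, end)
  ov <- data.table::foverlaps(region, wk, by.x = c("chrom", "start", "end"),
                              type = "any", nomatch = NULL)
  ## i.* columns are the gene-region fields; start is the window midpoint
  ov[, offset := (start - tss) * ifelse(strand == "+", 1L, -1L)]
  ov <- ov[offset >= span[1] & offset < span[2]]
  ov[, bin_idx := ((offset - span[1]) %/% bin) + 1L]
  gene_bin <- ov[!is.na(level),
                 .(level = mean(level)), by = .(gene_id, bin_idx, context)]
  gene_bin <- merge(gene_bin, promoter_status, by = "gene_id")
  groups <- c(paste0("with_", superfamilies), "no_te")
  labels <- c(paste0("with-", superfamilies), "no-TE")
  gm <- data.table::rbindlist(lapply(seq_along(groups), function(i) {
    sel <- gene_bin[get(groups[i]) == TRUE]
    if (nrow(sel) == 0L) return(NULL)
    res <- sel[, .(level = mean(level), n_genes = .N), by = .(bin_idx, context)]
    cbind(group = labels[i], res)
  }))
  bins <- data.table::data.table(
    bin = seq_len(n_bins),
    bin_lo = span[1] + (seq_len(n_bins) - 1L) * bin,
    bin_hi = span[1] + seq_len(n_bins) * bin)
  ratios <- data.table::rbindlist(lapply(superfamilies, function(sf) {
    with_g <- gm[group == paste0("with-", sf),
                 .(bin_idx, context, with_level = level)]
    no_g <- gm[group == "no-TE", .(bin_idx, context, no_level = level)]
    m <- merge(with_g, no_g, by = c("bin_idx", "context"))
    if (nrow(m) == 0L) return(NULL)
    m[, `:=`(superfamily = sf,
             ratio_no_over_with = ifelse(with_level > 0,
                                         no_level / with_level, NA_real_),
             ratio_with_over_no = ifelse(no_level > 0,
                                         with_level / no_level, NA_real_))]
    m[, .(bin = bin_idx, context, superfamily, ratio_no_over_with,
          ratio_with_over_no)]
  }))
  structure(list(bins = bins,
                 group_means = gm[, .(bin = bin_idx, context, group, level,
                                      n_genes)],
                 ratios = ratios),
            class = "methylation_ratio_profile")
}

#' @export
print.methylation_ratio_profile <- function(x, ...) {
  cat(sprintf("methylation_ratio_profile: %d bins x %d group rows\n",
              nrow(x$bins), nrow(x$group_means)))
  invisible(x)
}
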