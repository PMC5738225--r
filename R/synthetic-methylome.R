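## Synthetic bisulfite methylome: every cytosine on both strands receives a
## context from its trinucleotide, a true methylation probability
## baseline x TSS-shape x promoter-TE factor, and observed counts drawn
## binomially at Poisson-sampled depth.

#' @keywords internal
.cytosine_sites <- function(seq_string) {
  ## plus-strand cytosines and minus-strand cytosines (G on plus), with
  ## context codes 1=CG 2=CHG 3=CHH; sites whose context bases are N (or
  ## chromosome-edge) are dropped. Integer byte codes keep this fast.
  v <- utf8ToInt(seq_string)
  n <- length(v)
  A <- 65L; C <- 67L; G <- 71L; T <- 84L; N <- 78L
  nxt1 <- c(v[-1L], N); nxt2 <- c(v[-(1:2)], N, N)
  prv1 <- c(N, v[-n]); prv2 <- c(N, N, v[-((n - 1L):n)])
  idx_p <- which(v == C)
  b1 <- nxt1[idx_p]; b2 <- nxt2[idx_p]
  h1 <- b1 == A | b1 == C | b1 == T
  h2 <- b2 == A | b2 == C | b2 == T
  ctx_p <- integer(length(idx_p))
  ctx_p[b1 == G] <- 1L
  ctx_p[h1 & b2 == G] <- 2L
  ctx_p[h1 & h2] <- 3L
  idx_m <- which(v == G)
  ## minus-strand trinucleotide reads pos, pos-1, pos-2 complemented;
  ## complements of H = {A,C,T} are {T,G,A}
  b1 <- prv1[idx_m]; b2 <- prv2[idx_m]
  h1 <- b1 == T | b1 == G | b1 == A
  h2 <- b2 == T | b2 == G | b2 == A
  ctx_m <- integer(length(idx_m))
  ctx_m[b1 == C] <- 1L
  ctx_m[h1 & b2 == C] <- 2L
  ctx_m[h1 & h2] <- 3L
  dt <- data.table::data.table(
    pos = c(idx_p, idx_m),
    strand = rep(c("+", "-"), c(length(idx_p), length(idx_m))),
    ctx = c(ctx_p, ctx_m))
  dt <- dt[ctx > 0L]
  data.table::setorder(dt, pos)
  dt
}

#' @keywords internal
.nearest_sorted <- function(sorted_vals, query) {
  ## index of the nearest value in sorted_vals for each query
  j <- findInterval(query, sorted_vals)
  j_lo <- pmax(j, 1L); j_hi <- pmin(j + 1L, length(sorted_vals))
  d_lo <- abs(query - sorted_vals[j_lo])
  d_hi <- abs(sorted_vals[j_hi] - query)
  ifelse(j < 1L, j_hi,
         ifelse(j >= length(sorted_vals), j_lo,
                ifelse(d_lo <= d_hi, j_lo, j_hi)))
}

#' Simulate per-cytosine bisulfite methylation calls
#'
#' @param assembly a [genome_assembly()].
#' @param genes gene table with strand (TSS shapes anchor on the nearest
#'   TSS).
#' @param promoter_status per-gene TE flags (from [simulate_genome()] or
#'   [classify_promoters()]); the designated superfamily's flag drives the
#'   promoter-TE effect.
#' @param spec a [methylome_spec()].
#' @param seed RNG seed.
#' @return methylation call table (chrom, pos, strand, context, meth, total).
#' @export
simulate_methylome <- function(assembly, genes, promoter_status,
                               spec = methylome_spec(), seed = 1L) {
  set.seed(seed)
  g <- data.table::as.data.table(genes)
  has_genes <- !is.null(g) && nrow(g) > 0L
  flag_col <- paste0("with_", spec$te_superfamily)
  if (has_genes && !is.null(promoter_status) &&
      flag_col %in% names(promoter_status)) {
    g <- merge(g, promoter_status[, c("gene_id", flag_col), with = FALSE],
               by = "gene_id")
    data.table::setnames(g, flag_col, "with_te")
  } else if (has_genes) {
    g[, with_te := FALSE]
  }
  out <- vector("list", length(assembly$lengths))
  names(out) <- names(assembly$lengths)
  ctx_labels <- c("CG", "CHG", "CHH")
  baseline <- spec$baseline[ctx_labels]
  for (ch in names(assembly$lengths)) {
    sites <- .cytosine_sites(as.character(assembly$seq[[ch]]))
    if (nrow(sites) == 0L) {
      out[[ch]] <- NULL
      next
    }
    p <- unname(baseline)[sites$ctx]
    if (has_genes && nrow(g[chrom == ch]) > 0L) {
      gi <- g[chrom == ch][order(tss)]
      k <- .nearest_sorted(gi$tss, sites$pos)
      sgn <- c(1L, -1L)[(gi$strand[k] == "-") + 1L]
      offset <- (sites$pos - gi$tss[k]) * sgn
      with_te <- gi$with_te[k]
      is_cg <- sites$ctx == 1L
      is_chg <- sites$ctx == 2L
      is_chh <- sites$ctx == 3L
      tau <- rep(spec$tau_down, length(offset))
      tau[offset < 0] <- spec$tau_up
      dipshape <- exp(-abs(offset) / tau)
      p[is_cg] <- p[is_cg] * (1 - spec$tss_dip_depth[["CG"]] * dipshape[is_cg])
      p[is_chg] <- p[is_chg] * (1 - spec$tss_dip_depth[["CHG"]] *
                                  dipshape[is_chg])
      mound <- 1 + spec$chh_mound *
        exp(-(offset - spec$chh_mound_center)^2 /
              (2 * spec$chh_mound_width^2))
      p[is_chh] <- p[is_chh] * mound[is_chh]
      in_win <- offset >= spec$te_window[1] & offset < spec$te_window[2] &
        with_te
      p[in_win & is_cg] <- p[in_win & is_cg] * spec$te_factor_cg
      p[in_win & is_chg] <- p[in_win & is_chg] * spec$te_factor_chg
      p[in_win & is_chh] <- p[in_win & is_chh] * spec$te_factor_chh
    }
    p <- pmin(pmax(p, 0), 1)
    depth <- rpois(nrow(sites), spec$depth_mean)
    meth <- rbinom(nrow(sites), depth, p)
    out[[ch]] <- data.table::data.table(
      chrom = ch, pos = sites$pos, strand = sites$strand,
      context = ctx_labels[sites$ctx], meth = meth, total = depth)
  }
  calls <- data.table::rbindlist(out)
  rs_log("simulate_methylome: %d call(s) across %d chromosome(s)",
         nrow(calls), length(assembly$lengths))
  calls[]
}
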