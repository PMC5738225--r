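## Synthetic TE library generation and the specification objects consumed by
## the genome/methylome simulators.

## IUPAC-ish degenerate codes accepted in target-site motifs. 'N' means
## "unconstrained": the background base is left untouched at that position.
.MOTIF_CODES <- list(A = "A", C = "C", G = "G", T = "T",
                     W = c("A", "T"), S = c("C", "G"), R = c("A", "G"),
                     Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"))

#' @keywords internal
.sample_motif <- function(motif) {
  ## returns a character vector with NA at unconstrained (N) positions
  chars <- strsplit(toupper(motif), "")[[1]]
  vapply(chars, function(ch) {
    if (ch == "N") return(NA_character_)
    opts <- .MOTIF_CODES[[ch]]
    if (is.null(opts)) stop("unsupported motif code '", ch, "'")
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
}

#' Placement specification for one synthetic TE family
#'
#' Describes how copies of a library family are planted: how many, in which
#' chromosomal niche (distal = density rising toward telomeres,
#' proximal = toward the centromere, interstitial = mid-arm,
#' uniform), with what target-site motif, truncation behaviour, strand bias
#' and gene association.
#'
#' @param family family name (must exist in the library used for simulation).
#' @param copy_number copies to plant (>= 0).
#' @param niche one of "uniform", "distal", "interstitial", "proximal".
#' @param niche_conc beta-shape concentration of the niche density (larger =
#'   sharper niche); the arm coordinate u (0 = centromere, 1 = telomere) is
#'   drawn from Beta(conc, 1) (distal), Beta(1, conc) (proximal),
#'   Beta(conc, conc) (interstitial) or Uniform.
#' @param motif_left,motif_right degenerate target-site motifs written into
#'   the flanks at the insertion point, in element orientation (<= 30 bp per
#'   side; N = unconstrained).
#' @param trunc_prob probability that a copy is truncated.
#' @param trunc_range fraction of the consensus removed when truncating.
#' @param strand_bias probability that a gene-associated copy matches its
#'   gene's strand (0.5 = no bias).
#' @param near_gene_prob fraction of copies placed relative to a gene TSS.
#' @param tss_gap_meanlog,tss_gap_sdlog log-normal parameters of the gap
#'   between a gene-associated copy and the TSS (defaults put the mode in
#'   the 1-2 kb band).
#' @param chrom_weights optional named per-chromosome density multipliers.
#' @param max_divergence per-copy substitution rate is Uniform(0, this).
#' @return a `family_spec` list.
#' @export
family_spec <- function(family, copy_number,
                        niche = c("uniform", "distal", "interstitial",
                                  "proximal"),
                        niche_conc = 3, motif_left = NULL, motif_right = NULL,
                        trunc_prob = 0, trunc_range = c(0.2, 0.8),
                        strand_bias = 0.5, near_gene_prob = 0,
                        tss_gap_meanlog = log(1400), tss_gap_sdlog = 0.45,
                        chrom_weights = NULL, max_divergence = 0.1) {
  niche <- match.arg(niche)
  if (copy_number < 0) stop("'copy_number' must be >= 0")
  for (m in list(motif_left, motif_right)) {
    if (!is.null(m) && nchar(m) > 30L) stop("motif window > 30 bp per side")
  }
  stopifnot(trunc_prob >= 0, trunc_prob <= 1,
            strand_bias >= 0, strand_bias <= 1,
            near_gene_prob >= 0, near_gene_prob <= 1,
            max_divergence >= 0, max_divergence < 1)
  structure(list(family = family, copy_number = as.integer(copy_number),
                 niche = niche, niche_conc = niche_conc,
                 motif_left = motif_left, motif_right = motif_right,
                 trunc_prob = trunc_prob, trunc_range = trunc_range,
                 strand_bias = strand_bias, near_gene_prob = near_gene_prob,
                 tss_gap_meanlog = tss_gap_meanlog,
                 tss_gap_sdlog = tss_gap_sdlog,
                 chrom_weights = chrom_weights,
                 max_divergence = max_divergence),
            class = "family_spec")
}

#' @keywords internal
.random_dna <- function(n, gc = 0.44) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' @keywords internal
.random_orf <- function(n_codons) {
  ## ATG + stop-free codons + TAA
  non_stop <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")), 1, paste,
                            collapse = ""),
                      c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(non_stop, n_codons - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

#' Generate a synthetic TE reference library
#'
#' Families get random consensus sequences (autonomous families carry an
#' embedded long ORF so [classify_autonomy()] behaves realistically) and
#' names with the requested three-letter superfamily codes. The module
#' verifies that no two families satisfy the 80/80 family rule against each
#' other and fails constructively otherwise.
#'
#' @param n_families number of families (>= 1).
#' @param lengths consensus lengths, recycled to `n_families`.
#' @param superfamily_codes three-letter codes, recycled.
#' @param autonomous logical, recycled; autonomous families need length
#'   >= 3 * min_orf_codons + 100.
#' @param seed RNG seed.
#' @param gc background GC content of the consensi.
#' @param min_orf_codons ORF size given to autonomous families.
#' @return a [te_library()].
#' @export
generate_te_library <- function(n_families, lengths = 5000L,
                                superfamily_codes = "RLX",
                                autonomous = FALSE, seed = 1L, gc = 0.44,
                                min_orf_codons = 300L) {
  if (n_families < 1L) stop("'n_families' must be >= 1")
  set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n_families)
  codes <- rep_len(superfamily_codes, n_families)
  autonomous <- rep_len(autonomous, n_families)
  if (any(lengths < 30L)) stop("family length < 30 bp not supported")
  ## constructive impossibility check: k mutually dissimilar sequences of
  ## length L need 4^L >> k; in practice only pathological requests fail
  if (n_families > 4^min(lengths) / 100) {
    stop(sprintf(paste0("cannot build %d mutually <80/80 families of ",
                        "length %d: alphabet too small"),
                 n_families, min(lengths)))
  }
  seqs <- character(n_families)
  for (i in seq_len(n_families)) {
    s <- .random_dna(lengths[i], gc)
    if (autonomous[i]) {
      orf <- .random_orf(min_orf_codons + 20L)
      if (nchar(orf) + 20L > lengths[i]) {
        stop(sprintf("family %d: length %d too short for an autonomous ORF",
                     i, lengths[i]))
      }
      at <- sample.int(lengths[i] - nchar(orf) - 1L, 1L)
      s[at:(at + nchar(orf) - 1L)] <- strsplit(orf, "")[[1]]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("%s_sim%02d", codes, seq_len(n_families))
  lib <- te_library(seqs, autonomous = autonomous)
  ## verify pairwise dissimilarity under the 80/80 rule
  if (n_families > 1L) {
    for (i in seq_len(n_families)) {
      sub <- te_library(seqs[-i], autonomous = autonomous[-i])
      fam <- assign_family_80_80(seqs[[i]], sub)
      if (fam != "unassigned") {
        stop(sprintf(paste0("generated families %s and %s violate the 80/80 ",
                            "dissimilarity requirement; use longer or fewer ",
                            "families or another seed"),
                     names(seqs)[i], fam))
      }
    }
  }
  lib
}

#' Methylome simulation parameters
#'
#' States the methylation landscape the simulator emulates: per-context
#' baselines far from genes, a CG/CHG dip centred on the TSS (exponential
#' shoulders, faster genic recovery downstream), a CHH mound just upstream
#' of the TSS, and multiplicative promoter-TE effects applied near the TSS
#' of genes whose promoter contains the designated superfamily.
#'
#' @param baseline named per-context methylation probabilities far from
#'   genes (levels in 0..1).
#' @param tss_dip_depth named dip depths for CG/CHG (0..1; level at the TSS
#'   is baseline * (1 - depth)).
#' @param tau_up,tau_down exponential decay lengths (bp) of the dip upstream
#'   / downstream of the TSS.
#' @param chh_mound mound amplitude (multiplier - 1) for CHH.
#' @param chh_mound_center,chh_mound_width Gaussian centre/width (bp,
#'   TSS-relative) of the CHH mound.
#' @param te_superfamily designated superfamily whose promoter presence
#'   modulates methylation.
#' @param te_factor_cg,te_factor_chg,te_factor_chh multiplicative effects
#'   (> 0) applied inside `te_window` for genes carrying the element.
#' @param te_window TSS-relative window (gene orientation) where the effect
#'   acts; default the promoter, -1500..+500.
#' @param depth_mean mean sequencing depth (Poisson).
#' @return a `methylome_spec` list.
#' @export
methylome_spec <- function(baseline = c(CG = 0.85, CHG = 0.65, CHH = 0.05),
                           tss_dip_depth = c(CG = 0.8, CHG = 0.7),
                           tau_up = 1500, tau_down = 600,
                           chh_mound = 1.0, chh_mound_center = -400,
                           chh_mound_width = 400,
                           te_superfamily = "Mariner",
                           te_factor_cg = 0.5, te_factor_chg = 0.5,
                           te_factor_chh = 2.0,
                           te_window = c(-1500, 500), depth_mean = 20) {
  stopifnot(all(baseline >= 0 & baseline <= 1),
            all(tss_dip_depth >= 0 & tss_dip_depth <= 1),
            te_factor_cg > 0, te_factor_chg > 0, te_factor_chh > 0,
            depth_mean >= 0)
  structure(list(baseline = baseline, tss_dip_depth = tss_dip_depth,
                 tau_up = tau_up, tau_down = tau_down,
                 chh_mound = chh_mound, chh_mound_center = chh_mound_center,
                 chh_mound_width = chh_mound_width,
                 te_superfamily = te_superfamily,
                 te_factor_cg = te_factor_cg, te_factor_chg = te_factor_chg,
                 te_factor_chh = te_factor_chh, te_window = te_window,
                 depth_mean = depth_mean),
            class = "methylome_spec")
}
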