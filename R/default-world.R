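## The package's reference synthetic world: a 3 x 20 Mb genome with ~2000
## clustered genes and ten TE families whose sizes, copy numbers, niches and
## target-site motifs echo the landscape of a large TE-dominated cereal
## genome (high-copy LTR retrotransposon families of ~5-9 kb with distinct
## distal/interstitial/proximal niches, a strongly distal CACTA family, tiny
## gene-associated Mariner/Harbinger elements with A/T-rich target motifs, a
## Helitron with an asymmetric target, a uniform background family and a
## gene-associated LINE with forward orientation bias). `scale` shrinks the
## world proportionally (lengths, gene count and copy numbers) for quick
## tests without touching densities or effect sizes.

#' Default synthetic TE library (ten families)
#'
#' @param seed RNG seed.
#' @return a [te_library()].
#' @export
default_te_library <- function(seed = 1L) {
  generate_te_library(
    n_families = 10L,
    lengths = c(8000L, 8600L, 7000L, 5000L, 6000L, 200L, 300L, 1500L,
                1500L, 3000L),
    superfamily_codes = c("RLG", "RLC", "RLG", "RLC", "DTC", "DTT", "DTH",
                          "DHH", "RLX", "RIX"),
    autonomous = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, TRUE),
    seed = seed)
}

#' Default family placement specifications
#'
#' @param scale copy-number scale factor (1 = the reference world).
#' @param chromosomes chromosome names (for the per-chromosome bias of the
#'   third family, denser on the first chromosome).
#' @return list of [family_spec()]s.
#' @export
default_family_specs <- function(scale = 1, chromosomes = paste0("chr", 1:3)) {
  n <- function(x) as.integer(round(x * scale))
  bias <- setNames(c(4, rep(1, length(chromosomes) - 1L)), chromosomes)
  list(
    family_spec("RLG_sim01", n(600), niche = "interstitial", niche_conc = 4,
                trunc_prob = 0.35),
    family_spec("RLC_sim02", n(500), niche = "distal", niche_conc = 4,
                trunc_prob = 0.35),
    family_spec("RLG_sim03", n(350), niche = "proximal", niche_conc = 4,
                trunc_prob = 0.35, chrom_weights = bias),
    family_spec("RLC_sim04", n(250), niche = "proximal", niche_conc = 3,
                trunc_prob = 0.3),
    family_spec("DTC_sim05", n(350), niche = "distal", niche_conc = 6,
                trunc_prob = 0.2),
    family_spec("DTT_sim06", n(800), niche = "uniform", near_gene_prob = 0.7,
                motif_left = "WWNNT", motif_right = "ANNWW",
                trunc_prob = 0.05),
    family_spec("DTH_sim07", n(400), niche = "uniform", near_gene_prob = 0.6,
                motif_left = "TAA", motif_right = "TAA", trunc_prob = 0.05),
    family_spec("DHH_sim08", n(200), niche = "uniform", near_gene_prob = 0.4,
                motif_left = "A", motif_right = "TNNNNNNNAAA",
                trunc_prob = 0.1),
    family_spec("RLX_sim09", n(1500), niche = "uniform", trunc_prob = 0.15),
    family_spec("RIX_sim10", n(300), niche = "uniform", near_gene_prob = 0.5,
                strand_bias = 0.75, trunc_prob = 0.3)
  )
}

#' Simulate the package's reference world
#'
#' @param seed RNG seed.
#' @param scale proportional scale of the world (1 = 3 x 20 Mb, ~2000
#'   genes, ~5000 TE copies).
#' @param chromosome_lengths override the chromosome layout.
#' @param with_methylome also simulate methylation calls.
#' @param meth_spec [methylome_spec()] used when `with_methylome`.
#' @return a [simulate_genome()] result list, plus `library`, `specs` and
#'   (optionally) `calls`.
#' @export
simulate_world <- function(seed = 1L, scale = 1,
                           chromosome_lengths = NULL,
                           with_methylome = FALSE,
                           meth_spec = methylome_spec()) {
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- setNames(rep(as.integer(round(20e6 * scale)), 3L),
                                   paste0("chr", 1:3))
  }
  lib <- default_te_library(seed = seed)
  specs <- default_family_specs(scale = scale,
                                chromosomes = names(chromosome_lengths))
  world <- simulate_genome(
    chromosome_lengths, lib, specs,
    genes_spec = gene_spec(n_genes = as.integer(round(2000 * scale))),
    seed = seed)
  world$library <- lib
  world$specs <- specs
  if (with_methylome) {
    world$calls <- simulate_methylome(world$assembly, world$genes,
                                      world$promoter_status, meth_spec,
                                      seed = seed + 1L)
  }
  world
}
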