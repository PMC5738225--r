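# repeatscape

Repetitive-landscape analysis for large, TE-dominated plant genomes.

In genomes like those of barley or wheat, transposable elements (TEs) make up
80% or more of the DNA, and a handful of high-copy LTR retrotransposon
families dominate the sequence. `repeatscape` re-implements, as a tested R
package, the analysis pipeline used to characterise such a landscape:

* **Segment-based TE annotation.** Chromosomes are split into 180 bp
  segments which are searched against a reference TE library (built-in
  seed-and-extend aligner, or an adapter for external tabular hits). Segment
  hits are combined with explicit rules: overlapping/adjacent same-family,
  same-orientation hits are unioned; gaps of *fewer than 100 bp* between
  them are bridged (unless a hit of another family intervenes); annotations
  within 80 bp of an assembly N-gap are extended to the gap edge. Copies
  whose alignments reach both consensus termini (within a 20 bp tolerance)
  are flagged *complete*.
* **Copy numbers and niches.** Copy number is estimated as
  `round(total annotated bp / consensus length)`; occupied kb is binned
  along chromosomes (20–40 Mb bins at chromosome scale), arm-terminal
  enrichment uses the distal 20% of each arm, and per-chromosome abundance
  ratios expose families that prefer particular chromosomes.
* **Gene space.** Genes separated by less than 20 kb form clusters
  (single-linkage); a randomization null re-places the observed gene lengths
  uniformly without overlap. TE-to-gene distances (midpoint or edge),
  island-vs-intergenic (≥ 200 kb gene-free) composition, and TE orientation
  bias relative to genes (χ², df = 1, no continuity correction).
* **Positional profiles.** TSS/TES-anchored frequency matrices sampled at
  every 20th base over 10 kb flanks (500 offsets per side, longest covering
  hit wins), Gypsy:Copia ratio curves, and target-site nucleotide
  composition from the 30 bp flanking complete copies, with degenerate
  motif calling (e.g. the Mariner-style `[T/A][T/A]nnT-Ann[T/A][T/A]`).
* **Methylation.** Windowed `#C/(#C+#T)` levels per context (CG/CHG/CHH) in
  100 bp non-overlapping windows, no coverage filter by default; promoter
  classification (TE overlap with TSS−1500..+500); TSS-anchored 1 kb-bin
  profiles (−10 kb..+2 kb) and with/without-TE group ratios.
* **Synthetic data.** A generator that plants genes (in clusters), TE
  copies (with niches, target-site motifs, truncation, divergence, strand
  bias) and a methylome (TSS dips, CHH mounds, promoter-TE effects) with
  full ground truth, so every stage is testable offline.

Family names follow the three-letter superfamily code convention
(`RLC`/`RLG`/`RLX` Copia/Gypsy/unknown LTR, `RIX` LINE, `RSX` SINE, `DTC`
CACTA, `DTT` Mariner, `DTH` Harbinger, `DHH` Helitron). Two copies belong to
one family when they are >80% identical over >80% of their length (the
"80/80 rule"). All in-memory coordinates are 1-based inclusive.

## Worked example

```r
library(repeatscape)
w <- simulate_world(seed = 1, scale = 0.05)      # 3 x 1 Mb mini-world
w$assembly
#> genome_assembly: 3 chromosome(s), 3.000 Mb, 6 assembly gap(s)

res <- annotate_genome(w$assembly, w$library)
copy_number_table(res$annotations, w$library)[1:5]
#>       family superfamily total_kb consensus_length copy_number
#> 1: RLG_sim01       Gypsy  190.571             8000          24
#> 2: RLC_sim02       Copia  173.853             8600          20
#> 3: RLG_sim03       Gypsy  115.790             7000          17
#> 4: RLX_sim09 LTR_unknown  103.787             1500          69
#> 5: DTC_sim05       CACTA   90.735             6000          15

terminal_arm_enrichment(res$annotations, w$centromeres,
                        w$assembly$lengths)[family == "DTC_sim05"]
#>       family n_copies n_terminal terminal_fraction
#> 1: DTC_sim05       19         12         0.6315789
```

The copy-number column is `round(total bp / consensus length)`: the
distal-niche CACTA family (`DTC_sim05`) puts ~63% of its copies into the
terminal 20% of chromosome arms even in this tiny world. On the published
barley numbers the same estimator gives, e.g.,
`estimate_copy_number(623043000, 8630)` → `72195` copies for the most
abundant Copia family.

## Command line

```sh
repeatscape simulate   --config sim.cfg --out simdir --seed 4
repeatscape annotate   --config ann.cfg --out anndir
repeatscape landscape  --config ls.cfg  --out lsdir
```

Configs are flat `key = value` files; see `?repeatscape_cli` for each
subcommand's keys and outputs (TSV/GFF3/FASTA).

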