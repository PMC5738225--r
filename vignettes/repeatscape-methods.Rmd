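---
title: "repeatscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{repeatscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each stage
computes, the assumptions behind it, the tunable parameters with their
defaults and units, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates

All in-memory intervals are **1-based and inclusive**, the
Bioconductor/Biostrings convention. GFF3 (1-based inclusive on disk) is
read and written unshifted; BED is converted from 0-based half-open. A
design alternative was 0-based half-open internally; we chose the
convention of the ecosystem the package lives in, and translated every gap
rule accordingly: the gap between two intervals is the number of
*intervening bases*, `next.start - prev.end - 1`.

## Segment-based TE annotation

The genome is tiled into consecutive, non-overlapping segments
(`segment_length = 180` bp, final partial segment kept) and each segment is
searched against the TE library. The built-in backend is a seed-and-extend
local aligner (compiled): exact k-mer seeds (`k = 11`) are extended
ungapped in both directions with an x-drop criterion (`xdrop = 15`, match
+1 / mismatch −1), and a hit is reported when it reaches
`min_identity = 80`% over `min_hit_length = 50` bp. The ungapped model is
adequate for substitution-level divergence, which is what both the
synthetic worlds and the 80/80 family definition are about; for indel-rich
homology an external aligner's tabular output can be supplied through
`read_external_hits()` (BLAST `-outfmt 6` shape). The built-in aligner is
checked in the tests against an independent quadratic local-alignment
oracle (`Biostrings::pairwiseAlignment`): same top family, identity within
~1 point.

Segment hits become annotations via three rules, applied to a fixpoint:

1. **Union**: overlapping or adjacent hits of the same family and
   orientation are merged.
2. **Bridge**: a gap of *fewer than 100* intervening bases
   (`bridge_gap = 100`, strict) between same-family, same-orientation hits
   is closed — unless a hit of a different family (or the opposite strand)
   overlaps the gap. The paper-gap here was whether bridging may cross a
   third family's hit; we decided it may not, to avoid swallowing nested
   elements, and likewise do not bridge across opposite-strand fragments.
3. **N-gap extension**: an annotation separated from an assembly N-gap by
   fewer than `gap_extend = 80` bases is extended to the gap edge.

Rules 2 and 3 interact (an extension can pull two annotations within
bridging distance), so `merge_and_bridge()` iterates until nothing changes;
this is what makes the operation idempotent, and the test suite checks
equivalence against a brute-force pairwise fixpoint oracle on random hit
sets.

Completeness (`detect_full_length()`): a copy is 5′-intact when its
supporting alignments reach within `end_tolerance = 20` bp of consensus
position 1, and 3′-intact at the consensus length; hits carry
forward-consensus coordinates for both strands, so the test needs no
strand special-casing. Because hits shorter than `min_hit_length` at copy
boundaries are dropped, boundary error of up to one segment length is
expected and the recovery criteria use ±180 bp.

Family assignment uses the 80/80 rule: >80% identity over >80% of the
shorter of copy and consensus, strict on both thresholds, ties broken by
identity then name. The backend finds the best-supported diagonal from
k-mer votes and scores the maximal run exactly — again a
substitution-model simplification, documented as such.

`build_consensus()` delegates the multiple alignment to `mafft` (any
aligner of equivalent quality would do; the consensus logic is our own):
at least 3 and at most 100 copies (the longest ones), gap-majority columns
dropped, per-column majority base, ties resolved by alignment-wide
nucleotide frequency then alphabetically. `classify_autonomy()` calls a
family autonomous when any of the six reading frames contains an
ATG-initiated, stop-free run of at least `min_orf_codons = 300` codons.

## Landscape statistics

Copy number is `round(total annotated bp / consensus length)`, rounded
half away from zero — the convention that reproduces all ten printed
high-copy reference rows exactly (the bundled
`inst/extdata/te_copy_number_reference.tsv`). Known ±1–4 discrepancies in
the small-element blocks of the published table stem from its internally
unrounded totals; the package recomputes from its own unrounded totals and
the acceptance targets for those blocks therefore sum the *printed* column
(column arithmetic) rather than re-deriving each row.

Two conventions are used deliberately and labelled: statistics that count
copies (bin counts, arm membership) use the copy **midpoint**
(`floor((start+end)/2)`); statistics that report occupied kb apportion
annotation bp to bins **by overlap**, so an annotation straddling a bin
edge contributes proportionally and per-family bin sums conserve the
family total. Bin size defaults to 30 Mb — meaningful for ~0.5 Gb
chromosomes; synthetic tests use 1 Mb bins. Arm-terminal enrichment uses
the distal `terminal_fraction = 0.2` of each arm, arms defined by a
per-chromosome centromere coordinate (the simulator emits one; real use
requires it as input).

## Gene space

Clustering is single-linkage chaining with a strict edge-to-edge gap
threshold (`max_gap = 20000` bp): a 19,998-base gap joins, a 20,000-base
gap separates. "Separated by" was read as edge-to-edge, not
midpoint-to-midpoint (midpoint mode is available in
`te_gene_distance()`). The randomization null re-places the *observed*
gene lengths uniformly at random without overlap (rejection sampling) and
re-runs the clustering; its mean is validated against exact enumeration of
the sequential placement process on a discretised toy genome. The
empirical p-value is `(1 + #{null ≥ observed}) / (n_reps + 1)`.

Orientation bias counts a TE as *forward* when its strand equals its
nearest gene's strand, within a strand-aware window upstream of the TSS or
downstream of the TES, and tests forward:reverse against 50:50 with a
χ² (df = 1) without continuity correction — counts in the intended use are
large; a sliding mode emits 100 bp windows at 1 bp steps. Intergenic
regions are gene-free stretches ≥ 200 kb (`min_intergenic`); gene islands
are cluster spans ± `island_flank = 5000` bp, and island flanks are
excluded from intergenic area so the compartments do not overlap.

## Positional profiles and target sites

TSS/TES-anchored profiles sample every `step = 20` bp over
`flank = 10000` bp (500 offsets per side; offset 0, the anchor base, is
excluded as it lies in the gene). At a sampled position the covering hit
with the **longest alignment** wins (ties: identity, then name) — the
hit-level reading of "longest hit", not the longest merged annotation.
Minus-strand genes are reflected so upstream is biologically upstream;
positions beyond a chromosome end leave that gene out of the offset's
denominator. Profile invariance under chromosome renaming, coordinate
translation and whole-world reverse complement is property-tested.

Target-site matrices collect the 30 bp flanking *complete* copies on both
sides, in the element's orientation (minus-strand copies are
reverse-complemented; this fixes the axis convention, which was open).
`consensus_motif()` renders per position a single letter at fraction ≥
`majority_threshold = 0.8`, a two-letter class like `[T/A]` when the best
pair reaches the threshold (letters by decreasing frequency; exact ties
alphabetical), else `n`, with `-` marking the insertion point.

## Methylation

Window levels implement `#C/(#C+#T)` per context in 100 bp
non-overlapping windows with **no coverage filter by default**. The source
description admits two estimators — pooled read counts versus binarised
sites; the default is pooled (`Σ#C / Σ(#C+#T)`), with
`estimator = "site"` (site methylated iff its ratio > 0.5) available. The
promoter is TSS−1500..+500 in gene orientation; any bp overlap of a
tracked superfamily (Mariner, Harbinger, Helitron) sets the gene's flag,
and "no-TE" means none of the three. TSS-anchored profiles map window
midpoints into twelve strand-oriented 1000 bp bins spanning −10 kb..+2 kb
(bins are oriented for minus-strand genes — a choice the source leaves
open), average windows within a gene first and then genes within a group
(each gene weighted equally), and emit both ratio directions per bin,
context and superfamily.

## The synthetic world

The generator's defaults state the world the tests assume; they are not
tuned per test. Reference scale: 3 chromosomes × 20 Mb, centromeres at
0.5 of each chromosome, i.i.d. background at GC 0.44, ~2000 two-exon-style
genes in clusters (cluster-size distribution putting ~60% of genes in
clusters ≥ 2; gene GC 0.50 with +0.10 in the first 1.5 kb downstream of
the TSS), two planted 200–800 bp N-gaps per chromosome, and ten TE
families (~5000 copies, ~30% of the genome) echoing a TE-dominated cereal
landscape: interstitial/distal/proximal LTR families of 5–8.6 kb, a
strongly distal CACTA, tiny gene-associated Mariner (target motif
`WWNNT-ANNWW`) and Harbinger (`TAA-TAA`) elements, a Helitron with an
asymmetric `A-TnnnnnnnAAA` target, a uniform background family and a
gene-associated LINE with 0.75 forward-strand bias. Copies get a
per-copy substitution rate Uniform(0, 0.1), truncation with
family-specific probability, and a log-normal TSS-gap distribution with
mode in the 1–2 kb band for gene-associated families.

Placement samples a niche position (arm coordinate from Beta
distributions: Beta(c,1) distal, Beta(1,c) proximal, Beta(c,c)
interstitial) and rejects overlaps. The stated alternative — shifting to
the nearest motif match — is replaced by writing the sampled motif into
the flanks at the chosen site: on an i.i.d. background the two are
statistically equivalent, and planting makes the "100% of non-fallback
copies carry the motif" property hold by construction; copies whose flanks
are already occupied are flagged as fallback.

The methylome applies, per cytosine (both strands, context from the
trinucleotide): baseline levels (CG 0.85, CHG 0.65, CHH 0.05), an
exponential TSS dip for CG/CHG (depths 0.8/0.7, decay 1500 bp upstream and
600 bp downstream — the faster downstream recovery mimics genic CG
recovery), a Gaussian CHH mound centred 400 bp upstream (amplitude 1.0,
width 400 bp), and multiplicative promoter-TE effects inside
TSS−1500..+500 for genes whose promoter contains the designated
superfamily (defaults: Mariner; CG/CHG × 0.5, CHH × 2.0). Depth is
Poisson(20), observed counts Binomial(depth, p). These shapes are the
package's own quantitative stand-ins for qualitative published patterns —
the source figures are heatmaps and relative curves with no functional
form — and they are labelled as such.

**What a green test establishes — and what it does not.** The synthetic
world has no nested insertions by default, no indels within copies, no
subfamily structure, no solo-LTR recombination products and no sequencing
bias in the methylome. Green recovery tests therefore establish that the
implementation of the stated rules is correct and self-consistent, not
that the pipeline would reproduce the published genome-scale numbers (80%
TE fraction, 36% of Mariner within 5 kb of genes, Gypsy:Copia 1.3, 60%/30%
observed/null clustered fractions): those require the actual ~5 Gb
assembly, and the package emits exactly the statistics needed so that a
full-scale run could compute them.

One measured interaction worth knowing: in the crowded reference world the
uniform family's arm-terminal fraction drops below 0.2 (~0.17), because
rejection against the distal families' occupancy deforms the free space.
The uniformity acceptance checks therefore run in a dedicated
low-occupancy world (2 × 10 Mb, ~16% occupied), where the placement
sampler's own properties are what is being measured.

## Numerical choices

* Rounding of copy numbers: half away from zero (`trunc(x + 0.5·sign(x))`).
* Strict inequalities: bridge (< 100), N-gap extension (< 80), clustering
  (< 20 kb), 80/80 thresholds (> 80).
* Ties: longest hit → identity → family name (profiles, locus
  competition); majority base → global frequency → alphabet (consensus);
  bracket classes by frequency, exact ties alphabetical (motifs).
* Empirical p-values use the +1 convention; χ² without Yates correction.
* Missing values are reported as NA (never ∞): zero-Copia offsets,
  families without copies, chromosomes without genes, windows without
  covered sites.
* Degenerate inputs: empty assemblies/tables produce empty results; < 3
  consensus copies, centromeres out of bounds, invalid contexts and
  `meth > total` rows are errors.

## Known limitations

Homology-based annotation only (no structural LTR/TSD detection); ungapped
built-in alignment; no protein-domain evidence in autonomy calls (ORF
length only); descriptive niche statistics (no between-family tests);
methylation module starts at the per-cytosine call table (no read
processing).
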