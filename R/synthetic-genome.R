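## Synthetic genome simulator: i.i.d. background, clustered two-exon genes
## with elevated GC downstream of the TSS, assembly N-gaps, and TE copies
## planted by niche/gene-association with family-specific target-site
## motifs, truncation and divergence. Every planted feature is recorded in
## a ground-truth table.

#' Gene placement parameters for the genome simulator
#'
#' @param n_genes total genes to place (split across chromosomes by length).
#' @param cluster_size_probs probabilities of cluster sizes 1..k; the
#'   default puts ~60\% of genes in clusters of >= 2, matching the gene-space
#'   structure the analyses assume.
#' @param length_meanlog,length_sdlog,length_range log-normal gene length
#'   model (bp).
#' @param intra_gap_range uniform range of intra-cluster gene gaps (bp;
#'   must stay below the 20 kb clustering threshold).
#' @param cluster_margin reserved gene-free margin around clusters (bp) so
#'   separate clusters never chain together.
#' @param gc_genic GC content of gene bodies.
#' @param gc_tss_boost extra GC in the first 1.5 kb downstream of the TSS.
#' @return a `gene_spec` list.
#' @export
gene_spec <- function(n_genes = 2000L,
                      cluster_size_probs = c(0.65, 0.15, 0.08, 0.05, 0.03,
                                             0.02, 0.02),
                      length_meanlog = log(2800), length_sdlog = 0.35,
                      length_range = c(1200L, 8000L),
                      intra_gap_range = c(500L, 15000L),
                      cluster_margin = 20000L,
                      gc_genic = 0.5, gc_tss_boost = 0.1) {
  stopifnot(n_genes >= 0, all(cluster_size_probs >= 0),
            intra_gap_range[2] < 20000L + 1L)
  structure(list(n_genes = as.integer(n_genes),
                 cluster_size_probs = cluster_size_probs /
                   sum(cluster_size_probs),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 length_range = as.integer(length_range),
                 intra_gap_range = as.integer(intra_gap_range),
                 cluster_margin = as.integer(cluster_margin),
                 gc_genic = gc_genic, gc_tss_boost = gc_tss_boost),
            class = "gene_spec")
}

## Sorted-interval occupancy tracker (per chromosome).
#' @keywords internal
.new_tracker <- function() {
  env <- new.env(parent = emptyenv())
  env$starts <- integer(0)
  env$ends <- integer(0)
  env
}

#' @keywords internal
.tracker_free <- function(tr, s, e) {
  j <- findInterval(e, tr$starts)
  j < 1L || tr$ends[j] < s
}

#' @keywords internal
.tracker_claim <- function(tr, s, e) {
  if (!.tracker_free(tr, s, e)) return(FALSE)
  j <- findInterval(e, tr$starts)
  tr$starts <- append(tr$starts, as.integer(s), after = j)
  tr$ends <- append(tr$ends, as.integer(e), after = j)
  TRUE
}

#' @keywords internal
.mutate_seq <- function(chars, rate) {
  n <- length(chars)
  nmut <- rbinom(1L, n, rate)
  if (nmut == 0L) return(chars)
  at <- sample.int(n, nmut)
  alt <- vapply(chars[at], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1), USE.NAMES = FALSE)
  chars[at] <- alt
  chars
}

#' @keywords internal
.niche_position <- function(niche, conc, cen, L) {
  u <- switch(niche,
              uniform = runif(1),
              distal = rbeta(1, conc, 1),
              proximal = rbeta(1, 1, conc),
              interstitial = rbeta(1, conc, conc))
  if (niche == "uniform") return(1L + floor(u * (L - 1)))
  ## arm picked proportional to its length; u = 0 centromere, 1 telomere
  left <- runif(1) < cen / L
  if (left) as.integer(round(cen - u * (cen - 1))) else
    as.integer(round(cen + u * (L - cen)))
}

#' Simulate a genome with planted genes and TE copies
#'
#' See the package vignette for the model. Returns the assembly together
#' with a full ground-truth table of planted TE copies (exact boundaries,
#' intactness, divergence, placement route, motif status) and the gene
#' models.
#'
#' @param chromosome_lengths named integer vector.
#' @param library a [te_library()].
#' @param family_specs list of [family_spec()]s (families must exist in the
#'   library).
#' @param genes_spec a [gene_spec()].
#' @param seed RNG seed; output is bit-for-bit reproducible.
#' @param gc background GC content (default 0.44).
#' @param centromere_frac centromere position as a fraction of chromosome
#'   length.
#' @param n_assembly_gaps N-gaps planted per chromosome.
#' @param assembly_gap_range N-gap length range (bp).
#' @return list with `assembly` ([genome_assembly()]), `genes` (gene table),
#'   `truth` (planted TE table), `centromeres` (named vector),
#'   `promoter_status` (per-gene TE-in-promoter flags from the truth set).
#' @export
simulate_genome <- function(chromosome_lengths, library, family_specs,
                            genes_spec = gene_spec(), seed = 1L, gc = 0.44,
                            centromere_frac = 0.5, n_assembly_gaps = 2L,
                            assembly_gap_range = c(200L, 800L)) {
  set.seed(seed)
  chs <- names(chromosome_lengths)
  if (is.null(chs)) stop("'chromosome_lengths' must be named")
  spec_fams <- vapply(family_specs, `[[`, character(1), "family")
  if (!all(spec_fams %in% library$entries$family)) {
    stop("family_specs name families absent from the library: ",
         paste(setdiff(spec_fams, library$entries$family), collapse = ", "))
  }
  te_bp <- sum(vapply(family_specs, function(fs) {
    fs$copy_number * library_lengths(library)[fs$family]
  }, numeric(1)))
  gene_bp <- genes_spec$n_genes * exp(genes_spec$length_meanlog)
  if (te_bp + gene_bp > 0.8 * sum(chromosome_lengths)) {
    stop("requested TE + gene bp exceed 80% of the genome; reduce copy numbers")
  }
  centromeres <- setNames(as.integer(round(chromosome_lengths *
                                             centromere_frac)), chs)
  base <- lapply(chs, function(ch) .random_dna(chromosome_lengths[[ch]], gc))
  names(base) <- chs
  occ <- lapply(chs, function(ch) .new_tracker())   # all features
  names(occ) <- chs
  gene_excl <- lapply(chs, function(ch) .new_tracker())  # clusters + margins
  names(gene_excl) <- chs

  ## ---- assembly N-gaps -------------------------------------------------
  gap_rows <- list()
  for (ch in chs) {
    L <- chromosome_lengths[[ch]]
    for (i in seq_len(n_assembly_gaps)) {
      glen <- sample(assembly_gap_range[1]:assembly_gap_range[2], 1L)
      for (try in 1:50) {
        s <- sample.int(L - glen, 1L)
        if (.tracker_claim(occ[[ch]], s, s + glen - 1L)) {
          base[[ch]][s:(s + glen - 1L)] <- "N"
          gap_rows[[length(gap_rows) + 1L]] <-
            data.table::data.table(chrom = ch, start = s, end = s + glen - 1L)
          break
        }
      }
    }
  }

  ## ---- genes in clusters ----------------------------------------------
  gs <- genes_spec
  n_per_chr <- round(gs$n_genes * as.numeric(chromosome_lengths) /
                       sum(as.numeric(chromosome_lengths)))
  names(n_per_chr) <- chs
  gene_rows <- list()
  gid <- 0L
  for (ch in chs) {
    L <- chromosome_lengths[[ch]]
    placed <- 0L
    while (placed < n_per_chr[[ch]]) {
      k <- sample(seq_along(gs$cluster_size_probs), 1L,
                  prob = gs$cluster_size_probs)
      k <- min(k, n_per_chr[[ch]] - placed)
      lens <- pmin(pmax(as.integer(round(rlnorm(k, gs$length_meanlog,
                                                gs$length_sdlog))),
                        gs$length_range[1]), gs$length_range[2])
      gaps <- if (k > 1L) sample(gs$intra_gap_range[1]:gs$intra_gap_range[2],
                                 k - 1L, replace = TRUE) else integer(0)
      span <- sum(lens) + sum(gaps)
      ok <- FALSE
      for (try in 1:200) {
        a <- sample.int(max(L - span - 1L, 1L), 1L)
        m <- gs$cluster_margin
        ## claims already carry the margin, so testing the bare span keeps
        ## cluster spans >= margin apart without double-counting it
        if (!.tracker_free(gene_excl[[ch]], a, a + span - 1L)) next
        if (!.tracker_free(occ[[ch]], a, a + span - 1L)) next
        .tracker_claim(gene_excl[[ch]], max(1L, a - m), min(L, a + span + m))
        ok <- TRUE
        break
      }
      if (!ok) break  # chromosome too crowded; stop adding clusters
      cur <- a
      for (j in seq_len(k)) {
        s <- cur; e <- cur + lens[j] - 1L
        .tracker_claim(occ[[ch]], s, e)
        strand <- sample(c("+", "-"), 1L)
        gseq <- .random_dna(lens[j], gs$gc_genic)
        boost_len <- min(1500L, lens[j])
        boost <- .random_dna(boost_len, gs$gc_genic + gs$gc_tss_boost)
        if (strand == "+") gseq[seq_len(boost_len)] <- boost
        else gseq[(lens[j] - boost_len + 1L):lens[j]] <- boost
        base[[ch]][s:e] <- gseq
        gid <- gid + 1L
        gene_rows[[gid]] <- data.table::data.table(
          gene_id = sprintf("g%05d", gid), chrom = ch, start = s, end = e,
          strand = strand, confidence = "HC1")
        cur <- e + 1L + if (j < k) gaps[j] else 0L
      }
      placed <- placed + k
    }
  }
  genes <- data.table::rbindlist(gene_rows)
  if (nrow(genes) > 0L) genes <- add_tss_tes(genes)

  ## ---- TE copies -------------------------------------------------------
  lib_seq <- as.character(library$seq)
  lib_len <- library_lengths(library)
  truth_rows <- vector("list", sum(vapply(family_specs, `[[`, integer(1),
                                          "copy_number")))
  ti <- 0L
  for (fs in family_specs) {
    cons_chars <- strsplit(lib_seq[[fs$family]], "")[[1]]
    Lc <- lib_len[[fs$family]]
    sfam <- superfamily_of(fs$family)
    w <- as.numeric(chromosome_lengths)
    if (!is.null(fs$chrom_weights)) w <- w * fs$chrom_weights[chs]
    w <- w / sum(w)
    n_failed <- 0L
    for (cp in seq_len(fs$copy_number)) {
      ## truncation decides the kept consensus fragment
      a <- 1L; b <- Lc
      if (runif(1) < fs$trunc_prob) {
        side <- sample(c("5", "3", "both"), 1L, prob = c(0.45, 0.45, 0.1))
        f <- runif(1, fs$trunc_range[1], fs$trunc_range[2])
        cut <- as.integer(round(f * Lc))
        if (side %in% c("5", "both")) a <- min(Lc - 30L, 1L + cut %/%
                                                 (if (side == "both") 2L else 1L))
        if (side %in% c("3", "both")) b <- max(a + 30L, Lc - cut %/%
                                                 (if (side == "both") 2L else 1L))
      }
      elen <- b - a + 1L
      ## position and strand
      placement <- "niche"; gene_ref <- NA_character_
      near_gene <- runif(1) < fs$near_gene_prob && nrow(genes) > 0L
      if (near_gene) {
        gidx <- sample.int(nrow(genes), 1L)
        gene <- genes[gidx]
        d <- as.integer(round(pmin(pmax(rlnorm(1, fs$tss_gap_meanlog,
                                               fs$tss_gap_sdlog), 50), 9000)))
        upstream <- runif(1) < 0.8
        if (gene$strand == "+") {
          s <- if (upstream) gene$tss - d - elen + 1L else gene$tes + d
        } else {
          s <- if (upstream) gene$tss + d else gene$tes - d - elen + 1L
        }
        ch <- gene$chrom
        strand <- if (runif(1) < fs$strand_bias) gene$strand
                  else setdiff(c("+", "-"), gene$strand)
        placement <- "near_gene"; gene_ref <- gene$gene_id
      } else {
        ch <- sample(chs, 1L, prob = w)
        mid <- .niche_position(fs$niche, fs$niche_conc,
                               centromeres[[ch]], chromosome_lengths[[ch]])
        s <- mid - elen %/% 2L
        strand <- sample(c("+", "-"), 1L)
      }
      L <- chromosome_lengths[[ch]]
      s <- max(35L, min(s, L - elen - 34L))
      e <- s + elen - 1L
      if (!.tracker_claim(occ[[ch]], s, e)) {
        ## local retries, then skip the copy
        ok <- FALSE
        for (try in 1:60) {
          mid <- .niche_position(fs$niche, fs$niche_conc,
                                 centromeres[[ch]], L)
          s <- max(35L, min(mid - elen %/% 2L, L - elen - 34L))
          e <- s + elen - 1L
          if (.tracker_claim(occ[[ch]], s, e)) { ok <- TRUE; break }
        }
        if (!ok) { n_failed <- n_failed + 1L; next }
        if (placement == "near_gene") placement <- "niche"  # fell back
      }
      ## copy sequence: kept fragment, mutated, oriented
      rate <- runif(1, 0, fs$max_divergence)
      frag <- .mutate_seq(cons_chars[a:b], rate)
      if (strand == "-") frag <- rev(.comp[frag])
      base[[ch]][s:e] <- frag
      ## target-site motif into the flanks (element orientation)
      motif_planted <- FALSE
      if (!is.null(fs$motif_left) || !is.null(fs$motif_right)) {
        ml <- if (is.null(fs$motif_left)) character(0)
              else .sample_motif(fs$motif_left)
        mr <- if (is.null(fs$motif_right)) character(0)
              else .sample_motif(fs$motif_right)
        if (strand == "-") {
          tmp <- ml
          ml <- rev(.comp[mr]); mr <- rev(.comp[tmp])
          ml[is.na(ml)] <- NA; mr[is.na(mr)] <- NA
        }
        ls <- s - length(ml); le <- s - 1L
        rs <- e + 1L; re <- e + length(mr)
        flanks_ok <- ls >= 1L && re <= L &&
          (length(ml) == 0L || .tracker_free(occ[[ch]], ls, le)) &&
          (length(mr) == 0L || .tracker_free(occ[[ch]], rs, re))
        if (flanks_ok) {
          if (length(ml) > 0L) {
            keep <- !is.na(ml)
            base[[ch]][(ls:le)[keep]] <- ml[keep]
          }
          if (length(mr) > 0L) {
            keep <- !is.na(mr)
            base[[ch]][(rs:re)[keep]] <- mr[keep]
          }
          motif_planted <- TRUE
        }
      }
      ti <- ti + 1L
      truth_rows[[ti]] <- data.table::data.table(
        chrom = ch, start = s, end = e, family = fs$family,
        superfamily = sfam, strand = strand,
        cons_start = a, cons_end = b,
        five_prime_intact = a == 1L, three_prime_intact = b == Lc,
        complete = a == 1L && b == Lc,
        divergence = rate, placement = placement, gene_id = gene_ref,
        motif_planted = motif_planted)
    }
    if (n_failed > 0L) {
      rs_log("simulate_genome: %s: %d/%d copies could not be placed",
             fs$family, n_failed, fs$copy_number)
    }
  }
  truth <- data.table::rbindlist(truth_rows[seq_len(ti)])
  assembly <- genome_assembly(vapply(base, paste, character(1), collapse = ""))
  promoter_status <- if (nrow(genes) > 0L && nrow(truth) > 0L) {
    classify_promoters(genes, truth)
  } else NULL
  rs_log("simulate_genome: %d gene(s), %d TE copies on %d chromosome(s)",
         nrow(genes), nrow(truth), length(chs))
  list(assembly = assembly, genes = genes, truth = truth,
       centromeres = centromeres, promoter_status = promoter_status)
}

#' Write a simulated world to disk
#'
#' Emits genome FASTA, gene GFF3, truth TE GFF3, library FASTA, a centromere
#' sidecar TSV and (when present) the methylation TSV into a directory.
#'
#' @param world a [simulate_genome()] result.
#' @param library the [te_library()] used.
#' @param dir output directory (created).
#' @param calls optional methylation call table.
#' @export
write_world <- function(world, library, dir, calls = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$assembly, file.path(dir, "genome.fa"))
  write_gff3_genes(world$genes, file.path(dir, "genes.gff3"))
  write_gff3_te(world$truth, file.path(dir, "te_truth.gff3"))
  write_te_library(library, file.path(dir, "library.fa"))
  data.table::fwrite(
    data.table::data.table(chrom = names(world$centromeres),
                           centromere = world$centromeres),
    file.path(dir, "centromeres.tsv"), sep = "\t")
  if (!is.null(calls)) {
    write_methylation_table(calls, file.path(dir, "methylation.tsv"))
  }
  invisible(dir)
}
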