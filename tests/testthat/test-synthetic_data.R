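test_that("generate_te_library is reproducible and respects requests", {
  a <- generate_te_library(2L, lengths = c(300L, 900L),
                           superfamily_codes = c("DTT", "RLG"), seed = 1L)
  b <- generate_te_library(2L, lengths = c(300L, 900L),
                           superfamily_codes = c("DTT", "RLG"), seed = 1L)
  expect_identical(as.character(a$seq), as.character(b$seq))

  d <- generate_te_library(1L, lengths = 150L, superfamily_codes = "DTT",
                           seed = 3L)
  expect_match(d$entries$family, "^DTT_")
  expect_equal(d$entries$length, 150L)
  expect_equal(d$entries$superfamily, "Mariner")
  expect_equal(d$entries$class, 2L)

  expect_error(generate_te_library(400L, lengths = 5L), "length")
})

test_that("generated families are mutually unassignable under the 80/80 rule", {
  lib <- fixture_library()
  for (i in seq_len(nrow(lib$entries))) {
    others <- te_library(as.character(lib$seq)[-i])
    expect_equal(assign_family_80_80(as.character(lib$seq[[i]]), others),
                 "unassigned")
  }
})

test_that("autonomous flag matches ORF content of generated consensi", {
  lib <- fixture_library()
  got <- vapply(as.character(lib$seq), classify_autonomy, character(1),
                USE.NAMES = FALSE)
  expect_equal(got == "autonomous", lib$entries$autonomous)
})

test_that("simulate_genome is bit-for-bit reproducible", {
  lib <- fixture_library()
  specs <- list(family_spec("RLG_sim01", 20L, niche = "distal",
                            trunc_prob = 0.3),
                family_spec("DTT_sim02", 30L, near_gene_prob = 0.5,
                            motif_left = "T", motif_right = "A"))
  gsp <- gene_spec(n_genes = 30L)
  w1 <- simulate_genome(c(c1 = 500000L), lib, specs, gsp, seed = 5L)
  w2 <- simulate_genome(c(c1 = 500000L), lib, specs, gsp, seed = 5L)
  expect_identical(as.character(w1$assembly$seq), as.character(w2$assembly$seq))
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$genes, w2$genes)
  ## and the FASTA/GFF3 on disk are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_world(w1, lib, d1); write_world(w2, lib, d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "te_truth.gff3")),
                   readLines(file.path(d2, "te_truth.gff3")))
})

test_that("planted truth matches the genome content", {
  lib <- fixture_library()
  specs <- list(family_spec("RLG_sim01", 25L, max_divergence = 0.08,
                            trunc_prob = 0.4))
  w <- simulate_genome(c(c1 = 400000L, c2 = 300000L), lib, specs,
                       gene_spec(n_genes = 20L), seed = 8L)
  tr <- w$truth
  expect_true(all(tr$start >= 1L))
  expect_true(all(tr$end <= w$assembly$lengths[tr$chrom]))
  expect_true(all(tr$complete == (tr$five_prime_intact & tr$three_prime_intact)))
  cons <- as.character(lib$seq[["RLG_sim01"]])
  for (i in sample(nrow(tr), 10L)) {
    row <- tr[i]
    got <- substring(as.character(w$assembly$seq[[row$chrom]]),
                     row$start, row$end)
    want <- substr(cons, row$cons_start, row$cons_end)
    if (row$strand == "-") {
      got <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(got)))
    }
    expect_equal(nchar(got), nchar(want))
    mism <- sum(strsplit(got, "")[[1]] != strsplit(want, "")[[1]])
    expect_lte(mism / nchar(want), row$divergence + 0.02)
  }
})

test_that("target-site motifs flank every non-fallback copy", {
  lib <- fixture_library()
  specs <- list(family_spec("DTT_sim02", 80L, near_gene_prob = 0.5,
                            motif_left = "T", motif_right = "A"))
  w <- simulate_genome(c(c1 = 600000L), lib, specs, gene_spec(n_genes = 40L),
                       seed = 13L)
  tr <- w$truth[motif_planted == TRUE]
  expect_gt(nrow(tr), 50L)
  s <- as.character(w$assembly$seq[["c1"]])
  ## a T-A target reads T...A on the plus strand for either element strand
  expect_true(all(substring(s, tr$start - 1L, tr$start - 1L) == "T"))
  expect_true(all(substring(s, tr$end + 1L, tr$end + 1L) == "A"))
})

test_that("uniform-niche placement passes a KS test against uniform", {
  lib <- fixture_library()
  pvals <- vapply(1:3, function(sd) {
    specs <- list(family_spec("DTT_sim02", 1000L))
    w <- simulate_genome(c(c1 = 10000000L), lib, specs,
                         gene_spec(n_genes = 0L), seed = sd,
                         n_assembly_gaps = 0L)
    mids <- (w$truth$start + w$truth$end) / 2
    suppressWarnings(stats::ks.test(mids, "punif", 1,
                                    10000000)$p.value)
  }, numeric(1))
  ## seed-averaged: the typical seed passes at alpha = 0.01
  expect_gte(sum(pvals > 0.01), 2L)
})

test_that("niche densities shape the planted distributions", {
  lib <- fixture_library()
  specs <- list(family_spec("RLG_sim01", 150L, niche = "distal",
                            niche_conc = 4),
                family_spec("RLC_sim03", 150L, niche = "proximal",
                            niche_conc = 4))
  w <- simulate_genome(c(c1 = 8000000L), lib, specs, gene_spec(n_genes = 0L),
                       seed = 21L)
  cen <- w$centromeres[["c1"]]
  tr <- w$truth
  tr[, mid := (start + end) / 2]
  tr[, tel_frac := pmin(mid, 8000000 - mid) / cen]   # 0 telomere, 1 centromere
  ## distal family sits closer to telomeres than the proximal one
  expect_lt(tr[family == "RLG_sim01", median(tel_frac)],
            tr[family == "RLC_sim03", median(tel_frac)] - 0.2)
})

test_that("simulated methylome recovers baselines and honours depth", {
  lib <- fixture_library()
  w <- simulate_genome(c(c1 = 200000L), lib,
                       list(family_spec("RLG_sim01", 5L)),
                       gene_spec(n_genes = 0L), seed = 2L)
  spec <- methylome_spec(baseline = c(CG = 0.8, CHG = 0.5, CHH = 0.05),
                         depth_mean = 40)
  calls <- simulate_methylome(w$assembly, w$genes, NULL, spec, seed = 3L)
  lev <- calls[, .(level = sum(meth) / sum(total)), by = context]
  expect_equal(lev[context == "CG", level], 0.8, tolerance = 0.02)
  expect_equal(lev[context == "CHG", level], 0.5, tolerance = 0.02)
  expect_equal(lev[context == "CHH", level], 0.05, tolerance = 0.2)
  ## depth 0 everywhere -> all totals zero
  calls0 <- simulate_methylome(w$assembly, w$genes, NULL,
                               methylome_spec(depth_mean = 0), seed = 3L)
  expect_true(all(calls0$total == 0L))
  ## determinism
  calls2 <- simulate_methylome(w$assembly, w$genes, NULL, spec, seed = 3L)
  expect_identical(calls, calls2)
})

test_that("cytosine contexts are assigned correctly on both strands", {
  ##        123456789012345
  seq <- "ACGGATCCGTTACTGA"
  ## plus-strand Cs: pos2 (CGG->CG), pos7 (CCG->CHG), pos8 (CGT->CG),
  ##                 pos13 (CTG->CHH)
  ## minus-strand Cs (G on plus): pos3 (complement of CG at 2-3 -> CG),
  ##   pos4 (GGA; minus tri = C,C,G? pos4 G: prv1=G(3) -> not C;
  ##         prv2=C(2)? prv1 in {T,G,A} yes, prv2==C -> CHG)
  sites <- repeatscape:::.cytosine_sites(seq)
  get <- function(p, s) sites[pos == p & strand == s, ctx]
  expect_equal(get(2L, "+"), 1L)    # CG
  expect_equal(get(7L, "+"), 2L)    # CHG
  expect_equal(get(8L, "+"), 1L)    # CG
  expect_equal(get(13L, "+"), 2L)   # CTG -> CHG
  sites2 <- repeatscape:::.cytosine_sites("CATT")
  expect_equal(sites2[pos == 1L & strand == "+", ctx], 3L)  # CAT -> CHH
  expect_equal(get(3L, "-"), 1L)    # CG on minus
  expect_equal(get(4L, "-"), 2L)    # CHG on minus
  ## N context excluded
  sitesN <- repeatscape:::.cytosine_sites("ACN")
  expect_equal(nrow(sitesN[pos == 2L & strand == "+"]), 0L)
})
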