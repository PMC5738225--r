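lib <- fixture_library()

test_that("segment_genome tiles chromosomes and keeps the partial segment", {
  asm <- genome_assembly(c(c1 = strrep("A", 540), c2 = strrep("C", 500)))
  segs <- segment_genome(asm, 180L)
  expect_equal(segs[chrom == "c1", .N], 3L)
  expect_equal(segs[chrom == "c2", end - start + 1L], c(180L, 180L, 140L))
  expect_equal(segs$seg_index, seq_len(6L))
  expect_error(segment_genome(asm, 10L), ">= 20")

  empty <- genome_assembly(setNames(character(0), character(0)))
  expect_equal(nrow(segment_genome(empty)), 0L)
})

test_that("search_segments finds exact and diverged copies, not N runs", {
  cons <- as.character(lib$seq[["RLC_sim03"]])
  slice <- substr(cons, 301, 480)          # one full segment of consensus
  asm <- genome_assembly(c(c1 = slice))
  hits <- search_segments(asm, lib)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$family, "RLC_sim03")
  expect_equal(hits$identity, 100)
  expect_equal(c(hits$start, hits$end), c(1L, 180L))
  expect_equal(c(hits$cons_start, hits$cons_end), c(301L, 480L))

  asm_n <- genome_assembly(c(c1 = strrep("N", 180)))
  expect_equal(nrow(search_segments(asm_n, lib)), 0L)

  ## 27/180 mutations ~ 85% identity: rejected at threshold 90, found at 80
  mut <- mutate_k(slice, 27L, seed = 5L)
  asm_m <- genome_assembly(c(c1 = mut))
  expect_equal(nrow(search_segments(asm_m, lib, min_identity = 90)), 0L)
  h80 <- search_segments(asm_m, lib, min_identity = 80)
  expect_equal(h80$family[1], "RLC_sim03")
  ## built-in aligner agrees with the quadratic oracle within ~1 point
  orc <- sw_oracle(mut, slice)
  expect_lt(abs(h80$identity[1] - orc$identity), 1.5)
})

test_that("search_segments reports minus-strand hits in forward consensus coords", {
  cons <- as.character(lib$seq[["DTT_sim02"]])    # 200 bp MITE
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  asm <- genome_assembly(c(c1 = paste0(strrep("A", 50), rc, strrep("T", 110))))
  hits <- search_segments(asm, lib, min_hit_length = 50L)
  minus <- hits[strand == "-"]
  expect_gt(nrow(minus), 0L)
  expect_equal(min(minus$cons_start), 1L)
  expect_equal(max(minus$cons_end), 200L)
})

test_that("merge_and_bridge honours the strict 100 bp rule and strandness", {
  mk <- function(s1, e1, s2, e2, fam2 = "RLG_a", str2 = "+") {
    data.table::data.table(chrom = "c1", start = c(s1, s2), end = c(e1, e2),
                           family = c("RLG_a", fam2), strand = c("+", str2),
                           identity = c(90, 95))
  }
  ## gap of 99 intervening bases (1-based closed [101,280] + [380,559])
  ann <- merge_and_bridge(mk(101L, 280L, 380L, 559L))
  expect_equal(nrow(ann), 1L)
  expect_equal(c(ann$start, ann$end), c(101L, 559L))
  expect_equal(ann$identity, 95)
  ## gap of exactly 100 is not bridged
  ann <- merge_and_bridge(mk(101L, 280L, 381L, 560L))
  expect_equal(nrow(ann), 2L)
  ## same intervals, opposite strands: never merged
  ann <- merge_and_bridge(mk(101L, 280L, 380L, 559L, str2 = "-"))
  expect_equal(nrow(ann), 2L)
  ## an intervening hit of another family blocks the bridge
  h <- rbind(mk(101L, 280L, 380L, 559L),
             data.table::data.table(chrom = "c1", start = 300L, end = 330L,
                                    family = "DTT_b", strand = "+",
                                    identity = 99))
  ann <- merge_and_bridge(h)
  expect_equal(nrow(ann[family == "RLG_a"]), 2L)
})

test_that("annotations near assembly gaps are extended to the gap edge", {
  h <- data.table::data.table(chrom = "c1", start = 101L, end = 280L,
                              family = "RLG_a", strand = "+", identity = 90)
  gaps <- data.table::data.table(chrom = "c1", start = 341L, end = 400L)
  ann <- merge_and_bridge(h, assembly_gaps = gaps)   # 60 bases before gap
  expect_equal(ann$end, 340L)
  gaps2 <- data.table::data.table(chrom = "c1", start = 365L, end = 400L)
  ann2 <- merge_and_bridge(h, assembly_gaps = gaps2) # 84 bases: no extension
  expect_equal(ann2$end, 280L)
})

test_that("merge_and_bridge equals the brute-force oracle on random hit sets", {
  set.seed(99)
  for (rep in 1:200) {
    h <- random_hits(sample(1:10, 1L))
    gaps <- if (rep %% 3 == 0) {
      data.table::data.table(chrom = "c1",
                             start = c(1200L, 2500L), end = c(1260L, 2550L))
    } else NULL
    got <- merge_and_bridge(h, assembly_gaps = gaps)
    want <- merge_bridge_oracle(h, assembly_gaps = gaps)
    expect_equal(got[, .(chrom, start, end, family, strand, identity)],
                 want, info = sprintf("rep %d", rep))
  }
})

test_that("merge_and_bridge is idempotent and outputs never overlap in-group", {
  set.seed(123)
  for (rep in 1:50) {
    h <- random_hits(sample(2:10, 1L))
    gaps <- data.table::data.table(chrom = "c1", start = 1500L, end = 1560L)
    ann <- merge_and_bridge(h, assembly_gaps = gaps)
    again <- merge_and_bridge(ann, assembly_gaps = gaps)
    expect_equal(again[, .(chrom, start, end, family, strand)],
                 ann[, .(chrom, start, end, family, strand)])
    ## no same-family same-strand overlaps
    ann[, grp := paste(chrom, family, strand)]
    bad <- ann[, any(start[-1L] <= cummax(end)[-.N]), by = grp]$V1
    expect_false(any(bad))
  }
})

test_that("detect_full_length flags intact ends strand-awarely", {
  L <- lib$entries[family == "RLG_sim01", length]
  ann <- data.table::data.table(
    chrom = "c1", start = c(1000L, 5000L, 9000L),
    end = c(1000L, 5000L, 9000L) + c(L, L - 500L, L) - 1L,
    family = "RLG_sim01", superfamily = "Gypsy",
    strand = c("+", "+", "-"), identity = 95,
    cons_min = c(1L, 501L, 1L), cons_max = c(L, L, L))
  out <- detect_full_length(ann, lib, end_tolerance = 20L)
  expect_equal(out$five_prime_intact, c(TRUE, FALSE, TRUE))
  expect_equal(out$three_prime_intact, c(TRUE, TRUE, TRUE))
  expect_equal(out$complete, c(TRUE, FALSE, TRUE))
})

test_that("assign_family_80_80 applies both thresholds strictly", {
  cons <- as.character(lib$seq[["RLC_sim03"]])   # 2400 bp
  expect_equal(assign_family_80_80(cons, lib), "RLC_sim03")
  ## ~50% identity: a random sequence
  set.seed(3)
  rnd <- paste(sample(c("A", "C", "G", "T"), 2400, replace = TRUE),
               collapse = "")
  expect_equal(assign_family_80_80(rnd, lib), "unassigned")
  ## 85% identity over 85% of the length -> assigned
  frag <- substr(cons, 1, round(0.85 * 2400))
  mut <- mutate_k(frag, round(0.15 * nchar(frag)), seed = 9L)
  expect_equal(assign_family_80_80(mut, lib), "RLC_sim03")
  ## reverse complement is still recognised
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
  expect_equal(assign_family_80_80(rc, lib), "RLC_sim03")
  ## identity fine but alignable over only half the length -> unassigned
  half <- substr(cons, 1, 1200)
  padded <- paste0(half, paste(rep("A", 1200), collapse = ""))
  expect_equal(assign_family_80_80(padded, lib), "unassigned")
})

test_that("build_consensus calls majorities and enforces the copy minimum", {
  master <- as.character(lib$seq[["DTT_sim02"]])
  copies <- c(mutate_k(master, 1L, seed = 1L),
              mutate_k(master, 1L, seed = 2L),
              mutate_k(master, 1L, seed = 3L))
  cb <- build_consensus(copies)
  expect_s3_class(cb, "consensus_build")
  expect_equal(cb$consensus, master)
  expect_false(grepl("-", cb$consensus, fixed = TRUE))

  expect_error(build_consensus(copies[1:2]), "at least 3 copies, got 2")

  cb5 <- build_consensus(rep(master, 5L))
  expect_equal(cb5$consensus, master)
  expect_equal(cb5$n_copies, 5L)
})

test_that("classify_autonomy scans all six frames for long ORFs", {
  orf900 <- repeatscape:::.random_orf(900L)
  set.seed(11)
  pad <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  seq900 <- paste0(pad, orf900, pad)
  expect_equal(classify_autonomy(seq900), "autonomous")
  ## reverse complement: ORF on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq900)))
  expect_equal(classify_autonomy(rc), "autonomous")
  ## a 500-codon ORF broken mid-way leaves only ~250-codon halves
  orf500 <- repeatscape:::.random_orf(500L)
  broken <- paste0(substr(orf500, 1, 750), "TAA",
                   substr(orf500, 754, nchar(orf500)))
  expect_equal(classify_autonomy(paste0(pad, broken, pad)), "non-autonomous")
  expect_equal(classify_autonomy(strrep("N", 600)), "non-autonomous")
})

test_that("external tabular hits adapter converts coordinates and strands", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tRLG_sim01\t95.5\t180\t8\t0\t1001\t1180\t1\t180\t1e-50\t250",
               "c1\tRLG_sim01\t91.0\t150\t12\t0\t2001\t2150\t400\t251\t1e-40\t200",
               "c1\tRLG_sim01\t70.0\t150\t45\t0\t3001\t3150\t1\t150\t1e-5\t50"),
             f)
  hits <- read_external_hits(f, lib)
  expect_equal(nrow(hits), 2L)   # 70% identity filtered out
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$cons_start[2], 251L)
  expect_equal(hits$cons_end[2], 400L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("c1\tNOPE_fam\t95\t100\t1\t0\t1\t100\t1\t100\t0\t1", bad)
  expect_error(read_external_hits(bad, lib), "unknown families")
})
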