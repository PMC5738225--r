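one_gene <- function(start = 20001L, end = 23000L, strand = "+",
                     chrom = "c1") {
  data.table::data.table(gene_id = "g001", chrom = chrom, start = start,
                         end = end, strand = strand, confidence = "HC1")
}

test_that("a fully covered upstream flank gives frequency 1 at all offsets", {
  genes <- one_gene()
  hits <- data.table::data.table(
    chrom = "c1", start = 1L, end = 20000L, family = "RLG_a",
    superfamily = "Gypsy", strand = "+", length = 20000L, identity = 95)
  prof <- build_anchor_profile(genes, hits, c(c1 = 50000L),
                               flank = 10000L, step = 20L)
  up <- prof$upstream[group == "Gypsy"]
  expect_equal(nrow(up), 500L)
  expect_true(all(up$freq == 1.0))
  expect_true(all(prof$upstream$freq >= 0 & prof$upstream$freq <= 1))
})

test_that("minus-strand genes reflect offsets so upstream is biological", {
  ## gene on -: TSS at its end coordinate; upstream = higher coordinates
  genes <- one_gene(start = 5001L, end = 8000L, strand = "-")
  hits <- data.table::data.table(
    chrom = "c1", start = 8001L, end = 18000L, family = "RLG_a",
    superfamily = "Gypsy", strand = "+", length = 10000L, identity = 95)
  prof <- build_anchor_profile(genes, hits, c(c1 = 50000L))
  expect_true(all(prof$upstream[group == "Gypsy", freq] == 1.0))
})

test_that("the longest covering hit wins at a sampled position", {
  genes <- one_gene()
  hits <- data.table::data.table(
    chrom = "c1", start = c(19500L, 19000L), end = c(19900L, 19900L),
    family = c("DTT_m", "RLG_g"), superfamily = c("Mariner", "Gypsy"),
    strand = "+", length = c(400L, 900L), identity = c(99, 90))
  prof <- build_anchor_profile(genes, hits, c(c1 = 50000L))
  ## offsets 120..500 bp upstream hit both; the 900 bp alignment wins
  touched <- prof$upstream[offset_bp %in% seq(200L, 400L, 20L)]
  expect_true(all(touched$group == "Gypsy"))
})

test_that("flanks beyond the chromosome end shrink the denominator", {
  genes <- rbind(one_gene(start = 2001L, end = 4000L),
                 one_gene(start = 30001L, end = 32000L)[, gene_id := "g002"])
  hits <- data.table::data.table(
    chrom = "c1", start = 1L, end = 40000L, family = "RLG_a",
    superfamily = "Gypsy", strand = "+", length = 40000L, identity = 95)
  prof <- build_anchor_profile(genes, hits, c(c1 = 40000L))
  ## at 5 kb upstream only gene 2 has a valid position; freq still 1
  expect_equal(prof$upstream[offset_bp == 5000L, n_genes], 1L)
  expect_true(all(prof$upstream$freq == 1.0))
})

test_that("profiles are invariant to renaming and translation", {
  set.seed(17)
  genes <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:5), chrom = "c1",
    start = sort(sample.int(50000L, 5L)) + 20000L, strand = "+",
    confidence = "HC1")
  genes[, end := start + 1500L]
  hits <- random_hits(40L, L = 70000L)[chrom == "c1"]
  hits[, superfamily := superfamily_of(family)]
  hits[, length := end - start + 1L]
  p1 <- build_anchor_profile(genes, hits, c(c1 = 200000L), flank = 5000L)
  g2 <- data.table::copy(genes)[, chrom := "weird"]
  h2 <- data.table::copy(hits)[, chrom := "weird"]
  p2 <- build_anchor_profile(g2, h2, c(weird = 200000L), flank = 5000L)
  expect_equal(p1$upstream, p2$upstream)
  sh <- 12345L
  g3 <- data.table::copy(genes)[, `:=`(start = start + sh, end = end + sh)]
  h3 <- data.table::copy(hits)[, `:=`(start = start + sh, end = end + sh)]
  p3 <- build_anchor_profile(g3, h3, c(c1 = 200000L + sh), flank = 5000L)
  expect_equal(p1$upstream, p3$upstream)
  expect_equal(p1$downstream, p3$downstream)
})

test_that("reverse-complementing the world leaves profiles unchanged", {
  set.seed(18)
  L <- 100000L
  genes <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:4), chrom = "c1",
    start = c(20000L, 40000L, 60000L, 80000L),
    strand = c("+", "-", "+", "-"), confidence = "HC1")
  genes[, end := start + 2000L]
  hits <- random_hits(30L, L = 90000L)[chrom == "c1"]
  hits[, superfamily := superfamily_of(family)]
  hits[, length := end - start + 1L]
  p1 <- build_anchor_profile(genes, hits, c(c1 = L), flank = 5000L)
  ## mirror all coordinates and flip strands
  flip <- function(dt) {
    out <- data.table::copy(dt)
    out[, `:=`(start = L - dt$end + 1L, end = L - dt$start + 1L,
               strand = ifelse(strand == "+", "-", "+"))]
    out
  }
  p2 <- build_anchor_profile(flip(genes), flip(hits), c(c1 = L),
                             flank = 5000L)
  expect_equal(p1$upstream, p2$upstream)
  expect_equal(p1$downstream, p2$downstream)
})

test_that("gypsy_copia_ratio handles equal densities and zero Copia", {
  genes <- one_gene()
  hits <- data.table::data.table(
    chrom = "c1", start = c(1L, 1L), end = c(20000L, 20000L),
    family = c("RLG_a", "RLC_b"), superfamily = c("Gypsy", "Copia"),
    strand = "+", length = c(500L, 500L), identity = c(90, 90))
  ## both cover everything; winner alternates nowhere (tie -> identity ->
  ## name), so compute the ratio from a profile where both are present
  prof <- build_anchor_profile(genes, hits, c(c1 = 50000L))
  r <- gypsy_copia_ratio(prof)
  expect_true(all(is.na(r$ratio) | r$ratio >= 0))
  ## direct construction: equal frequencies -> ratio 1; zero Copia -> NA
  prof2 <- list(
    upstream = data.table::data.table(
      offset_bp = rep(c(20L, 40L), each = 2L),
      group = rep(c("Gypsy", "Copia"), 2L),
      freq = c(0.4, 0.4, 0.2, 0), n_genes = 10L),
    downstream = data.table::data.table(
      offset_bp = 20L, group = c("Gypsy", "Copia"), freq = c(0.3, 0.3),
      n_genes = 10L))
  class(prof2) <- "anchored_profile"
  r2 <- gypsy_copia_ratio(prof2)
  expect_equal(r2[anchor == "upstream" & offset_bp == 20L, ratio], 1.0)
  expect_true(is.na(r2[anchor == "upstream" & offset_bp == 40L, ratio]))
})

test_that("target_site_matrix counts flanks in element orientation", {
  ## genome: plant two complete copies with T at -1 and A at +1
  set.seed(19)
  bg <- sample(c("A", "C", "G", "T"), 2000L, replace = TRUE)
  elem <- sample(c("A", "C", "G", "T"), 100L, replace = TRUE)
  bg[501:600] <- elem
  bg[500] <- "T"; bg[601] <- "A"
  ## minus-strand copy: revcomp of elem; flank pattern mirrored
  rc <- rev(repeatscape:::.comp[elem])
  bg[1001:1100] <- rc
  bg[1000] <- "T"; bg[1101] <- "A"
  asm <- genome_assembly(setNames(paste(bg, collapse = ""), "c1"))
  ann <- data.table::data.table(
    chrom = "c1", start = c(501L, 1001L), end = c(600L, 1100L),
    family = "DTT_m", superfamily = "Mariner", strand = c("+", "-"),
    complete = TRUE)
  tsm <- target_site_matrix(ann, asm)
  expect_equal(tsm$n_copies, 2L)
  ## plus copy contributes T at -1; minus copy's 5' flank is revcomp of its
  ## right genomic flank, so it also reads T at -1
  expect_equal(unname(tsm$fractions["T", "-1"]), 1.0)
  expect_equal(unname(tsm$fractions["A", "1"]), 1.0)
  ## column sums are 1 wherever something was observed
  expect_true(all(abs(colSums(tsm$fractions) - 1) < 1e-9))

  expect_error(target_site_matrix(ann[0], asm), "no usable copies")
})

test_that("single-copy matrices are 0/1 and i.i.d. flanks are ~uniform", {
  set.seed(20)
  bg <- sample(c("A", "C", "G", "T"), 50000L, replace = TRUE)
  asm <- genome_assembly(setNames(paste(bg, collapse = ""), "c1"))
  one <- data.table::data.table(chrom = "c1", start = 1001L, end = 1100L,
                                family = "DTT_m", superfamily = "Mariner",
                                strand = "+", complete = TRUE)
  t1 <- target_site_matrix(one, asm)
  expect_true(all(t1$fractions %in% c(0, 1)))

  starts <- seq(2001L, 48000L, by = 150L)
  many <- data.table::data.table(chrom = "c1", start = starts,
                                 end = starts + 50L, family = "DTT_m",
                                 superfamily = "Mariner", strand = "+",
                                 complete = TRUE)
  tm <- target_site_matrix(many, asm)
  expect_true(all(abs(tm$fractions - 0.25) < 4 * sqrt(0.25 * 0.75 /
                                                        tm$n_copies)))
})

test_that("consensus_motif renders letters, pairs and n correctly", {
  fake <- function(frac_by_pos) {
    ## frac_by_pos: list of named numeric vectors per position
    m <- vapply(frac_by_pos, function(f) {
      v <- c(A = 0, C = 0, G = 0, T = 0)
      v[names(f)] <- f
      v
    }, numeric(4))
    structure(list(positions = c(-2L, -1L, 1L, 2L),
                   fractions = m, counts = m * 100, n_copies = 100L,
                   n_N = rep(0L, ncol(m))),
              class = "target_site_matrix")
  }
  tsm <- fake(list(c(T = 0.9, A = 0.1), c(T = 0.45, A = 0.45, C = 0.1),
                   c(A = 0.85, G = 0.15),
                   c(A = 0.3, C = 0.25, G = 0.25, T = 0.2)))
  ## exact ties order alphabetically inside the bracket class
  expect_equal(consensus_motif(tsm, 0.8), "T[A/T]-An")
})
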