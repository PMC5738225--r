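## Shared fixtures, all generated in code.

## small deterministic library: one autonomous LTR-sized family, one MITE,
## one mid-sized family
fixture_library <- function(seed = 42L) {
  generate_te_library(3L, lengths = c(1500L, 200L, 2400L),
                      superfamily_codes = c("RLG", "DTT", "RLC"),
                      autonomous = c(TRUE, FALSE, FALSE), seed = seed)
}

## assembly built from an explicit background with sequences written in at
## known positions: parts = list(list(seq=, at=)); returns genome_assembly
fixture_assembly <- function(len = 5000L, parts = list(), seed = 7L,
                             chrom = "c1") {
  set.seed(seed)
  bg <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (p in parts) {
    s <- strsplit(p$seq, "")[[1]]
    bg[p$at:(p$at + length(s) - 1L)] <- s
  }
  genome_assembly(setNames(paste(bg, collapse = ""), chrom))
}

## random hit tables for the merge/bridge property tests
random_hits <- function(n, families = c("RLG_a", "DTT_b"), L = 3000L) {
  start <- sample.int(L - 250L, n)
  len <- sample(30:200, n, replace = TRUE)
  data.table::data.table(
    chrom = sample(c("c1", "c2"), n, replace = TRUE),
    start = start, end = start + len,
    family = sample(families, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    identity = round(runif(n, 80, 100), 1))
}

## mutate exactly k positions of a sequence (guaranteed different base)
mutate_k <- function(seq, k, seed = 1L) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  at <- sample(seq_along(chars), k)
  chars[at] <- vapply(chars[at], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1))
  paste(chars, collapse = "")
}
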