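## Genome-wide abundance statistics: copy-number estimates, genome fractions,
## chromosomal bin distributions, arm-terminal enrichment and per-chromosome
## abundance contrasts.
##
## Convention (documented): statistics counting copies use the copy midpoint
## to decide bin/arm membership; statistics reporting occupied kb apportion
## annotation bp to bins by overlap.

#' Copy-number estimate from annotated bp and consensus length
#'
#' Total annotated base pairs divided by the consensus length, rounded half
#' away from zero. Vectorised.
#'
#' @param total_bp total annotated bp per family.
#' @param consensus_length consensus length in bp (> 0).
#' @return integer copy-number estimate(s).
#' @export
estimate_copy_number <- function(total_bp, consensus_length) {
  if (any(consensus_length <= 0)) stop("'consensus_length' must be > 0")
  if (any(total_bp < 0)) stop("'total_bp' must be >= 0")
  as.integer(round_half_away(total_bp / consensus_length))
}

#' Family copy-number table from annotations
#'
#' @param annotations TE annotation table.
#' @param library a [te_library()] providing consensus lengths.
#' @return data.table: family, superfamily, total_bp, total_kb,
#'   consensus_length, copy_number.
#' @export
copy_number_table <- function(annotations, library) {
  a <- data.table::as.data.table(annotations)
  tot <- a[, .(total_bp = sum(end - start + 1)), by = .(family, superfamily)]
  tot[, consensus_length := library_lengths(library)[family]]
  tot[, total_kb := total_bp / 1000]
  tot[, copy_number := estimate_copy_number(total_bp, consensus_length)]
  data.table::setorder(tot, -total_bp)
  tot[]
}

#' Genome fraction occupied per family, superfamily or class
#'
#' Occupied bp per group divided by the genome length, in percent.
#' Overlapping annotations of different families each count their own bp.
#'
#' @param annotations TE annotation table.
#' @param genome_length total genome length in bp (> 0).
#' @param group_by "family", "superfamily" or "class".
#' @return data.table: group, occupied_bp, percent.
#' @export
genome_fraction <- function(annotations, genome_length,
                            group_by = c("family", "superfamily", "class")) {
  group_by <- match.arg(group_by)
  if (genome_length <= 0) stop("'genome_length' must be > 0")
  a <- data.table::as.data.table(annotations)
  if (nrow(a) == 0L) {
    return(data.table::data.table(group = character(), occupied_bp = numeric(),
                                  percent = numeric()))
  }
  if (group_by == "class") a[, class := te_class_of(family)]
  grp <- switch(group_by, family = a$family, superfamily = a$superfamily,
                class = as.character(a$class))
  a[, group := grp]
  out <- a[, .(occupied_bp = sum(as.numeric(end - start + 1))), by = group]
  out[, percent := 100 * occupied_bp / genome_length]
  data.table::setorder(out, -occupied_bp)
  out[]
}

#' Per-bin occupied kb (and copy counts) along chromosomes
#'
#' Annotation bp are apportioned to fixed-size bins by overlap, so an
#' annotation straddling a bin edge contributes to both bins proportionally;
#' per-family bin sums equal the family's total annotated bp. Copy counts
#' per bin use midpoints.
#'
#' @param annotations TE annotation table.
#' @param chromosome_lengths named vector of chromosome lengths.
#' @param bin_size bin size in bp; 30 Mb is the field default for ~0.5 Gb
#'   chromosomes, 20-40 Mb is customary; use smaller bins for small genomes.
#' @return data.table: family, chrom, bin, bin_start, bin_end, occupied_bp,
#'   occupied_kb, n_copies.
#' @export
bin_distribution <- function(annotations, chromosome_lengths, bin_size = 30e6) {
  if (bin_size <= 0) stop("'bin_size' must be > 0")
  a <- data.table::as.data.table(annotations)
  bins <- data.table::rbindlist(lapply(names(chromosome_lengths), function(ch) {
    L <- chromosome_lengths[[ch]]
    starts <- seq.int(1, L, by = bin_size)
    data.table::data.table(chrom = ch, bin = seq_along(starts),
                           bin_start = as.integer(starts),
                           bin_end = as.integer(pmin(starts + bin_size - 1, L)))
  }))
  data.table::setkey(bins, chrom, bin_start, bin_end)
  if (nrow(a) == 0L) {
    out <- bins[, .(chrom, bin, bin_start, bin_end)]
    out[, `:=`(family = NA_character_, occupied_bp = 0, occupied_kb = 0,
               n_copies = 0L)]
    return(out[])
  }
  ov <- data.table::foverlaps(a[, .(chrom, start, end, family)], bins,
                              by.x = c("chrom", "start", "end"),
                              type = "any", nomatch = NULL)
  ov[, occ := overlap_width(start, end, bin_start, bin_end)]
  ov[, mid := interval_midpoint(start, end)]
  ov[, has_mid := mid >= bin_start & mid <= bin_end]
  out <- ov[, .(occupied_bp = sum(as.numeric(occ)), n_copies = sum(has_mid)),
            by = .(family, chrom, bin, bin_start, bin_end)]
  ## complete missing (family, bin) combinations with zeros
  full <- data.table::CJ(family = unique(a$family), chrom_bin = seq_len(nrow(bins)))
  full <- cbind(full[, .(family)], bins[full$chrom_bin])
  out <- merge(full, out,
               by = c("family", "chrom", "bin", "bin_start", "bin_end"),
               all.x = TRUE)
  out[is.na(occupied_bp), occupied_bp := 0]
  out[is.na(n_copies), n_copies := 0L]
  out[, occupied_kb := occupied_bp / 1000]
  data.table::setorder(out, family, chrom, bin)
  out[]
}

#' Fraction of copies in the distal terminal fraction of chromosome arms
#'
#' A copy (by midpoint) is terminal when its distance to the nearer telomere
#' is at most `terminal_fraction` of its arm's length; arms are defined by
#' the centromere coordinate. Families without copies are reported NA.
#'
#' @param annotations TE annotation table.
#' @param centromeres named vector of centromere coordinates per chromosome.
#' @param chromosome_lengths named vector of chromosome lengths.
#' @param terminal_fraction distal fraction of each arm (default 0.2).
#' @return data.table: family, n_copies, n_terminal, terminal_fraction.
#' @export
terminal_arm_enrichment <- function(annotations, centromeres,
                                    chromosome_lengths,
                                    terminal_fraction = 0.2) {
  a <- data.table::as.data.table(annotations)
  chs <- unique(a$chrom)
  if (!all(chs %in% names(centromeres)) ||
      !all(chs %in% names(chromosome_lengths))) {
    stop("centromere/length missing for some chromosome(s)")
  }
  if (any(centromeres[chs] < 1 | centromeres[chs] > chromosome_lengths[chs])) {
    stop("centromere outside chromosome bounds")
  }
  a[, mid := interval_midpoint(start, end)]
  a[, cen := centromeres[chrom]]
  a[, len := chromosome_lengths[chrom]]
  a[, arm_len := ifelse(mid <= cen, cen, len - cen)]
  a[, tel_dist := ifelse(mid <= cen, mid, len - mid + 1)]
  a[, terminal := tel_dist <= terminal_fraction * arm_len]
  out <- a[, .(n_copies = .N, n_terminal = sum(terminal)), by = family]
  out[, terminal_fraction := ifelse(n_copies > 0, n_terminal / n_copies,
                                    NA_real_)]
  out[]
}

#' Family-by-chromosome occupied kb with max/min abundance ratio
#'
#' @param annotations TE annotation table.
#' @return list with `matrix` (data.table family x chromosome occupied kb,
#'   rows summing to the family total) and `ratios` (family, max/min
#'   chromosome ratio, NA when a chromosome has no copies of the family).
#' @export
per_chromosome_abundance <- function(annotations) {
  a <- data.table::as.data.table(annotations)
  occ <- a[, .(occupied_kb = sum(end - start + 1) / 1000),
           by = .(family, chrom)]
  wide <- data.table::dcast(occ, family ~ chrom, value.var = "occupied_kb",
                            fill = 0)
  chrom_cols <- setdiff(names(wide), "family")
  wide[, total_kb := rowSums(.SD), .SDcols = chrom_cols]
  ratios <- wide[, .(family,
                     max_kb = do.call(pmax, .SD),
                     min_kb = do.call(pmin, .SD)), .SDcols = chrom_cols]
  ratios[, ratio := ifelse(min_kb > 0, max_kb / min_kb, NA_real_)]
  list(matrix = wide[], ratios = ratios[, .(family, max_kb, min_kb, ratio)])
}
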