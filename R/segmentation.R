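# Agglomerative segmentation of the aggregate profile.
#
# Starting from one segment per probe, the adjacent pair whose boundary is
# least significant (largest expected Euler characteristic at the jump and the
# adjacent segment widths) is merged, the two neighbouring boundaries are
# rescored with the new widths, and merging continues until every remaining
# boundary has significance <= E. A lazy-deletion priority queue keeps the
# procedure in P log P; ties in significance merge the leftmost boundary.
# Chromosomes are segmented independently.

build_segmentation <- function(res, probes, E, table) {
  cs <- chrom_starts(probes)
  ord <- attr(probes, "chrom_order")
  chrom_of <- function(p0) ord[findInterval(p0, cs)]
  segments <- data.frame(
    chrom = chrom_of(res$start), start_probe = res$start,
    end_probe = res$start + res$width, width = res$width,
    amplitude = res$mean, stringsAsFactors = FALSE)
  boundaries <- data.frame(
    boundary = res$boundary + 1L,           # b: cut between genome_order b-1, b
    chrom = if (length(res$boundary)) chrom_of(res$boundary) else character(),
    jump = res$jump, sig = res$sig, stringsAsFactors = FALSE)
  structure(list(segments = segments, boundaries = boundaries, E = E,
                 probes = probes, table_hash = table$data_hash),
            class = "segmentation")
}

#' Segment the genome-wide aggregate profile
#'
#' @param agg an `aggregate_profile`.
#' @param table an `euler_curves` table estimated from the same cohort (or a
#'   refined version of it).
#' @param E global significance threshold terminating the clustering; every
#'   surviving boundary has expected Euler characteristic `<= E`.
#' @return a `segmentation`: segments (`chrom`, `start_probe`, `end_probe`
#'   \[0-based half-open genome_order\], `width`, `amplitude`) tiling each
#'   chromosome, and boundaries (`boundary`, `chrom`, `jump`, `sig`).
#' @export
segment_genome <- function(agg, table, E) {
  stopifnot(inherits(agg, "aggregate_profile"), inherits(table, "euler_curves"),
            E > 0)
  cs <- chrom_starts(agg$probes)
  res <- cpp_segment(agg$values, as.integer(cs), E, unclass(table))
  build_segmentation(res, agg$probes, E, table)
}

#' Segment a single chromosome of the aggregate profile
#'
#' Convenience wrapper around [segment_genome()] restricted to one chromosome.
#'
#' @inheritParams segment_genome
#' @param chrom chromosome name.
#' @return a `segmentation` for that chromosome.
#' @export
segment_chromosome <- function(agg, chrom, table, E) {
  keep <- agg$probes$chrom == chrom
  if (!any(keep)) stop("no probes on chromosome ", chrom)
  probes <- agg$probes[keep, , drop = FALSE]
  probes$genome_order <- seq_len(nrow(probes)) - 1L
  attr(probes, "chrom_order") <- chrom
  attr(probes, "chrom_starts") <- c(0L, nrow(probes))
  class(probes) <- c("probe_map", "data.frame")
  sub <- structure(list(values = agg$values[keep], probes = probes,
                        n_samples = agg$n_samples, sign_mode = agg$sign_mode),
                   class = "aggregate_profile")
  segment_genome(sub, table, E)
}

#' Write a segmentation to bedGraph and TSV
#'
#' `<stem>.bedGraph` holds the segment amplitudes over the genomic extent of
#' their probes; `<stem>_boundaries.tsv` lists every significant boundary
#' with its base-pair position (start of the right segment's first probe),
#' jump and significance.
#'
#' @param seg a `segmentation`.
#' @param stem output path stem.
#' @return invisibly, the two file paths.
#' @export
write_segmentation <- function(seg, stem) {
  probes <- seg$probes
  cs <- chrom_starts(probes)
  s <- seg$segments
  end_bp <- ifelse(s$end_probe %in% cs[-1],
                   probes$pos[s$end_probe] + 1,
                   probes$pos[pmin(s$end_probe + 1, nrow(probes))])
  bg <- sprintf("%s\t%d\t%d\t%s", s$chrom,
                as.integer(probes$pos[s$start_probe + 1]),
                as.integer(end_bp), fmt6(s$amplitude))
  bgf <- paste0(stem, ".bedGraph")
  writeLines(bg, bgf)
  b <- seg$boundaries
  tsv <- paste0(stem, "_boundaries.tsv")
  out <- data.frame(chrom = b$chrom,
                    pos = if (nrow(b)) as.integer(probes$pos[b$boundary + 1])
                          else integer(),
                    boundary = b$boundary, jump = fmt6(b$jump),
                    sig = fmt6(b$sig))
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bedgraph = bgf, boundaries = tsv))
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("Segmentation at E = %g: %d segment(s), %d significant boundary(ies)\n",
              x$E, nrow(x$segments), nrow(x$boundaries)))
  invisible(x)
}
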