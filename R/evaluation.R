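# Benchmark metrics for driver recovery, real-data-style region filters and
# the cyclic-permutation gene-set enrichment test.

#' Filter called regions
#'
#' Removes regions overlapping no gene and regions wider than `max_width`
#' base pairs. Filters only ever remove rows; coordinates are untouched and
#' order is preserved.
#'
#' @param regions an annotated called-region table ([annotate_regions()]).
#' @param max_width maximum region width in base pairs (default 10 Mbp);
#'   `Inf` disables.
#' @param require_gene_overlap drop regions with no overlapping gene
#'   (requires an `n_genes` column; regions lacking one are kept).
#' @return the filtered table.
#' @export
filter_regions <- function(regions, max_width = 1e7,
                           require_gene_overlap = TRUE) {
  keep <- (regions$end - regions$start) <= max_width
  if (require_gene_overlap && "n_genes" %in% names(regions))
    keep <- keep & regions$n_genes > 0
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Driver-recovery metrics for called regions
#'
#' Overlap means an intersection of at least one base pair. The metrics are:
#' the proportion of driver genes overlapped by at least one region
#' (`tp_driver_prop`), the proportion of regions overlapping no driver
#' (`fp_region_prop`), the mean over regions of the fraction of overlapping
#' genes that are drivers (`mean_driver_fraction`), and the mean over regions
#' of one over the number of overlapping genes (`mean_inverse_gene_count`;
#' regions with no gene are excluded from the latter two means). Metrics with
#' an empty denominator are `NA`.
#'
#' @param regions a called-region table.
#' @param drivers ground-truth driver gene table.
#' @param all_genes full gene table (drivers included).
#' @return a `metric_report` list.
#' @export
compute_metrics <- function(regions, drivers, all_genes) {
  rep_ <- list(n_regions = nrow(regions), n_drivers = nrow(drivers),
               tp_driver_prop = NA_real_, fp_region_prop = NA_real_,
               mean_driver_fraction = NA_real_,
               mean_inverse_gene_count = NA_real_)
  if (nrow(drivers) > 0) {
    if (nrow(regions) > 0) {
      hits <- GenomicRanges::findOverlaps(genes_granges(drivers),
                                          regions_granges(regions))
      rep_$tp_driver_prop <- length(unique(S4Vectors::queryHits(hits))) /
        nrow(drivers)
    } else rep_$tp_driver_prop <- 0
  }
  if (nrow(regions) > 0) {
    gr <- regions_granges(regions)
    dhits <- GenomicRanges::findOverlaps(gr, genes_granges(drivers))
    rep_$fp_region_prop <- 1 - length(unique(S4Vectors::queryHits(dhits))) /
      nrow(regions)
    if (nrow(all_genes) > 0) {
      ghits <- GenomicRanges::findOverlaps(gr, genes_granges(all_genes))
      ng <- tabulate(S4Vectors::queryHits(ghits), nbins = nrow(regions))
      is_driver <- all_genes$gene_name %in% drivers$gene_name
      nd <- tabulate(S4Vectors::queryHits(ghits)[
        is_driver[S4Vectors::subjectHits(ghits)]], nbins = nrow(regions))
      with_genes <- ng > 0
      if (any(with_genes)) {
        rep_$mean_driver_fraction <- mean(nd[with_genes] / ng[with_genes])
        rep_$mean_inverse_gene_count <- mean(1 / ng[with_genes])
      }
    }
  }
  structure(rep_, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Driver-recovery metrics over %d region(s), %d driver(s):\n",
              x$n_regions, x$n_drivers))
  cat(sprintf("  driver genes recovered:     %s\n", fmt6(x$tp_driver_prop)))
  cat(sprintf("  regions with no driver:     %s\n", fmt6(x$fp_region_prop)))
  cat(sprintf("  mean driver fraction:       %s\n", fmt6(x$mean_driver_fraction)))
  cat(sprintf("  mean 1/genes per region:    %s\n", fmt6(x$mean_inverse_gene_count)))
  invisible(x)
}

#' Cyclic-permutation gene-set enrichment test
#'
#' The statistic is the number of gene-set members overlapped by at least one
#' called region. The null rotates all regions jointly by a random offset
#' along the concatenated genome (wrapping; inter-region spacing is
#' preserved) and the p-value is `(1 + #{rotations with statistic >=
#' observed}) / (1 + n_rot)`.
#'
#' @param regions a called-region table.
#' @param gene_set gene table of the set being tested.
#' @param chrom_lengths named vector of chromosome lengths (the rotation
#'   space); names define the concatenation order.
#' @param n_rot number of random rotations.
#' @param seed optional seed.
#' @param offsets optional numeric vector of rotation offsets overriding the
#'   random draw (for exhaustive enumeration on small genomes).
#' @return list with `p`, `observed`, and `null` (statistic per rotation).
#' @export
enrichment_test <- function(regions, gene_set, chrom_lengths, n_rot = 10000,
                            seed = NULL, offsets = NULL) {
  stopifnot(n_rot >= 1 || !is.null(offsets))
  G <- sum(chrom_lengths)
  off0 <- c(0, cumsum(chrom_lengths))[seq_along(chrom_lengths)]
  names(off0) <- names(chrom_lengths)
  gs <- gene_set$start + off0[gene_set$chrom]
  ge <- gene_set$end + off0[gene_set$chrom]
  count_overlap <- function(rs, re) {
    # genes overlapped by >= 1 region, on the concatenated line
    if (length(rs) == 0) return(0L)
    hit <- rep(FALSE, length(gs))
    for (k in seq_along(rs))
      hit <- hit | (gs < re[k] & ge > rs[k])
    sum(hit)
  }
  rs0 <- regions$start + off0[regions$chrom]
  re0 <- regions$end + off0[regions$chrom]
  rotate <- function(o) {
    rs <- (rs0 + o) %% G
    re <- rs + (re0 - rs0)
    wrap <- re > G                         # split regions crossing the end
    if (any(wrap)) {
      rs <- c(rs[!wrap], rs[wrap], rep(0, sum(wrap)))
      re <- c(re[!wrap], rep(G, sum(wrap)), re[wrap] - G)
    }
    count_overlap(rs, re)
  }
  observed <- count_overlap(rs0, re0)
  if (nrow(regions) == 0)
    return(list(p = 1, observed = 0L, null = integer(0)))
  if (is.null(offsets)) {
    if (!is.null(seed)) set.seed(seed)
    offsets <- floor(runif(n_rot, 0, G))
  }
  null <- vapply(offsets, rotate, numeric(1))
  list(p = (1 + sum(null >= observed)) / (1 + length(null)),
       observed = observed, null = null)
}
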