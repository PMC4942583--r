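# Calling local-maximum segments, region-level FDR control via the adaptive
# threshold iteration, and iterative refinement of the null model.

#' Call local-maximum segments as recurrent regions
#'
#' A segment is a local maximum when it is bordered by a positive jump on its
#' left and a negative jump on its right. A chromosome-end segment qualifies
#' when its single internal jump points uphill into it (positive left jump for
#' the last segment, negative right jump for the first). Region coordinates
#' run from the first base of the segment's first probe to the base before the
#' first probe after the segment (0-based half-open); a terminal segment ends
#' one base after its last probe.
#'
#' @param seg a `segmentation` from [segment_genome()].
#' @param direction label for the calls; default from the aggregate's sign
#'   mode recorded in the probe map context ("gain" unless segmenting a loss
#'   matrix).
#' @return a called-region data frame: `chrom`, `start`, `end`, `direction`,
#'   `amplitude`, `left_sig`, `right_sig` (NA at chromosome ends),
#'   `start_probe`, `end_probe`, `left_boundary`, `right_boundary`.
#' @export
call_local_maxima <- function(seg, direction = "gain") {
  s <- seg$segments
  b <- seg$boundaries
  probes <- seg$probes
  cs <- chrom_starts(probes)
  ord <- attr(probes, "chrom_order")
  rows <- vector("list", length(ord))
  for (ci in seq_along(ord)) {
    sc <- s[s$chrom == ord[ci], , drop = FALSE]
    bc <- b[b$chrom == ord[ci], , drop = FALSE]
    ns <- nrow(sc)
    if (ns < 2) next                       # single flat segment: nothing to call
    left_jump <- c(NA, bc$jump)            # jump at segment's left boundary
    right_jump <- c(bc$jump, NA)
    left_sig <- c(NA, bc$sig)
    right_sig <- c(bc$sig, NA)
    is_max <- (is.na(left_jump) | left_jump > 0) &
              (is.na(right_jump) | right_jump < 0)
    idx <- which(is_max)
    if (length(idx) == 0) next
    end_bp <- ifelse(sc$end_probe[idx] < cs[ci + 1],
                     probes$pos[sc$end_probe[idx] + 1L],
                     probes$pos[sc$end_probe[idx]] + 1)
    rows[[ci]] <- data.frame(
      chrom = ord[ci],
      start = probes$pos[sc$start_probe[idx] + 1L],
      end = end_bp,
      direction = direction,
      amplitude = sc$amplitude[idx],
      left_sig = left_sig[idx], right_sig = right_sig[idx],
      start_probe = sc$start_probe[idx], end_probe = sc$end_probe[idx],
      left_boundary = c(NA, bc$boundary)[idx],
      right_boundary = c(bc$boundary, NA)[idx],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), amplitude = numeric(),
                      left_sig = numeric(), right_sig = numeric(),
                      start_probe = integer(), end_probe = integer(),
                      left_boundary = integer(), right_boundary = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("called_regions", "data.frame")
  out
}

#' Adapt the global threshold E to a target FDR
#'
#' The expected number of false-positive called regions at threshold `E` is
#' bounded by `E/2`, so `E = n * 2 * fdr` keeps the expected false positives
#' below `fdr * n` for `n` called regions. Starting from `E = 2 * fdr`, the
#' threshold is re-derived from the region count until that count is stable
#' (Benjamini-Hochberg-style iteration). With a count of 100 at FDR 0.25 the
#' iteration settles at `E = 100 * 2 * 0.25 = 50`.
#'
#' @param count_regions function of `E` returning either an integer region
#'   count or a list with elements `n` and `regions`.
#' @param fdr target false discovery rate on called regions, in (0, 1).
#' @param max_iter iteration cap.
#' @return list with `E` (final threshold), `n`, `regions` (possibly `NULL`
#'   when `count_regions` returns bare counts) and `trajectory`
#'   (data frame of visited `E` and `n`).
#' @export
adaptive_threshold <- function(count_regions, fdr = 0.25, max_iter = 50) {
  stopifnot(is.function(count_regions), fdr > 0, fdr < 1, max_iter >= 1)
  eval_at <- function(E) {
    r <- count_regions(E)
    if (is.list(r)) list(n = as.integer(r$n), regions = r$regions)
    else list(n = as.integer(r), regions = NULL)
  }
  E <- 2 * fdr
  res <- eval_at(E)
  traj <- data.frame(iter = 0L, E = E, n = res$n)
  if (res$n == 0)
    return(list(E = E, n = 0L, regions = res$regions, trajectory = traj))
  seen_n <- res$n
  n <- res$n
  for (k in seq_len(max_iter)) {
    E2 <- n * 2 * fdr
    res2 <- eval_at(E2)
    traj <- rbind(traj, data.frame(iter = k, E = E2, n = res2$n))
    if (res2$n == n)
      return(list(E = E2, n = n, regions = res2$regions, trajectory = traj))
    if (res2$n %in% seen_n) {             # oscillation: settle on the smaller count
      warning("adaptive threshold oscillates; using the smaller region count")
      nmin <- min(res2$n, n)
      E3 <- nmin * 2 * fdr
      res3 <- eval_at(E3)
      traj <- rbind(traj, data.frame(iter = k + 1L, E = E3, n = res3$n))
      return(list(E = E3, n = res3$n, regions = res3$regions, trajectory = traj))
    }
    seen_n <- c(seen_n, res2$n)
    n <- res2$n
  }
  warning("adaptive threshold did not stabilize in ", max_iter, " iterations")
  list(E = n * 2 * fdr, n = n, regions = res2$regions, trajectory = traj)
}

#' Delete called recurrent breaks from sample profiles
#'
#' For each sample, every sample-level breakpoint (run boundary of that
#' sample's piecewise-constant profile, within a chromosome) that falls inside
#' a called recurrent-break window is removed by replacing the flanking runs
#' with their length-weighted mean. The edited matrix is used only for
#' re-estimating the null model, which would otherwise be biased by driver
#' breaks. Applying the operation twice with the same windows equals applying
#' it once.
#'
#' @param m a `cn_matrix`.
#' @param boundaries integer vector of called break boundaries (boundary `b`
#'   cuts between genome_order `b-1` and `b`).
#' @param margin window half-width in probes around each called boundary
#'   (default 0: the boundary's own inter-probe interval).
#' @return the edited `cn_matrix`.
#' @export
refine_null <- function(m, boundaries, margin = 0) {
  stopifnot(inherits(m, "cn_matrix"))
  boundaries <- unique(as.integer(boundaries[!is.na(boundaries)]))
  if (length(boundaries) == 0) return(m)
  cs <- chrom_starts(m$probes)
  v <- m$values
  in_window <- function(b) {
    ok <- rep(FALSE, length(b))
    for (w in boundaries) ok <- ok | (abs(b - w) <= margin)
    ok
  }
  for (s in seq_len(nrow(v))) {
    for (c in seq_len(length(cs) - 1)) {
      idx <- (cs[c] + 1):cs[c + 1]
      x <- v[s, idx]
      r <- rle(x)
      if (length(r$lengths) < 2) next
      bnd <- cs[c] + cumsum(r$lengths)[-length(r$lengths)]  # boundary indices b
      kill <- in_window(bnd)
      if (!any(kill)) next
      grp <- cumsum(c(TRUE, !kill))       # runs joined across killed boundaries
      len <- tapply(r$lengths, grp, sum)
      val <- tapply(r$lengths * r$values, grp, sum) / len
      v[s, idx] <- rep(as.numeric(val), as.integer(len))
    }
  }
  m$values <- v
  m
}

# one direction (gains or losses) of the full pipeline: estimate curves,
# adapt E, refine the null and repeat until the region count converges.
call_direction <- function(m_dir, cfg, fdr, max_bh_iters, max_null_refinements,
                           direction, refine_margin = 0, verbose = FALSE) {
  agg <- aggregate_profile(m_dir)
  m_null <- m_dir
  prev_n <- -1L
  iterations <- list()
  fit <- NULL
  for (k in 0:max_null_refinements) {
    table <- estimate_euler_curves(m_null, cfg)
    res <- adaptive_threshold(function(E) {
      seg <- segment_genome(agg, table, E)
      regs <- call_local_maxima(seg, direction)
      list(n = nrow(regs), regions = list(seg = seg, regions = regs))
    }, fdr = fdr, max_iter = max_bh_iters)
    regs <- res$regions$regions
    iterations[[k + 1]] <- data.frame(refinement = k, E = res$E, n = res$n)
    if (verbose)
      message(sprintf("[%s] refinement %d: E = %.4g, %d region(s)",
                      direction, k, res$E, res$n))
    fit <- list(E = res$E, n = res$n, regions = regs,
                segmentation = res$regions$seg, table = table,
                trajectory = res$trajectory)
    if (res$n == prev_n) break
    prev_n <- res$n
    if (k < max_null_refinements) {
      m_new <- refine_null(m_dir, c(regs$left_boundary, regs$right_boundary),
                           margin = refine_margin)
      if (identical(m_new$values, m_null$values)) break  # nothing deleted
      m_null <- m_new
    }
  }
  fit$refinements <- do.call(rbind, iterations)
  fit
}

#' Annotate called regions with overlapping genes
#'
#' Any intersection of at least one base pair counts as an overlap.
#'
#' @param regions a called-region table.
#' @param genes a gene table from [read_genes()] (0-based half-open).
#' @return `regions` with `genes` (comma-separated names) and `n_genes` columns.
#' @export
annotate_regions <- function(regions, genes) {
  regions$genes <- rep("", nrow(regions))
  regions$n_genes <- rep(0L, nrow(regions))
  if (nrow(regions) == 0 || is.null(genes) || nrow(genes) == 0) return(regions)
  hits <- GenomicRanges::findOverlaps(regions_granges(regions), genes_granges(genes))
  if (length(hits) > 0) {
    by_region <- split(genes$gene_name[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
    for (q in names(by_region)) {
      i <- as.integer(q)
      regions$genes[i] <- paste(by_region[[q]], collapse = ",")
      regions$n_genes[i] <- length(by_region[[q]])
    }
  }
  regions
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1,
                                          end = regions$end))
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(start = genes$start + 1,
                                          end = genes$end))
}
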