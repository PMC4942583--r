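# Main fit: the full recurrent-break detection pipeline.

#' Detect recurrently aberrated regions in a copy-number cohort
#'
#' Splits the cohort into gains and losses, and for each direction: estimates
#' expected-Euler-characteristic curves under the cyclic-shift null, segments
#' the aggregate profile at a threshold `E` adapted to the requested
#' region-level FDR, calls local-maximum segments, then iteratively refines
#' the null by deleting the called breaks from the sample profiles and
#' re-estimating, until the region count converges (or
#' `max_null_refinements` passes). Called regions are finally annotated with
#' overlapping genes and filtered: regions overlapping no gene (when a gene
#' table is supplied and `require_gene_overlap` is on) and regions wider than
#' `max_region_width` are dropped.
#'
#' Both directions draw their permutation offsets from the same derived seed,
#' so running the pipeline on the negated matrix mirrors gains and losses
#' exactly.
#'
#' @param m a `cn_matrix` with `sign_mode = "raw"` (see [read_seg()]).
#' @param genes optional gene table ([read_genes()]) for annotation/filtering.
#' @param fdr target region-level false discovery rate (default 0.25).
#' @param n_perm cyclic-shift permutations per null estimation.
#' @param seed integer seed making the run deterministic.
#' @param scale_grid,threshold_grid optional grids, see [null_config()].
#' @param max_bh_iters cap on adaptive-threshold iterations.
#' @param max_null_refinements cap on null-refinement passes (default 3);
#'   refinement also stops as soon as a pass deletes no sample breakpoint.
#' @param refine_margin half-width, in probes, of the deletion window around
#'   each called break boundary used by [refine_null()] (default 0: the
#'   boundary's own inter-probe interval).
#' @param max_region_width regions wider than this many base pairs are
#'   filtered out (default 10 Mbp); `Inf` disables.
#' @param require_gene_overlap drop regions overlapping no gene (only
#'   effective when `genes` is supplied).
#' @param verbose log the threshold trajectory per refinement.
#' @return a `breakrec` object with elements `gains`, `losses` (filtered
#'   called-region tables), `gains_fit`, `losses_fit` (threshold, trajectory,
#'   segmentation, curve table), and `config`.
#' @examples
#' sim <- simulate_cohort(8, genome = genome_model(c(chr1 = 3e7), 3e4),
#'                        drivers = NULL, seed = 1)
#' fit <- breakrec(sim$matrix, fdr = 0.25, n_perm = 20, seed = 1)
#' fit
#' @export
breakrec <- function(m, genes = NULL, fdr = 0.25, n_perm = 100, seed = NULL,
                     scale_grid = NULL, threshold_grid = NULL,
                     max_bh_iters = 50, max_null_refinements = 3,
                     refine_margin = 0, max_region_width = 1e7,
                     require_gene_overlap = !is.null(genes),
                     verbose = FALSE) {
  stopifnot(inherits(m, "cn_matrix"))
  if (m$sign_mode != "raw")
    stop("breakrec() expects an unsplit (raw) matrix")
  split <- split_gains_losses(m)
  dir_seed <- if (is.null(seed)) NULL else as.integer(seed)
  cfg <- null_config(n_perm = n_perm, scale_grid = scale_grid,
                     threshold_grid = threshold_grid)
  fits <- list()
  for (dir in c("gain", "loss")) {
    if (!is.null(dir_seed)) set.seed(dir_seed)
    m_dir <- if (dir == "gain") split$gains else split$losses
    fits[[dir]] <- call_direction(m_dir, cfg, fdr, max_bh_iters,
                                  max_null_refinements, dir,
                                  refine_margin = refine_margin,
                                  verbose = verbose)
  }
  finalize <- function(fit) {
    regs <- annotate_regions(fit$regions, genes)
    filter_regions(regs, max_width = max_region_width,
                   require_gene_overlap = require_gene_overlap && !is.null(genes))
  }
  structure(list(
    gains = finalize(fits$gain), losses = finalize(fits$loss),
    gains_fit = fits$gain, losses_fit = fits$loss,
    config = list(fdr = fdr, n_perm = n_perm, seed = seed,
                  max_bh_iters = max_bh_iters,
                  max_null_refinements = max_null_refinements,
                  max_region_width = max_region_width,
                  require_gene_overlap = require_gene_overlap),
    n_samples = nrow(m$values), P = ncol(m$values),
    call = match.call()),
    class = "breakrec")
}

#' @export
print.breakrec <- function(x, ...) {
  cat("Recurrent copy-number break detection\n")
  cat(sprintf("  %d sample(s), %d probes; FDR = %g, %d permutation(s)\n",
              x$n_samples, x$P, x$config$fdr, x$config$n_perm))
  cat(sprintf("  gains:  E = %.4g, %d region(s) after filtering\n",
              x$gains_fit$E, nrow(x$gains)))
  cat(sprintf("  losses: E = %.4g, %d region(s) after filtering\n",
              x$losses_fit$E, nrow(x$losses)))
  invisible(x)
}

#' @export
summary.breakrec <- function(object, ...) {
  x <- object
  cat("Recurrent copy-number break detection\n\n")
  for (dir in c("gains", "losses")) {
    fit <- x[[paste0(dir, "_fit")]]
    cat(sprintf("%s: final E = %.4g after %d refinement pass(es)\n", dir,
                fit$E, nrow(fit$refinements)))
    print(fit$refinements, row.names = FALSE)
    regs <- x[[dir]]
    cat(sprintf("%d filtered region(s)\n", nrow(regs)))
    if (nrow(regs) > 0) {
      show <- regs[, c("chrom", "start", "end", "amplitude", "left_sig",
                       "right_sig", "genes")]
      print(utils::head(show, 20), row.names = FALSE)
      if (nrow(regs) > 20) cat("  ...\n")
    }
    cat("\n")
  }
  invisible(x)
}

#' Plot the segmented aggregate profile of a fit
#'
#' Aggregate profile (grey), segmented amplitudes (red for gains, blue for
#' losses, mirrored below zero) and called regions (shaded).
#'
#' @param x a `breakrec` object.
#' @param direction "gain" or "loss".
#' @param chrom optional chromosome to restrict to.
#' @param ... passed to [plot()].
#' @export
plot.breakrec <- function(x, direction = c("gain", "loss"), chrom = NULL, ...) {
  direction <- match.arg(direction)
  fit <- if (direction == "gain") x$gains_fit else x$losses_fit
  seg <- fit$segmentation
  probes <- seg$probes
  s <- seg$segments
  if (!is.null(chrom)) s <- s[s$chrom == chrom, , drop = FALSE]
  sgn <- if (direction == "gain") 1 else -1
  ymax <- max(s$amplitude, 0) * 1.05 + 1e-9
  plot(range(c(s$start_probe + 1, s$end_probe)), c(0, sgn * ymax), type = "n",
       xlab = "probe (genome order)",
       ylab = sprintf("aggregate %s amplitude", direction), ...)
  regs <- if (direction == "gain") x$gains else x$losses
  if (!is.null(chrom)) regs <- regs[regs$chrom == chrom, , drop = FALSE]
  if (nrow(regs) > 0)
    graphics::rect(regs$start_probe + 1, 0, regs$end_probe, sgn * ymax,
                   col = "moccasin", border = NA)
  graphics::segments(s$start_probe + 1, sgn * s$amplitude,
                     s$end_probe, sgn * s$amplitude,
                     col = if (direction == "gain") "red" else "blue", lwd = 2)
  graphics::abline(v = chrom_starts(probes)[-1] + 0.5, col = "grey", lty = 3)
  invisible(x)
}
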