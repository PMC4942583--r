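# End-to-end benchmark: simulate -> call -> evaluate at multiple sample sizes.

#' Benchmark driver recovery on simulated cohorts
#'
#' For each sample size and replicate: draw a fresh gene table, pick driver
#' genes with normal proliferation coefficients, simulate a cohort under the
#' clonal-evolution model, run the full calling pipeline at the requested
#' FDR, filter the called regions (gene overlap, maximum width) and score
#' driver recovery with [compute_metrics()] over the regions of both
#' directions combined.
#'
#' @param sample_sizes integer vector of cohort sizes.
#' @param replicates cohorts per sample size.
#' @param genome a [genome_model()]; default is the desk-scale genome
#'   (3 chromosomes x 100 Mb, 3 kb probe spacing).
#' @param n_genes genes in the annotation; drivers are a subset.
#' @param n_drivers driver genes per cohort.
#' @param coeff_sd driver-coefficient standard deviation.
#' @param fdr target region-level FDR.
#' @param n_perm permutations per null estimation.
#' @param max_region_width region-width filter in base pairs.
#' @param seed master seed; per-run seeds are derived from it.
#' @param verbose print one line per run.
#' @return data frame with one row per (sample size, replicate): the metric
#'   fields of [compute_metrics()] plus `n_samples`, `replicate`, `seed`,
#'   `n_regions_gain`, `n_regions_loss`.
#' @export
benchmark <- function(sample_sizes = c(20, 50, 100), replicates = 3,
                      genome = genome_model_scaled(), n_genes = 300,
                      n_drivers = 20, coeff_sd = 1, fdr = 0.25, n_perm = 50,
                      max_region_width = 1e7, seed = 1, verbose = FALSE) {
  stopifnot(replicates >= 1)
  rows <- list()
  run_id <- 0L
  for (n in sample_sizes) {
    for (rep_i in seq_len(replicates)) {
      run_id <- run_id + 1L
      run_seed <- (as.integer(seed) * 1000L + run_id) %% .Machine$integer.max
      set.seed(run_seed)
      genes <- random_genes(genome, n_genes)
      drivers <- driver_set(genome, n_drivers, coeff_sd = coeff_sd,
                            genes = genes)
      sim <- simulate_cohort(n, genome = genome, drivers = drivers)
      fit <- breakrec(sim$matrix, genes = genes, fdr = fdr, n_perm = n_perm,
                      seed = run_seed, max_region_width = max_region_width)
      regions <- rbind(fit$gains, fit$losses)
      met <- compute_metrics(regions, drivers, genes)
      if (verbose)
        message(sprintf("n = %d rep %d: %d region(s), fp = %s, tp = %s",
                        n, rep_i, met$n_regions, fmt6(met$fp_region_prop),
                        fmt6(met$tp_driver_prop)))
      rows[[run_id]] <- data.frame(
        n_samples = n, replicate = rep_i, seed = run_seed,
        n_regions = met$n_regions,
        n_regions_gain = nrow(fit$gains), n_regions_loss = nrow(fit$losses),
        tp_driver_prop = met$tp_driver_prop,
        fp_region_prop = met$fp_region_prop,
        mean_driver_fraction = met$mean_driver_fraction,
        mean_inverse_gene_count = met$mean_inverse_gene_count)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
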