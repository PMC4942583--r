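# Clonal-evolution copy-number simulator.
#
# A sample evolves from a diploid dominant clone by repeated rounds of
# randomization (descendants each acquire random aberrations) and selection
# (the descendant with the highest proliferation score becomes the new
# dominant clone). A gene's contribution to proliferation is its coefficient
# times the length-weighted mean copy-number fold change 2^(log2 ratio) over
# the gene body; positive coefficients mark oncogenes, negative tumour
# suppressors. With a single descendant per round there is no selection and
# the model degenerates to neutral passenger accumulation.

#' Genome model for simulation
#'
#' @param lengths named numeric vector of chromosome lengths in base pairs.
#' @param spacing probe spacing in base pairs used when rendering profiles.
#' @return a `genome_model`.
#' @export
genome_model <- function(lengths, spacing = 3000) {
  stopifnot(length(lengths) >= 1, all(lengths > 0), !is.null(names(lengths)),
            spacing >= 1)
  structure(list(chrom = names(lengths), lengths = lengths, spacing = spacing),
            class = "genome_model")
}

#' Desk-scale default genome: 3 chromosomes of 100 Mb, 3 kb probe spacing
#' @export
genome_model_scaled <- function() {
  genome_model(c(chr1 = 1e8, chr2 = 1e8, chr3 = 1e8), spacing = 3000)
}

#' Human-sized genome preset (approximate GRCh37 chromosome lengths)
#' @param spacing probe spacing in base pairs.
#' @export
genome_model_human <- function(spacing = 3e4) {
  lengths <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
               115, 107, 103, 90, 81, 78, 59, 63, 48, 51, 155) * 1e6
  names(lengths) <- c(paste0("chr", 1:22), "chrX")
  genome_model(lengths, spacing)
}

#' Probe map implied by a genome model
#' @param genome a `genome_model`.
#' @return a `probe_map` with probes every `spacing` bases.
#' @export
probe_map_from_genome <- function(genome) {
  pos <- lapply(genome$lengths, function(L) seq(0, L - 1, by = genome$spacing))
  chrom <- rep(genome$chrom, lengths(pos))
  pos <- unlist(pos, use.names = FALSE)
  new_probe_map(paste0(chrom, "_", format(pos, scientific = FALSE, trim = TRUE)),
                chrom, pos, genome$chrom)
}

#' Aberration model
#'
#' Parametric stand-in for empirical tumour aberration width and magnitude
#' distributions: focal events with log-uniform widths (probability
#' `p_focal`) mixed with broad arm-scale events, exponential |log2 ratio|
#' magnitudes, and a fair amplification/deletion coin by default. Broad
#' events take a width that is a uniform fraction (`broad_frac_range`) of
#' their chromosome and are placed uniformly rather than pinned to fixed arm
#' boundaries: fixed boundaries would make break positions recur at the
#' centromere even without selection, so passenger breaks would no longer be
#' exchangeable.
#'
#' @param p_focal probability that an event is focal (vs broad).
#' @param focal_range width range (bp) of the log-uniform focal component.
#' @param broad_frac_range chromosome-length fraction range of broad events.
#' @param log2_mean mean of the exponential |log2 ratio| magnitude.
#' @param p_gain probability that an event is an amplification.
#' @export
aberration_model <- function(p_focal = 0.9, focal_range = c(1e4, 1e7),
                             broad_frac_range = c(0.25, 0.5),
                             log2_mean = 0.35, p_gain = 0.5) {
  stopifnot(p_focal >= 0, p_focal <= 1, focal_range[1] > 0,
            focal_range[2] >= focal_range[1], log2_mean > 0,
            p_gain >= 0, p_gain <= 1,
            broad_frac_range[1] > 0, broad_frac_range[2] <= 1)
  structure(list(p_focal = p_focal, focal_range = focal_range,
                 broad_frac_range = broad_frac_range,
                 log2_mean = log2_mean, p_gain = p_gain),
            class = "aberration_model")
}

#' Random gene intervals on a genome
#'
#' Chromosome chosen proportional to length, start uniform, lengths
#' log-uniform over `len_range` (clipped at chromosome ends).
#'
#' @param genome a `genome_model`.
#' @param n number of genes.
#' @param len_range gene length range in base pairs.
#' @param prefix gene-name prefix.
#' @return a gene table (`gene_name`, `chrom`, `start`, `end`).
#' @export
random_genes <- function(genome, n, len_range = c(5e3, 5e5), prefix = "gene") {
  ci <- sample.int(length(genome$lengths), n, replace = TRUE,
                   prob = genome$lengths)
  len <- exp(runif(n, log(len_range[1]), log(len_range[2])))
  L <- genome$lengths[ci]
  start <- floor(runif(n, 0, pmax(L - len, 1)))
  g <- data.frame(gene_name = paste0(prefix, "_", seq_len(n)),
                  chrom = genome$chrom[ci], start = start,
                  end = pmin(ceiling(start + len), L), stringsAsFactors = FALSE)
  g[order(match(g$chrom, genome$chrom), g$start), , drop = FALSE]
}

#' Driver genes with proliferation coefficients
#'
#' Coefficients are drawn from a normal distribution with mean 0; positive
#' values represent oncogenes, negative tumour suppressors.
#'
#' @param genome a `genome_model`.
#' @param n_drivers number of driver genes.
#' @param coeff_sd standard deviation of the coefficient distribution.
#' @param genes optional gene table to sample drivers from; otherwise random
#'   intervals are drawn via [random_genes()].
#' @return a gene table with an extra `coef` column.
#' @export
driver_set <- function(genome, n_drivers = 100, coeff_sd = 1, genes = NULL) {
  d <- if (is.null(genes)) {
    random_genes(genome, n_drivers, prefix = "driver")
  } else {
    stopifnot(nrow(genes) >= n_drivers)
    genes[sort(sample.int(nrow(genes), n_drivers)), , drop = FALSE]
  }
  d$coef <- rnorm(nrow(d), 0, coeff_sd)
  rownames(d) <- NULL
  d
}

new_clone <- function(genome) {
  profile <- lapply(genome$lengths, function(L) list(bp = c(0, L), val = 0))
  structure(list(genome = genome, profile = profile,
                 ev = list(chrom = character(), start = numeric(),
                           end = numeric(), delta = numeric())),
            class = "clone_profile")
}

#' Event log of a clone profile
#' @param clone a `clone_profile`.
#' @return data frame of accumulated aberrations (`chrom`, `start`, `end`,
#'   `delta`), in application order.
#' @export
event_log <- function(clone) {
  as.data.frame(clone$ev, stringsAsFactors = FALSE)
}

#' @export
print.clone_profile <- function(x, ...) {
  cat(sprintf("Clone profile: %d chromosome(s), %d accumulated event(s)\n",
              length(x$profile), length(x$ev$start)))
  invisible(x)
}

# insert a breakpoint into a per-chromosome piecewise profile
insert_bp <- function(pr, x) {
  i <- findInterval(x, pr$bp, rightmost.closed = FALSE)
  if (x > pr$bp[i] && x < pr$bp[length(pr$bp)]) {
    pr$bp <- append(pr$bp, x, after = i)
    pr$val <- append(pr$val, pr$val[i], after = i)
  }
  pr
}

#' Apply one copy-number aberration to a clone profile
#'
#' Adds `delta` to the log2 ratio on `[start, end)`; disjoint aberrations
#' commute and overlapping ones add.
#'
#' @param clone a `clone_profile`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval in base pairs.
#' @param delta log2-ratio increment.
#' @return the updated `clone_profile`.
#' @export
apply_aberration <- function(clone, chrom, start, end, delta) {
  L <- clone$genome$lengths[[chrom]]
  stopifnot(start >= 0, end <= L, start < end)
  pr <- clone$profile[[chrom]]
  pr <- insert_bp(pr, start)
  pr <- insert_bp(pr, end)
  sel <- pr$bp[-length(pr$bp)] >= start & pr$bp[-length(pr$bp)] < end
  pr$val[sel] <- pr$val[sel] + delta
  clone$profile[[chrom]] <- pr
  clone$ev$chrom <- c(clone$ev$chrom, chrom)
  clone$ev$start <- c(clone$ev$start, start)
  clone$ev$end <- c(clone$ev$end, end)
  clone$ev$delta <- c(clone$ev$delta, delta)
  clone
}

# length-weighted mean of 2^log2ratio over [a, b) of one chromosome profile
fold_over <- function(pr, a, b) {
  bp <- pmin(pmax(pr$bp, a), b)
  len <- diff(bp)
  keep <- len > 0
  if (!any(keep)) return(1)
  sum(len[keep] * 2^pr$val[keep]) / (b - a)
}

#' Proliferation score of a clone
#'
#' Sum over driver genes of coefficient times the length-weighted mean
#' copy-number fold change `2^log2ratio` over the gene body; a diploid clone
#' scores `sum(coef)`.
#'
#' @param clone a `clone_profile`.
#' @param drivers a [driver_set()] table.
#' @return numeric score.
#' @export
proliferation_score <- function(clone, drivers) {
  f <- vapply(seq_len(nrow(drivers)), function(i)
    fold_over(clone$profile[[drivers$chrom[i]]], drivers$start[i], drivers$end[i]),
    numeric(1))
  sum(drivers$coef * f)
}

# draw n random aberrations: chromosome by length, start uniform, focal or
# whole-arm width, signed exponential magnitude
draw_events <- function(genome, ab_model, n) {
  ci <- sample.int(length(genome$lengths), n, replace = TRUE,
                   prob = genome$lengths)
  L <- genome$lengths[ci]
  loc <- runif(n, 0, L)
  focal <- runif(n) < ab_model$p_focal
  width <- ifelse(focal,
                  exp(runif(n, log(ab_model$focal_range[1]),
                            log(ab_model$focal_range[2]))),
                  L * runif(n, ab_model$broad_frac_range[1],
                            ab_model$broad_frac_range[2]))
  start <- pmax(loc - width / 2, 0)
  end <- pmin(loc + width / 2, L)
  delta <- rexp(n, 1 / ab_model$log2_mean) *
    ifelse(runif(n) < ab_model$p_gain, 1, -1)
  data.frame(chrom = genome$chrom[ci], start = floor(start),
             end = pmax(ceiling(end), floor(start) + 1), delta = delta,
             stringsAsFactors = FALSE)
}

# fold change of one driver under parent profile plus a set of candidate
# events (clipped to the gene); used for incremental descendant scoring
fold_with_events <- function(pr, gs, ge, ev_start, ev_end, ev_delta) {
  cuts <- sort(unique(c(gs, ge, pr$bp[pr$bp > gs & pr$bp < ge],
                        pmin(pmax(c(ev_start, ev_end), gs), ge))))
  lo <- cuts[-length(cuts)]
  len <- diff(cuts)
  base <- pr$val[findInterval(lo, pr$bp)]
  for (k in seq_along(ev_delta))
    base <- base + ev_delta[k] * (lo >= ev_start[k] & lo < ev_end[k])
  sum(len * 2^base) / (ge - gs)
}

#' Evolve one sample by randomization and selection
#'
#' Each round derives `descendants` clones from the dominant clone by adding
#' `n_aberrations` random aberrations each, scores them with
#' [proliferation_score()] and promotes the highest-scoring descendant. With
#' `descendants = 1` the process is neutral passenger accumulation
#' (no selection; `drivers` may be `NULL`).
#'
#' @param genome a `genome_model`.
#' @param drivers a [driver_set()] table, or `NULL` in passenger-only mode.
#' @param ab_model an [aberration_model()].
#' @param rounds number of randomization/selection rounds.
#' @param descendants descendants per round.
#' @param n_aberrations aberrations added per descendant.
#' @return the final dominant `clone_profile`; its `events` log has
#'   `rounds * n_aberrations` rows and `round_scores` records the winning
#'   (maximal) candidate score per round.
#' @export
simulate_sample <- function(genome, drivers = NULL,
                            ab_model = aberration_model(), rounds = 20,
                            descendants = 100, n_aberrations = 10) {
  stopifnot(rounds >= 1, descendants >= 1, n_aberrations >= 1)
  clone <- new_clone(genome)
  if (descendants > 1 && is.null(drivers))
    stop("selection (descendants > 1) needs a driver set")
  round_scores <- numeric(rounds)
  if (descendants == 1) {
    # neutral accumulation: all events commute, so the profile is built in
    # one pass per chromosome instead of event by event
    ev <- draw_events(genome, ab_model, rounds * n_aberrations)
    for (ch in unique(ev$chrom)) {
      sel <- which(ev$chrom == ch)
      L <- genome$lengths[[ch]]
      bp <- sort(unique(c(0, L, ev$start[sel], ev$end[sel])))
      d <- numeric(length(bp))
      i1 <- match(ev$start[sel], bp)
      i2 <- match(ev$end[sel], bp)
      for (k in seq_along(sel)) {
        d[i1[k]] <- d[i1[k]] + ev$delta[sel[k]]
        d[i2[k]] <- d[i2[k]] - ev$delta[sel[k]]
      }
      clone$profile[[ch]] <- list(bp = bp,
                                  val = cumsum(d[seq_len(length(bp) - 1)]))
    }
    clone$ev <- list(chrom = ev$chrom, start = ev$start, end = ev$end,
                     delta = ev$delta)
    clone$round_scores <- rep(NA_real_, rounds)
    return(clone)
  }
  # cache per-driver fold changes of the dominant clone
  f <- vapply(seq_len(nrow(drivers)), function(i)
    fold_over(clone$profile[[drivers$chrom[i]]], drivers$start[i],
              drivers$end[i]), numeric(1))
  for (r in seq_len(rounds)) {
    ev <- draw_events(genome, ab_model, descendants * n_aberrations)
    ev$desc <- rep(seq_len(descendants), each = n_aberrations)
    base_score <- sum(drivers$coef * f)
    # events overlapping any driver, per descendant
    scores <- rep(base_score, descendants)
    ov <- which(outer(seq_len(nrow(ev)), seq_len(nrow(drivers)),
                      function(i, j) ev$chrom[i] == drivers$chrom[j] &
                        ev$start[i] < drivers$end[j] &
                        ev$end[i] > drivers$start[j]),
                arr.ind = TRUE)
    if (nrow(ov) > 0) {
      ov_desc <- ev$desc[ov[, 1]]
      for (d in unique(ov_desc)) {
        rows <- ov[ov_desc == d, , drop = FALSE]
        delta <- 0
        for (j in unique(rows[, 2])) {
          eidx <- which(ev$desc == d & ev$chrom == drivers$chrom[j] &
                          ev$start < drivers$end[j] & ev$end > drivers$start[j])
          full <- ev$start[eidx] <= drivers$start[j] &
                  ev$end[eidx] >= drivers$end[j]
          if (all(full)) {
            # events covering the whole gene scale its fold change exactly
            fj <- f[j] * 2^sum(ev$delta[eidx])
          } else {
            fj <- fold_with_events(clone$profile[[drivers$chrom[j]]],
                                   drivers$start[j], drivers$end[j],
                                   ev$start[eidx], ev$end[eidx], ev$delta[eidx])
          }
          delta <- delta + drivers$coef[j] * (fj - f[j])
        }
        scores[d] <- base_score + delta
      }
    }
    win <- which.max(scores)
    round_scores[r] <- scores[win]
    wev <- ev[ev$desc == win, , drop = FALSE]
    for (i in seq_len(nrow(wev)))
      clone <- apply_aberration(clone, wev$chrom[i], wev$start[i], wev$end[i],
                                wev$delta[i])
    touched <- unique(ov[ev$desc[ov[, 1]] == win, 2])
    for (j in touched)
      f[j] <- fold_over(clone$profile[[drivers$chrom[j]]], drivers$start[j],
                        drivers$end[j])
  }
  clone$round_scores <- round_scores
  clone
}

#' Render a clone profile on a probe grid
#'
#' @param clone a `clone_profile`.
#' @param probes a `probe_map` on the same genome.
#' @return numeric vector of log2 ratios, one per probe.
#' @export
render_profile <- function(clone, probes) {
  out <- numeric(nrow(probes))
  for (ch in unique(probes$chrom)) {
    idx <- probes$chrom == ch
    pr <- clone$profile[[ch]]
    out[idx] <- pr$val[findInterval(probes$pos[idx], pr$bp)]
  }
  out
}

#' Simulate a cohort of copy-number profiles
#'
#' Independent samples evolved with [simulate_sample()] and rendered on the
#' genome's probe grid. With `drivers = NULL` (and `descendants = 1`) the
#' cohort is passenger-only.
#'
#' @inheritParams simulate_sample
#' @param n_samples cohort size.
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @param probes optional precomputed `probe_map` for the genome (avoids
#'   rebuilding it when simulating many cohorts).
#' @return list with `matrix` (a raw `cn_matrix`), `probes`, and `drivers`
#'   (the ground-truth driver table, or `NULL`).
#' @export
simulate_cohort <- function(n_samples, genome = genome_model_scaled(),
                            drivers = NULL, ab_model = aberration_model(),
                            rounds = 20, descendants = if (is.null(drivers)) 1 else 100,
                            n_aberrations = 10, seed = NULL, probes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(probes)) probes <- probe_map_from_genome(genome)
  vals <- matrix(0, nrow = n_samples, ncol = nrow(probes))
  if (n_samples > 0)
    rownames(vals) <- sprintf("sample_%03d", seq_len(n_samples))
  for (s in seq_len(n_samples)) {
    clone <- simulate_sample(genome, drivers, ab_model, rounds, descendants,
                             n_aberrations)
    vals[s, ] <- render_profile(clone, probes)
  }
  list(matrix = structure(list(sample_ids = rownames(vals), values = vals,
                               probes = probes, sign_mode = "raw"),
                          class = "cn_matrix"),
       probes = probes, drivers = drivers)
}

#' Write a simulated cohort to SEG / marker / BED files
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probes <- sim$probes
  mk <- file.path(dir, "markers.tsv")
  utils::write.table(data.frame(probe_id = probes$probe_id,
                                chrom = probes$chrom, pos = probes$pos),
                     mk, sep = "\t", quote = FALSE, row.names = FALSE)
  segf <- file.path(dir, "cohort.seg")
  rows <- list()
  cs <- chrom_starts(probes)
  v <- sim$matrix$values
  for (s in seq_len(nrow(v))) {
    for (c in seq_len(length(cs) - 1)) {
      idx <- (cs[c] + 1):cs[c + 1]
      r <- rle(v[s, idx])
      ends <- cumsum(r$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      pos <- probes$pos[idx]
      # disk coords 1-based inclusive; run extends to the base before the
      # next run's first probe
      end_bp <- c(pos[utils::head(ends, -1) + 1], pos[length(pos)] + 1)
      rows[[length(rows) + 1]] <- data.frame(
        sample = rownames(v)[s], chrom = probes$chrom[idx[1]],
        start = pos[starts] + 1, end = end_bp,
        n_probes = r$lengths, seg_mean = r$values)
    }
  }
  seg <- do.call(rbind, rows)
  seg$seg_mean <- sprintf("%.6g", seg$seg_mean)
  utils::write.table(seg, segf, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(markers = mk, seg = segf)
  if (!is.null(sim$drivers)) {
    bed <- file.path(dir, "drivers.bed")
    writeLines(sprintf("%s\t%d\t%d\t%s", sim$drivers$chrom,
                       as.integer(sim$drivers$start),
                       as.integer(sim$drivers$end), sim$drivers$gene_name), bed)
    paths <- c(paths, drivers = bed)
  }
  invisible(paths)
}
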