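# Fixtures and independent oracles shared across tests.

# probe map with `nper` probes per chromosome, evenly spaced
make_pm <- function(nper = c(12, 10), spacing = 100,
                    chroms = paste0("chr", seq_along(nper))) {
  chrom <- rep(chroms, nper)
  pos <- unlist(lapply(nper, function(n) (seq_len(n) - 1) * spacing))
  breakrec:::new_probe_map(paste0("p", seq_along(chrom)), chrom, pos, chroms)
}

make_cnm <- function(values, pm, sign_mode = "raw") {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  breakrec:::new_cn_matrix(values, pm, sign_mode)
}

# random non-negative cohort on a small genome
rand_gains <- function(nper = c(30, 25), n_samples = 3, seed = 1) {
  set.seed(seed)
  pm <- make_pm(nper)
  v <- matrix(pmax(rnorm(n_samples * sum(nper)), 0), n_samples)
  make_cnm(v, pm, "gains")
}

# brute-force excursion-component counter (independent of rle)
brute_euler <- function(tv, chrom, t0) {
  n <- 0L
  for (g in split(tv, factor(chrom, levels = unique(chrom)))) {
    for (sgn in c(1, -1)) {
      inrun <- FALSE
      for (x in sgn * g) {
        if (x >= t0 && !inrun) { n <- n + 1L; inrun <- TRUE }
        if (x < t0) inrun <- FALSE
      }
    }
  }
  n
}

# O(P^2) agglomerative reference without a priority queue: recompute every
# boundary score each round, merge the largest (leftmost on ties)
reference_segment <- function(agg, table, E) {
  cs <- breakrec:::chrom_starts(agg$probes)
  segs <- data.frame(start = 0:(length(agg$values) - 1), width = 1,
                     sum = agg$values,
                     chrom = rep(seq_len(length(cs) - 1), diff(cs)))
  repeat {
    ns <- nrow(segs)
    if (ns == 1) break
    same <- segs$chrom[-ns] == segs$chrom[-1]
    if (!any(same)) break
    jump <- segs$sum[-1] / segs$width[-1] - segs$sum[-ns] / segs$width[-ns]
    sig <- rep(-Inf, ns - 1)
    idx <- which(same)
    sig[idx] <- suppressWarnings(
      significance(table, abs(jump[idx]),
                   cbind(segs$width[idx], segs$width[idx + 1])))
    if (max(sig) <= E) break
    i <- which.max(sig)                 # first = leftmost on ties
    segs$width[i] <- segs$width[i] + segs$width[i + 1]
    segs$sum[i] <- segs$sum[i] + segs$sum[i + 1]
    segs <- segs[-(i + 1), , drop = FALSE]
  }
  segs
}

# hand-built segmentation object for calling tests
fake_segmentation <- function(amplitudes, widths = NULL, pm = NULL,
                              sigs = NULL) {
  n <- length(amplitudes)
  if (is.null(widths)) widths <- rep(2L, n)
  if (is.null(pm)) pm <- make_pm(sum(widths))
  start <- cumsum(c(0L, widths[-n]))
  segments <- data.frame(chrom = pm$chrom[1], start_probe = start,
                         end_probe = start + widths, width = widths,
                         amplitude = amplitudes, stringsAsFactors = FALSE)
  if (is.null(sigs)) sigs <- rep(0.01, max(n - 1, 0))
  boundaries <- if (n > 1) {
    data.frame(boundary = segments$end_probe[seq_len(n - 1)],
               chrom = pm$chrom[1], jump = diff(amplitudes), sig = sigs,
               stringsAsFactors = FALSE)
  } else {
    data.frame(boundary = integer(), chrom = character(), jump = numeric(),
               sig = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(segments = segments, boundaries = boundaries, E = 1,
                 probes = pm, table_hash = ""), class = "segmentation")
}
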