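# The break-recurrence statistic and its permutation null.
#
# The aggregate profile is the per-probe sum of log2 ratios over samples. A
# boundary b (between genome_order b-1 and b) at scale w = (w_L, w_R) scores
# t_w(b) = mean(aggregate over the w_R probes right of b) -
#          mean(aggregate over the w_L probes left of b),
# the jump a piecewise-constant fit would take there. Under the cyclic-shift
# null (each sample's profile rotated by an independent random offset over the
# concatenated genome) break locations are independent across samples while
# within-sample structure is retained; the expected number of excursion-set
# components of the t-track above |t| (the expected Euler characteristic)
# serves as the significance of an observed break.

#' Aggregate (sum) a copy-number cohort over samples
#'
#' @param m a `cn_matrix`.
#' @return an `aggregate_profile`: per-probe sums, the probe map and the
#'   number of samples.
#' @export
aggregate_profile <- function(m) {
  stopifnot(inherits(m, "cn_matrix"), nrow(m$values) >= 1)
  structure(list(values = colSums(m$values), probes = m$probes,
                 n_samples = nrow(m$values), sign_mode = m$sign_mode),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat(sprintf("Aggregate %s profile over %d sample(s), %d probes\n",
              x$sign_mode, x$n_samples, length(x$values)))
  invisible(x)
}

check_window <- function(agg, boundary, w) {
  stopifnot(length(w) == 2, all(w >= 1))
  P <- length(agg$values)
  if (boundary < 1 || boundary > P - 1) stop("boundary out of range")
  cs <- chrom_starts(agg$probes)
  c_id <- findInterval(boundary - 1, cs, left.open = FALSE)  # chromosome of left probe
  c0 <- cs[c_id]; c1 <- cs[c_id + 1]
  if (boundary >= c1)  # boundary between chromosomes
    stop("boundary ", boundary, " lies between chromosomes")
  if (boundary - w[1] < c0 || boundary + w[2] > c1)
    stop("window (", w[1], ",", w[2], ") crosses a chromosome end at boundary ", boundary)
  invisible(TRUE)
}

#' Break-recurrence score at one boundary
#'
#' @param agg an `aggregate_profile`.
#' @param boundary boundary index b in 1..P-1: the cut between the probes with
#'   genome_order b-1 and b. Both windows must lie within one chromosome.
#' @param w integer pair `c(w_L, w_R)` of window widths in probes.
#' @return the difference of right and left window means.
#' @export
break_score <- function(agg, boundary, w) {
  check_window(agg, boundary, w)
  v <- agg$values
  mean(v[(boundary + 1):(boundary + w[2])]) - mean(v[(boundary - w[1] + 1):boundary])
}

#' Break-recurrence score track at a fixed scale
#'
#' Evaluates [break_score()] at every boundary admitting full windows; no
#' window crosses a chromosome end. Chromosomes shorter than `w_L + w_R`
#' contribute no boundaries.
#'
#' @inheritParams break_score
#' @return data frame with columns `boundary`, `chrom`, `t`.
#' @export
score_track <- function(agg, w) {
  stopifnot(length(w) == 2, all(w >= 1))
  cs <- chrom_starts(agg$probes)
  ord <- attr(agg$probes, "chrom_order")
  S <- c(0, cumsum(agg$values))
  out <- vector("list", length(cs) - 1)
  for (c in seq_len(length(cs) - 1)) {
    c0 <- cs[c]; c1 <- cs[c + 1]
    if (c1 - c0 < w[1] + w[2]) next
    b <- (c0 + w[1]):(c1 - w[2])
    t <- (S[b + w[2] + 1] - S[b + 1]) / w[2] - (S[b + 1] - S[b - w[1] + 1]) / w[1]
    out[[c]] <- data.frame(boundary = b, chrom = ord[c], t = t,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(boundary = integer(), chrom = character(), t = numeric())
  rownames(res) <- NULL
  res
}

#' Euler characteristic of the excursion sets of a track
#'
#' Counts maximal runs with `track >= t0` plus maximal runs with
#' `track <= -t0`; runs never span chromosome boundaries.
#'
#' @param track numeric vector of scores, or a data frame from [score_track()]
#'   (whose `chrom` column is then used).
#' @param t0 non-negative threshold.
#' @param chrom optional grouping vector (same length as `track`); runs are
#'   counted within groups.
#' @return integer count.
#' @export
euler_characteristic <- function(track, t0, chrom = NULL) {
  stopifnot(t0 >= 0)
  if (is.data.frame(track)) {
    chrom <- track$chrom
    track <- track$t
  }
  if (length(track) == 0) return(0L)
  if (is.null(chrom)) chrom <- rep(1L, length(track))
  n <- 0L
  for (g in split(track, factor(chrom, levels = unique(chrom)))) {
    rp <- rle(g >= t0)
    rn <- rle(g <= -t0)
    n <- n + sum(rp$values) + sum(rn$values)
  }
  as.integer(n)
}

#' Cyclically shift each sample's profile
#'
#' Row s is rotated right by `offsets[s]` over the concatenated genome:
#' a row `c(a, b, c)` with offset 1 becomes `c(c, a, b)`. The per-row value
#' multiset (and hence the aggregate total) is preserved.
#'
#' @param m a `cn_matrix`.
#' @param offsets integer vector, one offset in 0..P-1 per sample.
#' @return the shifted `cn_matrix`.
#' @export
cyclic_shift <- function(m, offsets) {
  stopifnot(inherits(m, "cn_matrix"))
  P <- ncol(m$values)
  offsets <- as.integer(offsets)
  stopifnot(length(offsets) == nrow(m$values), all(offsets >= 0), all(offsets < P))
  v <- m$values
  for (s in seq_len(nrow(v))) {
    o <- offsets[s]
    if (o > 0) v[s, ] <- v[s, c((P - o + 1):P, 1:(P - o))]
  }
  m$values <- v
  m
}

#' Null-model configuration
#'
#' @param n_perm number of cyclic-shift permutations.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param scale_grid integer vector of window widths (probes); default is the
#'   geometric grid 1, 2, 4, ... capped at P/4 and at half the longest
#'   chromosome.
#' @param threshold_grid non-negative ascending thresholds (first must be 0);
#'   default is a geometric grid reaching just above the largest observed |t|.
#' @return a `null_config` list.
#' @export
null_config <- function(n_perm = 100, seed = NULL, scale_grid = NULL,
                        threshold_grid = NULL) {
  stopifnot(n_perm >= 1)
  structure(list(n_perm = as.integer(n_perm), seed = seed,
                 scale_grid = scale_grid, threshold_grid = threshold_grid),
            class = "null_config")
}

default_scale_grid <- function(probes) {
  cs <- chrom_starts(probes)
  P <- cs[length(cs)]
  longest <- max(diff(cs))
  cap <- min(floor(P / 4), floor((longest - 1) / 2))
  if (cap < 1) stop("no chromosome long enough for any scale")
  2L^(0:floor(log2(cap)))
}

# largest |t| over the equal-scale tracks
max_abs_t <- function(agg, scales) {
  cpp_max_abs_t(agg$values, as.integer(chrom_starts(agg$probes)),
                as.integer(scales))
}

# geometric grid: observed |t| spans orders of magnitude (weak recurrent
# breaks vs near-fixated driver loci), so log spacing keeps resolution where
# most break scores live while still covering the largest observed jump
default_threshold_grid <- function(agg, scales, n = 25, span = 300) {
  tmax <- max_abs_t(agg, scales)
  if (tmax <= 0) tmax <- 1
  tmax <- 1.05 * tmax
  c(0, exp(seq(log(tmax / span), log(tmax), length.out = n - 1)))
}

# content hash for curve caching (not cryptographic)
profile_hash <- function(m) {
  v <- m$values
  sprintf("%.10e|%.10e|%.6e|%d", sum(v), sum(v * v), v[length(v) %/% 2 + 1],
          length(v))
}

#' Estimate expected-Euler-characteristic curves under the cyclic-shift null
#'
#' For every unordered scale pair on the grid and every threshold, the mean
#' Euler characteristic of the break-score track over `n_perm` independent
#' random rotations of the cohort. Unless `fit = FALSE`, each per-pair curve
#' is then cleaned by (antitonic) isotonic regression and given a Gaussian-
#' style tail, `log E = a - b t^2`, fitted to the upper thresholds, which is
#' what [significance()] evaluates.
#'
#' @param m a `cn_matrix` (one sign: gains or losses, or raw for diagnostics).
#' @param cfg a [null_config()].
#' @param offsets optional integer matrix (`n_perm` x n_samples, offsets in
#'   0..P-1) overriding random offset generation; used for exhaustive
#'   enumeration and reproduction.
#' @param fit if `FALSE` the table keeps the raw Monte-Carlo means with no
#'   monotonicity cleanup or tail (diagnostic mode: grid lookups reproduce the
#'   tabulated means exactly).
#' @param cache optional JSON path: when the file exists and its key (data
#'   hash, permutation count, seed, grids) matches, the stored table is
#'   returned and permutation is skipped; otherwise the freshly estimated
#'   table is written there.
#' @return an `euler_curves` object.
#' @export
estimate_euler_curves <- function(m, cfg = null_config(), offsets = NULL,
                                  fit = TRUE, cache = NULL) {
  stopifnot(inherits(m, "cn_matrix"))
  if (!is.null(cache) && file.exists(cache)) {
    tab <- read_euler_curves(cache)
    same_scalar <- function(a, b) {
      (is.null(a) && is.null(b)) ||
        (length(a) == 1 && length(b) == 1 && as.numeric(a) == as.numeric(b))
    }
    if (identical(tab$data_hash, profile_hash(m)) &&
        identical(isTRUE(as.logical(tab$fit)), fit) &&
        same_scalar(tab$n_perm, cfg$n_perm) &&
        same_scalar(tab$seed, cfg$seed) &&
        (is.null(cfg$scale_grid) ||
           identical(tab$scales, as.integer(sort(unique(cfg$scale_grid))))) &&
        (is.null(cfg$threshold_grid) ||
           isTRUE(all.equal(tab$thresholds, as.numeric(cfg$threshold_grid)))))
      return(tab)
  }
  probes <- m$probes
  cs <- chrom_starts(probes)
  P <- ncol(m$values)
  scales <- cfg$scale_grid
  if (is.null(scales)) {
    scales <- default_scale_grid(probes)
  } else {
    scales <- sort(unique(as.integer(scales)))
    feasible <- 2 * scales <= max(diff(cs))
    if (!all(feasible)) {
      warning("dropping scale(s) exceeding the longest chromosome: ",
              paste(scales[!feasible], collapse = ", "))
      scales <- scales[feasible]
    }
    if (length(scales) == 0) stop("no feasible scale left")
  }
  agg <- aggregate_profile(m)
  thresholds <- cfg$threshold_grid
  if (is.null(thresholds)) thresholds <- default_threshold_grid(agg, scales)
  thresholds <- as.numeric(thresholds)
  stopifnot(!is.unsorted(thresholds, strictly = TRUE), thresholds[1] == 0)

  if (is.null(offsets)) {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    offsets <- matrix(sample.int(P, cfg$n_perm * nrow(m$values), replace = TRUE) - 1L,
                      nrow = cfg$n_perm)
  } else {
    offsets <- matrix(as.integer(offsets), nrow = nrow(offsets))
    stopifnot(ncol(offsets) == nrow(m$values), all(offsets >= 0), all(offsets < P))
  }

  means <- cpp_euler_curve_counts(t(m$values), as.integer(cs), offsets,
                                  as.integer(scales), thresholds)
  ns <- length(scales)
  pairs <- do.call(rbind, lapply(seq_len(ns), function(i)
    data.frame(wa = scales[i], wb = scales[i:ns])))
  pair_id0 <- matrix(0L, ns, ns)
  k <- 0L
  for (i in seq_len(ns)) for (j in i:ns) {
    pair_id0[i, j] <- k; pair_id0[j, i] <- k; k <- k + 1L
  }

  tab <- structure(list(
    scales = scales, pairs = pairs, thresholds = thresholds, means = means,
    log_w = log(scales), pair_id0 = pair_id0,
    n_perm = nrow(offsets), seed = cfg$seed,
    P = P, chrom_start = as.integer(cs), n_samples = nrow(m$values),
    fit = fit, data_hash = profile_hash(m), version = 1L),
    class = "euler_curves")
  tab <- fit_curve_tails(tab)
  if (!is.null(cache)) write_euler_curves(tab, cache)
  tab
}

# isotonic cleanup + quadratic-in-t tail fit of log E[chi]; fills logv, tstar0,
# tail_b. With fit disabled the raw means are kept and the last grid value is
# carried into a steep default tail.
fit_curve_tails <- function(tab) {
  eps <- 1e-12
  n_thr <- length(tab$thresholds)
  n_pairs <- nrow(tab$pairs)
  logv <- matrix(log(eps), n_pairs, n_thr)
  tstar0 <- integer(n_pairs)
  tail_b <- numeric(n_pairs)
  t2 <- tab$thresholds^2
  dt2 <- if (n_thr > 1) t2[n_thr] - t2[n_thr - 1] else 1
  b_default <- log(1e6) / dt2
  for (p in seq_len(n_pairs)) {
    v <- tab$means[p, ]
    if (tab$fit && n_thr > 1) v <- -stats::isoreg(tab$thresholds, -v)$yf
    v <- pmax(v, 0)
    pos <- which(v > eps)
    ks <- if (length(pos) > 0) max(pos) else 1L
    logv[p, 1:ks] <- log(pmax(v[1:ks], eps))
    tstar0[p] <- ks - 1L
    if (!tab$fit) {
      tstar0[p] <- n_thr - 1L
      logv[p, ] <- log(pmax(v, eps))
      tail_b[p] <- b_default
      next
    }
    fitpts <- pos[pos >= max(2, ceiling(n_thr / 2))]
    if (length(fitpts) < 3) fitpts <- pos[pos >= 2]
    if (length(fitpts) >= 2 && stats::sd(t2[fitpts]) > 0) {
      x <- t2[fitpts]; y <- log(v[fitpts])
      slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      tail_b[p] <- max(-slope, 1e-9)
    } else {
      tail_b[p] <- b_default
    }
  }
  tab$logv <- logv
  tab$tstar0 <- tstar0
  tab$tail_b <- tail_b
  tab
}

#' @export
print.euler_curves <- function(x, ...) {
  cat(sprintf(paste0("Expected Euler characteristic curves: %d scale(s) ",
                     "(%d pairs) x %d thresholds, %d permutation(s), P = %d\n"),
              length(x$scales), nrow(x$pairs), length(x$thresholds),
              x$n_perm, x$P))
  invisible(x)
}

#' Break significance: expected Euler characteristic at (|t|, w)
#'
#' Evaluates the per-pair curve fits at `|t|` with bilinear interpolation in
#' `(log w_L, log w_R)` over the symmetrised scale grid. Non-increasing in
#' `|t|`, exchange-symmetric in the scale pair, and non-negative. Scales
#' outside the grid are clamped to its range (with a warning).
#'
#' @param table an `euler_curves` object.
#' @param t observed break score(s); the absolute value is used.
#' @param w scale pair `c(w_L, w_R)`, or a two-column matrix with one row per
#'   element of `t`.
#' @return numeric vector of expected Euler characteristics.
#' @export
significance <- function(table, t, w) {
  stopifnot(inherits(table, "euler_curves"))
  if (is.matrix(w)) {
    stopifnot(ncol(w) == 2, nrow(w) == length(t))
    wl <- w[, 1]; wr <- w[, 2]
  } else {
    stopifnot(length(w) == 2)
    wl <- rep(w[1], length(t)); wr <- rep(w[2], length(t))
  }
  rng <- range(table$scales)
  if (any(wl < rng[1] | wl > rng[2] | wr < rng[1] | wr > rng[2]))
    warning("scale outside the estimated grid; clamped to [",
            rng[1], ", ", rng[2], "]")
  cpp_significance(as.numeric(t), as.numeric(wl), as.numeric(wr),
                   unclass(table))
}

#' Serialize Euler curves to a JSON cache
#'
#' The cache is keyed by data hash, permutation count, seed and both grids, so
#' a rerun on identical input can skip permutation.
#'
#' @param table an `euler_curves` object.
#' @param path output JSON path.
#' @export
write_euler_curves <- function(table, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for curve serialization")
  x <- unclass(table)
  x$means <- as.data.frame(x$means)
  x$logv <- as.data.frame(x$logv)
  x$pair_id0 <- as.data.frame(x$pair_id0)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read back a serialized Euler-curve table
#' @param path JSON path written by [write_euler_curves()].
#' @return an `euler_curves` object.
#' @export
read_euler_curves <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for curve serialization")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$means <- as.matrix(x$means)
  x$logv <- as.matrix(x$logv)
  x$pair_id0 <- matrix(as.integer(as.matrix(x$pair_id0)), nrow = nrow(x$pair_id0))
  x$chrom_start <- as.integer(x$chrom_start)
  x$scales <- as.integer(x$scales)
  x$tstar0 <- as.integer(x$tstar0)
  dimnames(x$means) <- dimnames(x$logv) <- NULL
  structure(x, class = "euler_curves")
}
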