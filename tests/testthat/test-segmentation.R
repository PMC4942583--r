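# Agglomerative segmentation of the aggregate profile.

test_that("a flat aggregate collapses to one segment per chromosome", {
  pm <- make_pm(c(12, 8))
  m <- make_cnm(matrix(1, 2, 20), pm, "gains")
  tab <- estimate_euler_curves(rand_gains(c(12, 8), 2, seed = 1),
                               null_config(n_perm = 5, seed = 1))
  seg <- segment_genome(aggregate_profile(m), tab, E = 1)
  expect_equal(nrow(seg$segments), 2)
  expect_equal(seg$segments$width, c(12, 8))
  expect_equal(nrow(seg$boundaries), 0)
})

test_that("an infinite threshold accepts the per-probe segmentation as is", {
  # every boundary is immediately significant at E = Inf, so no merge happens
  m <- rand_gains(c(10), 2, seed = 2)
  tab <- estimate_euler_curves(m, null_config(n_perm = 5, seed = 2))
  seg <- segment_genome(aggregate_profile(m), tab, E = Inf)
  expect_equal(nrow(seg$segments), 10)
})

test_that("segment amplitudes are the aggregate means and sigs respect E", {
  m <- rand_gains(c(50, 35), 3, seed = 7)
  agg <- aggregate_profile(m)
  tab <- estimate_euler_curves(m, null_config(n_perm = 10, seed = 7))
  seg <- segment_genome(agg, tab, E = 2)
  s <- seg$segments
  # segments tile each chromosome without gaps
  cs <- breakrec:::chrom_starts(m$probes)
  expect_equal(sum(s$width), 85)
  expect_equal(s$start_probe[1], 0)
  expect_true(all(s$end_probe[-nrow(s)] == s$start_probe[-1] |
                    s$end_probe[-nrow(s)] %in% cs))
  for (i in seq_len(nrow(s)))
    expect_equal(s$amplitude[i],
                 mean(agg$values[(s$start_probe[i] + 1):s$end_probe[i]]))
  # every surviving boundary is significant, re-checked via significance()
  b <- seg$boundaries
  if (nrow(b) > 0) {
    li <- match(b$boundary, s$end_probe)
    ri <- match(b$boundary, s$start_probe)
    resig <- suppressWarnings(
      significance(tab, abs(b$jump), cbind(s$width[li], s$width[ri])))
    expect_true(all(resig <= 2 + 1e-9))
    expect_equal(resig, b$sig, tolerance = 1e-9)
  }
})

test_that("single-probe chromosomes come back as one boundary-less segment", {
  pm <- make_pm(c(1, 8))
  v <- matrix(pmax(rnorm(18), 0), 2)
  m <- make_cnm(v, pm, "gains")
  tab <- estimate_euler_curves(m, null_config(n_perm = 5, seed = 3))
  seg <- segment_genome(aggregate_profile(m), tab, E = 1)
  s1 <- seg$segments[seg$segments$chrom == "chr1", ]
  expect_equal(nrow(s1), 1)
  expect_equal(s1$width, 1)
  expect_false(any(seg$boundaries$chrom == "chr1"))
})

test_that("a merge rescores at most the two adjacent boundaries", {
  m <- rand_gains(c(200), 3, seed = 9)
  tab <- estimate_euler_curves(m, null_config(n_perm = 10, seed = 9))
  res <- breakrec:::cpp_segment(aggregate_profile(m)$values,
                                as.integer(breakrec:::chrom_starts(m$probes)),
                                0.5, unclass(tab), diagnostics = TRUE)
  expect_lte(res$max_rescored, 2)
})

test_that("segmentation is deterministic and chromosome-independent", {
  m <- rand_gains(c(60, 40), 3, seed = 11)
  agg <- aggregate_profile(m)
  tab <- estimate_euler_curves(m, null_config(n_perm = 10, seed = 11))
  seg1 <- segment_genome(agg, tab, E = 1)
  seg2 <- segment_genome(agg, tab, E = 1)
  expect_identical(seg1$segments, seg2$segments)
  # per-chromosome runs concatenate to the genome-wide result
  for (ch in c("chr1", "chr2")) {
    segc <- segment_chromosome(agg, ch, tab, E = 1)
    full <- seg1$segments[seg1$segments$chrom == ch, ]
    offset <- min(full$start_probe)
    expect_equal(segc$segments$width, full$width)
    expect_equal(segc$segments$amplitude, full$amplitude)
    expect_equal(segc$segments$start_probe + offset, full$start_probe)
  }
})

test_that("segmentations export as bedGraph plus a boundary table", {
  m <- rand_gains(c(30, 20), 2, seed = 15)
  tab <- estimate_euler_curves(m, null_config(n_perm = 5, seed = 15))
  seg <- segment_genome(aggregate_profile(m), tab, E = 2)
  paths <- write_segmentation(seg, tempfile())
  bg <- read.table(paths[["bedgraph"]], sep = "\t")
  expect_equal(nrow(bg), nrow(seg$segments))
  expect_true(all(bg$V3 > bg$V2))
  bd <- read.delim(paths[["boundaries"]])
  expect_equal(nrow(bd), nrow(seg$boundaries))
  if (nrow(bd) > 0) expect_true(all(bd$sig <= 2))
})

test_that("runtime grows near-linearly when the probe count doubles", {
  # P log P contract: doubling P must not much more than double the runtime
  tab <- estimate_euler_curves(rand_gains(c(2000), 2, seed = 13),
                               null_config(n_perm = 3, seed = 13))
  time_at <- function(P) {
    set.seed(1)
    pm <- make_pm(P)
    m <- make_cnm(matrix(pmax(rnorm(2 * P), 0), 2), pm, "gains")
    agg <- aggregate_profile(m)
    segment_genome(agg, tab, E = 0.5)       # warm-up
    # minimum over repeats: scheduling noise only ever inflates a timing
    min(vapply(1:12, function(i)
      system.time(segment_genome(agg, tab, E = 0.5))[["elapsed"]], 1))
  }
  ratio <- time_at(300000) / max(time_at(150000), 1e-3)
  if (ratio >= 2.5)   # scheduling noise inflates ratios; re-measure once
    ratio <- min(ratio, time_at(300000) / max(time_at(150000), 1e-3))
  expect_lt(ratio, 2.5)
})
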