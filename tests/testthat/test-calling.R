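# Local-maximum calling, the adaptive threshold and null refinement.

test_that("local maxima are segments with uphill-left, downhill-right jumps", {
  seg <- fake_segmentation(c(1, 3, 2))
  regs <- call_local_maxima(seg)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$amplitude, 3)
  expect_equal(regs$start_probe, 2L)   # second segment, width-2 segments
  # monotone profile: only the terminal segment qualifies
  regs2 <- call_local_maxima(fake_segmentation(c(1, 2, 3)))
  expect_equal(nrow(regs2), 1)
  expect_equal(regs2$amplitude, 3)
  expect_true(is.na(regs2$right_sig))
  # first segment qualifies when its right jump is downhill
  regs3 <- call_local_maxima(fake_segmentation(c(3, 2, 1)))
  expect_equal(regs3$amplitude, 3)
  expect_true(is.na(regs3$left_sig))
  # flat single segment: nothing to call
  expect_equal(nrow(call_local_maxima(fake_segmentation(5))), 0)
})

test_that("region coordinates span probe extents, half-open", {
  seg <- fake_segmentation(c(1, 3, 2), widths = c(2L, 2L, 2L),
                           pm = make_pm(6, spacing = 100))
  regs <- call_local_maxima(seg)
  expect_equal(regs$start, 200)   # first probe of segment 2 sits at 200
  expect_equal(regs$end, 400)     # first probe after the segment
  # terminal segment ends one base after its last probe
  regs2 <- call_local_maxima(fake_segmentation(c(1, 2, 3), widths = c(2L, 2L, 2L),
                                               pm = make_pm(6, spacing = 100)))
  expect_equal(regs2$end, 501)
})

test_that("the adaptive threshold reproduces the worked iteration", {
  res <- adaptive_threshold(function(E) 100L, fdr = 0.25)
  expect_equal(res$E, 50)
  expect_equal(res$n, 100L)
  # zero calls at the initial threshold stop immediately
  res0 <- adaptive_threshold(function(E) 0L, fdr = 0.25)
  expect_equal(res0$E, 0.5)
  expect_equal(res0$n, 0L)
  # a decreasing sequence stabilizes at its fixed point
  res2 <- adaptive_threshold(function(E) if (E < 5) 20L else 40L, fdr = 0.25)
  expect_equal(res2$n, 40L)
  expect_equal(res2$E, 20)
  # oscillation falls back to the smaller member with a warning
  expect_warning(
    res3 <- adaptive_threshold(function(E) if (E < 3) 10L else 4L, fdr = 0.25),
    "oscillates")
  expect_equal(res3$E, 2)
})

test_that("null refinement deletes called breaks by length-weighted merging", {
  pm <- make_pm(c(4))
  m <- make_cnm(matrix(c(0, 0, 2, 2), 1), pm)
  out <- refine_null(m, boundaries = 2L)
  expect_equal(unname(out$values[1, ]), rep(1, 4))
  # breaks outside every window are untouched
  out2 <- refine_null(m, boundaries = 3L)
  expect_equal(out2$values, m$values)
  # margin widens the window
  out3 <- refine_null(m, boundaries = 3L, margin = 1)
  expect_equal(unname(out3$values[1, ]), rep(1, 4))
  # idempotence
  expect_equal(refine_null(out, boundaries = 2L)$values, out$values)
  # weights follow run lengths
  m2 <- make_cnm(matrix(c(0, 0, 0, 4), 1), pm)
  expect_equal(unname(refine_null(m2, 3L)$values[1, ]), rep(1, 4))
  # runs on different chromosomes never merge
  pm2 <- make_pm(c(2, 2))
  m3 <- make_cnm(matrix(c(0, 0, 2, 2), 1), pm2)
  expect_equal(refine_null(m3, 2L)$values, m3$values)
})

test_that("the full fit is deterministic given a seed", {
  genome <- genome_model(c(chr1 = 2e7, chr2 = 2e7), spacing = 2e4)
  set.seed(21)
  drivers <- driver_set(genome, 5, coeff_sd = 2)
  sim <- simulate_cohort(10, genome = genome, drivers = drivers, seed = 21)
  f1 <- breakrec(sim$matrix, fdr = 0.25, n_perm = 15, seed = 77)
  f2 <- breakrec(sim$matrix, fdr = 0.25, n_perm = 15, seed = 77)
  expect_equal(f1$gains, f2$gains)
  expect_equal(f1$losses, f2$losses)
  expect_equal(f1$gains_fit$E, f2$gains_fit$E)
})

test_that("filters only drop rows and never alter coordinates", {
  regions <- data.frame(chrom = "chr1", start = c(0, 0, 2e6), end = c(5e6, 2e7, 4e6),
                        n_genes = c(2L, 3L, 0L), stringsAsFactors = FALSE)
  kept <- filter_regions(regions, max_width = 1e7)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 0)
  expect_equal(kept$end, 5e6)
  kept2 <- filter_regions(regions, max_width = 1e7, require_gene_overlap = FALSE)
  expect_equal(nrow(kept2), 2)
  expect_true(all(paste(kept2$start, kept2$end) %in%
                    paste(regions$start, regions$end)))
})
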