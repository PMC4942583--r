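# Readers, writers and the gains/losses split.

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

test_that("marker tables are sorted into the declared chromosome order", {
  f <- write_tmp(c("probe_id\tchrom\tpos",
                   "a\tchr2\t100", "b\tchr1\t200", "c\tchr1\t100",
                   "d\tchr2\t50"))
  pm <- read_markers(f)
  expect_equal(pm$probe_id, c("c", "b", "d", "a"))
  expect_equal(pm$genome_order, 0:3)
  expect_equal(attr(pm, "chrom_order"), c("chr1", "chr2"))
  # custom order flips chromosomes
  pm2 <- read_markers(f, chrom_order = c("chr2", "chr1"))
  expect_equal(pm2$probe_id, c("d", "a", "c", "b"))
})

test_that("marker reading rejects duplicates and unknown chromosomes", {
  f <- write_tmp(c("probe_id\tchrom\tpos", "a\tchr1\t100", "b\tchr1\t100"))
  expect_error(read_markers(f), "duplicate")
  f2 <- write_tmp(c("probe_id\tchrom\tpos", "a\tchr1\t100", "b\tchrX\t50"))
  expect_error(read_markers(f2, chrom_order = "chr1"), "unknown chromosome")
})

test_that("SEG segments fill covered probes with their mean", {
  pm <- make_pm(c(4))
  f <- write_tmp(c("sample\tchrom\tstart\tend\tn_probes\tseg_mean",
                   "s1\tchr1\t1\t150\t2\t0.0",
                   "s1\tchr1\t151\t1000\t2\t1.0"))
  m <- read_seg(f, pm)
  expect_equal(unname(m$values[1, ]), c(0, 0, 1, 1))
  expect_equal(m$sign_mode, "raw")
})

test_that("uncovered probes error by default and impute on request", {
  pm <- make_pm(c(3))
  f <- write_tmp(c("sample\tchrom\tstart\tend\tn_probes\tseg_mean",
                   "s1\tchr1\t1\t150\t2\t0.5"))     # probe at 200 uncovered
  expect_error(read_seg(f, pm), "not covered")
  m <- read_seg(f, pm, impute = TRUE)
  expect_equal(unname(m$values[1, ]), c(0.5, 0.5, 0.5))
})

test_that("optional clipping caps extreme log2 ratios", {
  pm <- make_pm(c(4))
  f <- write_tmp(c("sample\tchrom\tstart\tend\tn_probes\tseg_mean",
                   "s1\tchr1\t1\t150\t2\t5",
                   "s1\tchr1\t151\t1000\t2\t-3"))
  m <- read_seg(f, pm, clip = 1.5)
  expect_equal(unname(m$values[1, ]), c(1.5, 1.5, -1.5, -1.5))
  expect_equal(unname(read_seg(f, pm)$values[1, ]), c(5, 5, -3, -3))
})

test_that("overlapping segments within a sample are rejected", {
  pm <- make_pm(c(3))
  f <- write_tmp(c("sample\tchrom\tstart\tend\tn_probes\tseg_mean",
                   "s1\tchr1\t1\t200\t2\t0.5",
                   "s1\tchr1\t150\t300\t1\t1.0"))
  expect_error(read_seg(f, pm), "overlapping")
})

test_that("SEG round trip through write_cohort preserves the matrix", {
  genome <- genome_model(c(chr1 = 2e5, chr2 = 1e5), spacing = 1e3)
  sim <- simulate_cohort(3, genome = genome,
                         ab_model = aberration_model(focal_range = c(5e3, 5e4)),
                         seed = 42)
  dir <- tempfile()
  write_cohort(sim, dir)
  pm <- read_markers(file.path(dir, "markers.tsv"))
  m <- read_seg(file.path(dir, "cohort.seg"), pm)
  expect_equal(unname(m$values), unname(sim$matrix$values), tolerance = 1e-5)
})

test_that("BED genes are parsed, named, sorted and validated", {
  f <- write_tmp(c("chr2\t100\t200\tg1", "chr1\t500\t900\tg2",
                   "chr1\t50\t60"))
  f_bad <- write_tmp(c("chr1\t10\t20\ta", "chr1\t30\t30\tb"))
  expect_warning(g <- read_genes(f_bad), "dropped")
  expect_equal(g$gene_name, "a")
  g2 <- read_genes(f)
  expect_equal(g2$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(g2$start, c(50, 500, 100))
  expect_error(read_genes(write_tmp("chr1\t-5\t20\tx")), "negative")
})

test_that("gains/losses split is a non-negative decomposition of the input", {
  pm <- make_pm(c(3))
  m <- make_cnm(matrix(c(1, -2, 0), 1), pm)
  sp <- split_gains_losses(m)
  expect_equal(unname(sp$gains$values[1, ]), c(1, 0, 0))
  expect_equal(unname(sp$losses$values[1, ]), c(0, 2, 0))
  expect_equal(sp$gains$sign_mode, "gains")
  # reconstruction and non-negativity on random input
  set.seed(3)
  m2 <- make_cnm(matrix(rnorm(30), 3), make_pm(10))
  sp2 <- split_gains_losses(m2)
  expect_true(all(sp2$gains$values >= 0) && all(sp2$losses$values >= 0))
  expect_equal(sp2$gains$values - sp2$losses$values, m2$values)
  expect_error(split_gains_losses(sp2$gains), "already split")
})

test_that("called regions survive a TSV round trip and emit BED", {
  regions <- data.frame(
    chrom = c("chr1", "chr1"), start = c(100, 5000), end = c(900, 9000),
    direction = "gain", amplitude = c(2.5, 1.25),
    left_sig = c(0.01, NA), right_sig = c(0.2, 0.5),
    genes = c("a,b", ""), start_probe = c(1L, 50L), end_probe = c(9L, 90L),
    left_boundary = c(1L, NA), right_boundary = c(9L, 90L),
    stringsAsFactors = FALSE)
  stem <- tempfile()
  paths <- write_regions(regions, stem)
  back <- read_regions(paths[["tsv"]])
  expect_equal(back$start, regions$start)
  expect_equal(back$left_sig, regions$left_sig)
  expect_equal(back$genes, regions$genes)
  expect_equal(length(readLines(paths[["bed"]])), 2)
  # empty table: header-only TSV, empty BED
  paths2 <- write_regions(regions[0, ], tempfile())
  expect_equal(nrow(read_regions(paths2[["tsv"]])), 0)
  expect_equal(nchar(paste(readLines(paths2[["bed"]]), collapse = "")), 0)
})
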