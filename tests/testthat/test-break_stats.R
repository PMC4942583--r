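# Aggregate profile, break scores, Euler characteristics and the
# cyclic-shift null.

test_that("aggregation sums samples and ignores sample order", {
  pm <- make_pm(c(2))
  m <- make_cnm(rbind(c(1, 2), c(1, 2)), pm, "gains")
  expect_equal(aggregate_profile(m)$values, c(2, 4))
  m2 <- make_cnm(rbind(c(5, 1), c(0, 3), c(2, 2)), pm, "gains")
  m3 <- make_cnm(m2$values[c(3, 1, 2), ], pm, "gains")
  expect_equal(aggregate_profile(m2)$values, aggregate_profile(m3)$values)
})

test_that("break score is the difference of window means", {
  pm <- make_pm(c(6))
  agg <- aggregate_profile(make_cnm(matrix(c(1, 1, 1, 5, 5, 5), 1), pm, "gains"))
  expect_equal(break_score(agg, 3, c(3, 3)), 4)
  agg2 <- aggregate_profile(make_cnm(matrix(c(0, 2, 0, 0, 0, 0), 1), pm, "gains"))
  expect_equal(break_score(agg2, 1, c(1, 1)), 2)
  # constant aggregate scores zero everywhere
  aggc <- aggregate_profile(make_cnm(matrix(2, 1, 6), pm, "gains"))
  for (b in 1:5) expect_equal(break_score(aggc, b, c(1, 1)), 0)
  expect_error(break_score(agg, 5, c(1, 3)), "crosses")
})

test_that("score tracks exclude partial windows and respect chromosomes", {
  m <- rand_gains(c(20, 9), 2, seed = 5)
  agg <- aggregate_profile(m)
  tr <- score_track(agg, c(3, 4))
  expect_equal(sum(tr$chrom == "chr1"), 20 - 3 - 4 + 1)
  expect_equal(sum(tr$chrom == "chr2"), 9 - 3 - 4 + 1)
  # chromosome shorter than the window contributes nothing
  tr2 <- score_track(agg, c(5, 5))
  expect_equal(sum(tr2$chrom == "chr2"), 0)
  # every entry agrees with the single-boundary operation
  for (i in seq_len(nrow(tr)))
    expect_equal(break_score(agg, tr$boundary[i], c(3, 4)), tr$t[i])
  # a single-step profile attains its largest |t| at the step
  pm <- make_pm(c(12))
  aggs <- aggregate_profile(make_cnm(matrix(rep(c(0, 6), each = 6), 1), pm, "gains"))
  trs <- score_track(aggs, c(2, 2))
  expect_equal(trs$boundary[which.max(abs(trs$t))], 6)
})

test_that("euler characteristic counts disjoint excursion components", {
  expect_equal(euler_characteristic(c(0, 2, 0, -2, 0), 1), 2)
  expect_equal(euler_characteristic(rep(0, 5), 1), 0)
  expect_equal(euler_characteristic(c(3, 3, 3), 1), 1)
  # runs never span chromosome boundaries
  expect_equal(euler_characteristic(c(3, 3, 3), 1, chrom = c(1, 1, 2)), 2)
})

test_that("cyclic shift rotates rows and preserves their content", {
  pm <- make_pm(c(3))
  m <- make_cnm(matrix(c(1, 2, 3), 1), pm, "gains")
  expect_equal(unname(cyclic_shift(m, 0L)$values[1, ]), c(1, 2, 3))
  expect_equal(unname(cyclic_shift(m, 1L)$values[1, ]), c(3, 1, 2))
  set.seed(8)
  m2 <- rand_gains(c(15, 10), 4, seed = 8)
  off <- sample(0:24, 4)
  sh <- cyclic_shift(m2, off)
  for (s in 1:4) {
    expect_equal(sort(sh$values[s, ]), sort(m2$values[s, ]))
    # circular adjacent-difference multiset is preserved too
    d1 <- diff(c(m2$values[s, ], m2$values[s, 1]))
    d2 <- diff(c(sh$values[s, ], sh$values[s, 1]))
    expect_equal(sort(unname(round(d1, 12))), sort(unname(round(d2, 12))))
  }
  expect_equal(rowSums(sh$values), rowSums(m2$values))
})

test_that("euler curve tables are seeded, monotone and anchored at the grid", {
  m <- rand_gains(c(40, 30), 3, seed = 2)
  cfg <- null_config(n_perm = 8, seed = 99)
  t1 <- estimate_euler_curves(m, cfg)
  t2 <- estimate_euler_curves(m, cfg)
  expect_identical(t1$means, t2$means)
  # tabulated means are non-increasing in t after isotonic cleanup
  iso <- exp(t1$logv)
  for (p in seq_len(nrow(iso)))
    expect_true(all(diff(iso[p, seq_len(t1$tstar0[p] + 1)]) <= 1e-12))
  # with the fit disabled, grid lookups reproduce the raw Monte-Carlo means
  thr <- c(0, 0.5, 1, 2)
  t3 <- estimate_euler_curves(m, null_config(n_perm = 8, seed = 99,
                                             scale_grid = c(1, 2, 4),
                                             threshold_grid = thr), fit = FALSE)
  k <- 0
  for (i in 1:3) for (j in i:3) {
    k <- k + 1
    for (ti in seq_along(thr)) {
      expect_equal(significance(t3, thr[ti], c(c(1, 2, 4)[i], c(1, 2, 4)[j])),
                   max(t3$means[k, ti], 1e-12), tolerance = 1e-9)
    }
  }
  # infeasible scales are dropped with a warning
  expect_warning(
    estimate_euler_curves(m, null_config(n_perm = 2, scale_grid = c(2, 64))),
    "dropping scale")
})

test_that("significance clamps out-of-grid scales with a warning", {
  m <- rand_gains(c(30), 2, seed = 4)
  tab <- estimate_euler_curves(m, null_config(n_perm = 5, seed = 1,
                                              scale_grid = c(1, 2, 4)))
  expect_warning(significance(tab, 1, c(64, 64)), "clamped")
})

test_that("curve tables survive JSON serialization", {
  skip_if_not_installed("jsonlite")
  m <- rand_gains(c(25, 20), 2, seed = 6)
  tab <- estimate_euler_curves(m, null_config(n_perm = 5, seed = 3))
  f <- tempfile(fileext = ".json")
  write_euler_curves(tab, f)
  back <- read_euler_curves(f)
  expect_equal(back$means, tab$means)
  t <- seq(0, 3, by = 0.37)
  expect_equal(significance(back, t, c(2, 8)), significance(tab, t, c(2, 8)))
  expect_equal(back$data_hash, tab$data_hash)
})

test_that("a matching cache skips permutation; a stale one does not", {
  skip_if_not_installed("jsonlite")
  m <- rand_gains(c(25, 20), 2, seed = 12)
  f <- tempfile(fileext = ".json")
  cfg <- null_config(n_perm = 5, seed = 9)
  t1 <- estimate_euler_curves(m, cfg, cache = f)
  expect_true(file.exists(f))
  t2 <- estimate_euler_curves(m, cfg, cache = f)
  expect_equal(t2$means, t1$means)
  # different data invalidates the key and the cache is rewritten
  m2 <- rand_gains(c(25, 20), 2, seed = 13)
  t3 <- estimate_euler_curves(m2, cfg, cache = f)
  expect_equal(t3$data_hash, breakrec:::profile_hash(m2))
  expect_false(identical(t3$data_hash, t1$data_hash))
})
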