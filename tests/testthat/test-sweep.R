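test_that("after one sweep every invisible run has counter 1 and q = 0", {
  set.seed(2)
  s1 <- run_sweep(new_genome(5000), sweep_params(nu = 3, mu = 1))
  validate_genome_state(s1$state)
  expect_equal(sweep_index(s1$state), 1L)
  expect_true(all(s1$state$counter[!s1$state$visible] == 1L))
  expect_true(all(s1$events$q == 0L))
  cen <- counter_census(s1$state)
  expect_equal(cen$proportion[cen$i == 1L], 1)
})

test_that("a vanishing deletion-length mean deletes (almost) nothing", {
  set.seed(3)
  s1 <- run_sweep(new_genome(1000), sweep_params(nu = 3, mu = 1e-8))
  expect_gt(visible_length(s1$state) / 1000, 1 - 1e-6)
})

test_that("one sweep deletes about mu/(nu+mu) of the visible length", {
  set.seed(5)
  kept <- vapply(1:20, function(i) {
    visible_length(run_sweep(new_genome(10000), sweep_params(3, 1))$state) / 10000
  }, numeric(1))
  se <- sd(kept) / sqrt(length(kept))
  expect_lt(abs(mean(kept) - 0.75), 3 * se)
})

test_that("identical seed and config give bit-identical trajectories", {
  cfg <- sim_config(genome_length = 2000, sweeps = 3, replicates = 2, seed = 77)
  r1 <- run_fractionation(sweep_params(3, 1), cfg)
  r2 <- run_fractionation(sweep_params(3, 1), cfg)
  expect_identical(r1$sweeps[[3]]$states, r2$sweeps[[3]]$states)
  f1 <- tempfile(); f2 <- tempfile()
  write_segments(r1$sweeps[[3]]$states[[1]], f1)
  write_segments(r2$sweeps[[3]]$states[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("replenishment is a no-op without a deficit and errors on an empty pool", {
  g0 <- new_genome(2000)
  expect_identical(replenish(g0, list()), g0)        # full genome: nothing to do
  set.seed(8)
  a <- run_sweep(g0, sweep_params(3, 1))$state
  expect_lt(visible_length(a), 2000)
  expect_error(replenish(a, list()), "empty")
})

test_that("replenishment appends donor segments with counters verbatim", {
  set.seed(8)
  p <- sweep_params(3, 1)
  a <- run_sweep(new_genome(2000), p)$state
  b <- run_sweep(new_genome(2000), p)$state
  expect_lt(visible_length(a), 2000)
  out <- replenish(a, b)
  validate_genome_state(out)
  expect_equal(visible_length(out), 2000, tolerance = 1e-9)
  # appended rows are a contiguous donor slice, shifted, counters preserved
  n_old <- length(a$start)
  app_cnt <- out$counter[(n_old + 1):length(out$counter)]
  app_vis <- out$visible[(n_old + 1):length(out$visible)]
  ptr <- which(b$visible != a$visible[n_old])[1L]
  idx <- ptr:(ptr + length(app_cnt) - 1L)
  expect_equal(app_vis, b$visible[idx])
  expect_equal(app_cnt, b$counter[idx])
  # alternation across the splice
  expect_false(out$visible[n_old] == out$visible[n_old + 1L])
})

test_that("full trajectories keep every genome-state invariant", {
  run <- run_fractionation(sweep_params(3, 1),
                           sim_config(genome_length = 2000, sweeps = 4,
                                      replicates = 3, seed = 13))
  for (s in seq_along(run$sweeps))
    for (st in run$sweeps[[s]]$states) {
      validate_genome_state(st)
      expect_equal(visible_length(st), 2000, tolerance = 1e-9)
      expect_equal(sweep_index(st), s)
    }
})

test_that("length pooling respects alternation and conserves the span", {
  ls0 <- collect_lengths(new_genome(100))
  expect_equal(ls0$visible, 100)
  expect_length(ls0$invisible, 0L)

  run <- run_fractionation(sweep_params(3, 1),
                           sim_config(2000, sweeps = 2, replicates = 2, seed = 19))
  for (st in run$sweeps[[2]]$states) {
    sm <- collect_lengths(st)
    expect_lte(abs(length(sm$visible) - length(sm$invisible)), 1L)
    expect_equal(sum(sm$visible) + sum(sm$invisible), total_span(st),
                 tolerance = 1e-9)
  }
  pooled <- collect_lengths(run, sweep = 2)
  expect_equal(sum(pooled$visible), 2 * 2000, tolerance = 1e-9)
})

test_that("overlap histogram counts every event and starts at zero overlap", {
  run <- run_fractionation(sweep_params(3, 1),
                           sim_config(2000, sweeps = 2, replicates = 2, seed = 23))
  h1 <- overlap_histogram(run, sweep = 1)
  expect_equal(sum(h1$count[h1$q > 0]), 0L)
  h2 <- overlap_histogram(run, sweep = 2)
  expect_equal(sum(h2$count),
               sum(vapply(run$sweeps[[2]]$events, nrow, integer(1))))
})

test_that("counter census is a distribution and handles empty states", {
  run <- run_fractionation(sweep_params(3, 1),
                           sim_config(2000, sweeps = 3, replicates = 2, seed = 29))
  cen <- counter_census(run, sweep = 3)
  expect_equal(sum(cen$proportion), 1)
  expect_true(all(cen$i >= 1L))

  empty <- counter_census(new_genome(50))
  expect_equal(attr(empty, "n_total"), 0L)
  expect_equal(nrow(empty), 0L)
})
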