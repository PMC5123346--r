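test_that("the spacing law nu/t agrees with its recursion", {
  expect_equal(lambda_exact(3, 1), 3)
  expect_equal(lambda_exact(3, 5), 0.6)
  expect_equal(lambda_recursion(3, 1), 3)
  expect_equal(lambda_recursion(3, 2), 1.5)
  for (t in c(1:10, 50, 100))
    expect_equal(lambda_recursion(7.3, t), lambda_exact(7.3, t),
                 tolerance = 1e-12)
  expect_error(lambda_exact(3, 0), "positive integer")
  # the historical two-sweep approximation differs from the recursion
  expect_equal(lambda_two_sweep_approx(3, 1), 3 / (1 + 3 / 4))
  expect_false(isTRUE(all.equal(lambda_two_sweep_approx(3, 1),
                                lambda_exact(3, 2))))
})

test_that("the overlap pmf is geometric and matches printed instances", {
  expect_equal(overlap_pmf(0, mu = 2, lam = 2), 0.5)
  expect_equal(overlap_pmf(0, mu = 1, lam = 3), 0.75)
  expect_equal(overlap_pmf(1, mu = 1, lam = 3), 0.1875)
  expect_equal(sum(overlap_pmf(0:200, mu = 1, lam = 3)), 1, tolerance = 1e-12)
  # truncation error bound (mu/(mu+lam))^(Q+1)
  for (Q in c(3, 10)) {
    miss <- 1 - sum(overlap_pmf(0:Q, mu = 2, lam = 1))
    expect_equal(miss, (2 / 3)^(Q + 1), tolerance = 1e-12)
  }
  expect_error(overlap_pmf(-1, 1, 1), "non-negative")
})

test_that("quadrature of the defining integrals reproduces the closed form", {
  grid <- c(0.2, 1, 3, 10)
  for (mu in grid) for (lam in grid) {
    expect_equal(overlap_pmf_integral(0, mu, lam), overlap_pmf(0, mu, lam),
                 tolerance = 1e-6)
    expect_equal(overlap_pmf_integral(1, mu, lam), overlap_pmf(1, mu, lam),
                 tolerance = 1e-6)
  }
  expect_equal(overlap_pmf_integral(0, 2, 2), 0.5, tolerance = 1e-6)
})

test_that("retained proportion follows (1 - mu/(nu+mu))^t", {
  expect_equal(retained_proportion(1, 3, 0), 1)
  expect_equal(retained_proportion(1, 3, 1), 0.75)
  expect_equal(retained_proportion(1, 3, 4), 0.75^4)
  p <- retained_proportion(1, 3, 0:8)
  expect_true(all(diff(p) < 0))
  expect_true(retained_proportion(2, 3, 3) < retained_proportion(1, 3, 3))
})

test_that("the event-count gain matches brute-force composition sums", {
  set.seed(31)
  i_max <- 9L
  pi <- rexp(i_max); pi <- pi / sum(pi)
  mu <- 1.4; lam <- 2.2
  delta <- fractionate:::pi_delta(pi, mu, lam)
  loss <- pi * (mu / lam)
  for (i in 1:8)
    expect_equal(delta[i] + loss[i], brute_gain(pi, mu, lam, i),
                 tolerance = 1e-12)
  # printed structure at i = 4: p1 pi(3) + 2 p2 pi(1)pi(2) + p3 pi(1)^3
  p <- overlap_pmf(0:3, mu, lam)
  expect_equal(delta[4] + loss[4],
               p[2] * pi[3] + p[3] * 2 * pi[1] * pi[2] + p[4] * pi[1]^3,
               tolerance = 1e-12)
})

test_that("per-event bookkeeping: one counter created, mu/lam destroyed", {
  # from the point mass at 1, Delta(1) = p0 - mu/lam
  i_max <- 40L
  pi1 <- c(1, numeric(i_max - 1L))
  d <- fractionate:::pi_delta(pi1, 1, 3)
  expect_equal(d[1], overlap_pmf(0, 1, 3) - 1 / 3, tolerance = 1e-12)
  # sum Delta = 1 - mu/lam up to convolution truncation (pi concentrated at
  # small i so the truncated mass is negligible)
  pi <- 0.5^(1:i_max); pi <- pi / sum(pi)
  d <- fractionate:::pi_delta(pi, 1, 2)
  expect_equal(sum(d), 1 - 1 / 2, tolerance = 1e-4)
})

test_that("the event-weighted update reproduces the exact second sweep", {
  # (mu = 1, nu = 3): pi_2(1) = 0.875, pi_2(i >= 2) = p_{i-1}/2 exactly
  tr <- pi_trajectory(mu = 1, nu = 3, t = 2, i_max = 60)
  expect_equal(tr[[1]][1], 1)
  expect_equal(tr[[2]][1], 0.875, tolerance = 1e-9)
  p <- overlap_pmf(1:4, mu = 1, lam = 3)
  expect_equal(tr[[2]][2:5], p / 2, tolerance = 1e-9)
})

test_that("pi trajectories stay normalized with monotone tails", {
  for (mode in c("event", "renorm")) {
    tr <- pi_trajectory(mu = 1, nu = 1, t = 4, i_max = 80, mode = mode)
    for (s in 1:4) expect_equal(sum(tr[[s]]), 1, tolerance = 1e-9)
  }
  tr <- pi_trajectory(mu = 1, nu = 3, t = 4, i_max = 60)
  tail_part <- tr[[4]][10:40]
  expect_true(all(diff(tail_part) < 0))
  expect_error(pi_update(c(0.7, 0.2), 1, 1, nu = 1), "normalized")
})

test_that("simulated counter censuses track the analytic trajectory", {
  # (mu = 1, nu = 3), sweeps 2..4, i <= 4: analytic event-weighted update vs
  # Monte-Carlo proportions pooled over replicates, across 4 seeds
  tr <- pi_trajectory(1, 3, 4, i_max = 60)
  cen <- sapply(1:4, function(seed) {
    run <- run_fractionation(sweep_params(3, 1),
                             sim_config(5000, sweeps = 4, replicates = 3,
                                        seed = 300 + seed))
    sapply(2:4, function(t) counter_census(run, sweep = t)$proportion[1:4])
  })
  for (t in 2:4) for (i in 1:4) {
    row <- (t - 2L) * 4L + i
    m <- mean(cen[row, ]); se <- sd(cen[row, ]) / sqrt(ncol(cen))
    expect_lt(abs(tr[[t]][i] - m), 4 * se + 0.002)
  }
})
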