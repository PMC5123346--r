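test_that("exponential rate fitting is 1/mean and scale-equivariant", {
  expect_equal(as.numeric(fit_exponential(c(2, 2, 2))), 0.5)
  x <- c(0.3, 1.2, 4.5, 0.9)
  expect_equal(as.numeric(fit_exponential(3 * x)),
               as.numeric(fit_exponential(x)) / 3)
  set.seed(41)
  x <- rexp(10000, rate = 1 / 0.6)
  r <- fit_exponential(x)
  expect_lt(abs(as.numeric(r) - 1 / 0.6), 3 * attr(r, "se"))
  expect_error(fit_exponential(numeric(0)), "non-empty")
  expect_error(fit_exponential(c(1, -1)), "positive")
  expect_error(fit_exponential(5), "at least 2")
})

test_that("moment gamma fitting satisfies the moment identities", {
  set.seed(43)
  x <- rgamma(500, shape = 2, rate = 1)
  gf <- fit_gamma(x, method = "moments")
  expect_equal(gf$alpha, mean(x)^2 / var(x), tolerance = 1e-12)
  expect_equal(gf$beta, mean(x) / var(x), tolerance = 1e-12)
  expect_equal(gf$method, "moments")
})

test_that("gamma MLE recovers parameters and solves the score equation", {
  set.seed(47)
  x <- rgamma(10000, shape = 0.9, rate = 0.35)
  gf <- fit_gamma(x)
  expect_equal(gf$method, "mle")
  expect_lt(abs(gf$alpha - 0.9), 3 * gf$sd[1])
  expect_lt(abs(gf$beta - 0.35), 3 * gf$sd[2])
  # independent oracle: shape root of log(a) - digamma(a) = log(mean) - mean(log)
  cst <- log(mean(x)) - mean(log(x))
  root <- uniroot(function(a) log(a) - digamma(a) - cst, c(1e-3, 1e3),
                  tol = 1e-12)$root
  expect_equal(gf$alpha, root, tolerance = 1e-3)
  expect_equal(gf$beta, root / mean(x), tolerance = 1e-3)
})

test_that("gamma MLE and moments agree on clean gamma samples", {
  set.seed(53)
  x <- rgamma(5000, shape = 1.7, rate = 2.2)
  a <- fit_gamma(x, "mle"); b <- fit_gamma(x, "moments")
  expect_lt(abs(a$alpha - b$alpha) / a$alpha, 0.1)
  expect_lt(abs(a$beta - b$beta) / a$beta, 0.1)
  # exponential data: fitted shape near 1
  y <- rexp(5000, 2)
  expect_lt(abs(fit_gamma(y)$alpha - 1), 0.08)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_gamma(rep(2, 100)), "degenerate")
  expect_error(fit_gamma(c(1, 2, 3)), "at least 10")
  expect_message(fit_exponential(c(rexp(50), 1e-14)), "dropped")
})

test_that("Cullen-Frey coordinates sit at the family landmarks", {
  set.seed(59)
  cf <- cullen_frey(rexp(30000), n_boot = 30)
  expect_lt(abs(cf$skewness_sq - 4), 0.5)
  expect_lt(abs(cf$kurtosis - 9), 1.6)
  k <- 4
  cfg <- cullen_frey(rgamma(30000, shape = k), n_boot = 30)
  expect_lt(abs(cfg$skewness_sq - 4 / k), 0.3)
  expect_lt(abs(cfg$kurtosis - (3 + 6 / k)), 0.6)
  # bootstrap cloud surrounds the point estimate
  expect_true(cf$skewness_sq >= min(cf$boot[, 1]) &
              cf$skewness_sq <= max(cf$boot[, 1]))
  expect_true(cf$kurtosis >= min(cf$boot[, 2]) &
              cf$kurtosis <= max(cf$boot[, 2]))
})

test_that("moment coordinates agree with fitdistrplus sample statistics", {
  set.seed(61)
  x <- rgamma(2000, shape = 0.8)
  pt <- fractionate:::moment_point(x)
  ref <- fitdistrplus::descdist(x, graph = FALSE, method = "sample")
  expect_equal(pt[1], ref$skewness^2, tolerance = 1e-8)
  expect_equal(pt[2], ref$kurtosis, tolerance = 1e-8)
})

test_that("the fitted gamma describes invisible lengths far better than an exponential", {
  run <- run_fractionation(sweep_params(3, 1),
                           sim_config(10000, sweeps = 5, replicates = 5, seed = 67))
  for (t in 2:5) {
    st <- run$sweeps[[t]]$states[[1]]
    iv <- collect_lengths(st)$invisible
    gf <- suppressMessages(fit_gamma(iv))
    Dg <- suppressWarnings(ks.test(iv, "pgamma", gf$alpha, gf$beta)$statistic)
    De <- suppressWarnings(ks.test(iv, "pexp", 1 / mean(iv))$statistic)
    # the gamma is a close (if not exact) description; lack of fit grows
    # slowly with t but stays well below the exponential's
    expect_lt(Dg, 0.08)
    expect_lt(Dg, 0.7 * De)
  }
})

test_that("fitted observables match the spacing law on simulator output", {
  run <- run_fractionation(sweep_params(3, 1),
                           sim_config(10000, sweeps = 5, replicates = 5, seed = 71))
  for (t in c(2, 5)) {
    sm <- collect_lengths(run, sweep = t)
    r <- fit_exponential(sm$visible)
    # nu/t is an approximation, and pooling replenished replicates leaves
    # duplicated segments in the sample, so allow 2%
    expect_lt(abs(as.numeric(r) * 3 / t - 1), 0.02)
  }
  fs <- suppressMessages(fit_summary(collect_lengths(run)))
  expect_s3_class(fs, "fit_summary")
  expect_equal(fs$method, "mle")
  expect_gt(fs$alpha, 0.6); expect_lt(fs$alpha, 0.75)
})
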