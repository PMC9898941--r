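# correlated Bernoulli model: feasibility bounds, latent construction,
# pattern distribution, sampling

test_that("pairwise correlation bounds match the Frechet-derived range", {
  expect_equal(pairwise_correlation_bounds(0.5, 0.5), c(-1, 1))
  expect_equal(pairwise_correlation_bounds(0.3, 0.7)[2], 3 / 7,
               tolerance = 1e-12)
  expect_equal(pairwise_correlation_bounds(0.9, 0.1)[2], 1 / 9,
               tolerance = 1e-12)
  for (pp in list(c(0.3, 0.7), c(0.9, 0.1), c(0.2, 0.4), c(0.55, 0.85))) {
    got <- pairwise_correlation_bounds(pp[1], pp[2])
    ora <- oracle_correlation_range(pp[1], pp[2])
    expect_equal(got, ora, tolerance = 1e-4)
  }
  expect_error(pairwise_correlation_bounds(0, 0.5), "degenerate")
  expect_error(pairwise_correlation_bounds(0.5, 1), "degenerate")
})

test_that("parameter validation rejects infeasible correlations", {
  expect_error(bernoulli_params(c(0.3, 0.7), structure = "exchangeable",
                                r = 0.6), "outside the feasible range")
  expect_error(bernoulli_params(c(0.3, 0.7), R = matrix(c(1, 0.2, 0.3, 1), 2)),
               "symmetric")
  # degenerate site must be uncorrelated
  expect_error(bernoulli_params(c(0, 0.5), structure = "exchangeable", r = 0.3),
               "degenerate")
  expect_silent(bernoulli_params(c(0, 0.5), structure = "independent"))
})

test_that("latent correlation solver matches the tetrachoric identity", {
  expect_equal(solve_latent_correlation(0.5, 0.5, 0), 0, tolerance = 1e-8)
  expect_equal(solve_latent_correlation(0.5, 0.5, 1), 1)
  expect_equal(solve_latent_correlation(0.5, 0.5, 0.5), sin(pi / 4),
               tolerance = 1e-7)
  # closed form r = 2 arcsin(rho) / pi at median dichotomization, on a grid
  for (r in c(0.1, 0.25, 0.75, 0.9)) {
    expect_equal(solve_latent_correlation(0.5, 0.5, r), sin(pi * r / 2),
                 tolerance = 1e-7)
  }
  expect_error(solve_latent_correlation(0.3, 0.7, 0.6), "feasible range")
  expect_error(solve_latent_correlation(0, 0.5, 0), "degenerate")
})

test_that("latent solver round-trips: thresholded pair recovers r", {
  cases <- expand.grid(p1 = c(0.2, 0.5, 0.8), p2 = c(0.3, 0.6), r = c(-0.2, 0.1, 0.35))
  for (i in seq_len(nrow(cases))) {
    p1 <- cases$p1[i]; p2 <- cases$p2[i]; r <- cases$r[i]
    b <- pairwise_correlation_bounds(p1, p2)
    if (r < b[1] || r > b[2]) next
    rho <- solve_latent_correlation(p1, p2, r)
    q <- pattern_distribution(bernoulli_params(c(p1, p2),
                                               R = matrix(c(1, r, r, 1), 2)))$q
    expect_equal(implied_pairwise_cor(q, 2, 1, 2), r, tolerance = 1e-6)
  }
})

test_that("latent model assembles thresholds and Sigma per pair", {
  lat <- build_latent_model(bernoulli_params(0.5, n = 3))
  expect_equal(lat$z, rep(0, 3))
  expect_equal(lat$Sigma, diag(3))
  expect_false(lat$repaired)

  lat <- build_latent_model(bernoulli_params(0.5, n = 4,
                                             structure = "exchangeable", r = 0.5))
  off <- lat$Sigma[upper.tri(lat$Sigma)]
  expect_equal(off, rep(sin(pi / 4), 6), tolerance = 1e-7)

  lat <- build_latent_model(bernoulli_params(c(0.3, 0.6)))
  expect_equal(lat$Sigma, diag(2))
  expect_equal(lat$z, qnorm(c(0.3, 0.6)))

  expect_error(build_latent_model(bernoulli_params(c(0, 0.5))),
               "strictly inside")
})

test_that("pattern distribution reproduces the closed forms", {
  # independence: uniform at p = 1/2
  expect_equal(unname(pattern_distribution(bernoulli_params(c(0.5, 0.5)))$q),
               rep(0.25, 4))
  # 2-CpG correlated closed form: q0 = r p (1-p) + (1-p)^2 etc.
  q <- pattern_distribution(bernoulli_params(0.5, n = 2,
                                             structure = "exchangeable",
                                             r = 0.5))$q
  expect_equal(unname(q), c(0.375, 0.125, 0.125, 0.375), tolerance = 1e-9)
  # product form, last site as least-significant bit
  q <- pattern_distribution(bernoulli_params(c(0.3, 0.6)))$q
  expect_equal(unname(q), c(0.28, 0.42, 0.12, 0.18), tolerance = 1e-12)
  # perfect exchangeable correlation concentrates on the two extremes
  q <- pattern_distribution(bernoulli_params(0.3, n = 4,
                                             structure = "exchangeable", r = 1))$q
  expect_equal(unname(q[c("0000", "1111")]), c(0.7, 0.3), tolerance = 1e-9)
  expect_equal(sum(q), 1)
  expect_equal(max(q[setdiff(names(q), c("0000", "1111"))]), 0)
})

test_that("pattern distribution is a valid, consistent distribution", {
  cases <- list(
    bernoulli_params(c(0.2, 0.5, 0.7), structure = "exchangeable", r = 0.3),
    bernoulli_params(c(0.3, 0.5, 0.6, 0.8), structure = "ar1", r = 0.5),
    bernoulli_params(0.4, n = 4, structure = "exchangeable", r = 0.7),
    bernoulli_params(c(0.35, 0.65), structure = "exchangeable", r = -0.3)
  )
  for (params in cases) {
    q <- pattern_distribution(params)$q
    n <- params$n
    expect_true(all(q >= 0))
    expect_equal(sum(q), 1, tolerance = 1e-12)
    B <- pattern_matrix(n)
    # marginal recovery
    for (i in seq_len(n)) {
      expect_equal(sum(q[B[, i] == 1]), params$p[i], tolerance = 1e-6)
    }
    # pairwise correlation recovery
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        expect_equal(implied_pairwise_cor(q, n, i, j), params$R[i, j],
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("independent-site path equals the product form exactly", {
  p <- c(0.15, 0.4, 0.8, 0.55)
  q <- pattern_distribution(bernoulli_params(p))$q
  B <- pattern_matrix(4)
  expected <- apply(B, 1, function(b) prod(ifelse(b == 1, p, 1 - p)))
  expect_equal(unname(q), unname(expected), tolerance = 1e-14)
})

test_that("thresholding path agrees with the 2-CpG closed form on a grid", {
  for (p in seq(0.1, 0.9, by = 0.1)) {
    for (r in c(0, 0.25, 0.5, 0.75, 1)) {
      b <- pairwise_correlation_bounds(p, p)
      if (r > b[2]) next
      params <- bernoulli_params(p, n = 2, structure = "exchangeable", r = r)
      q_closed <- c(r * p * (1 - p) + (1 - p)^2,
                    p * (1 - p) * (1 - r),
                    p * (1 - p) * (1 - r),
                    r * p * (1 - p) + p^2)
      # closed-form route (n = 2 shortcut)
      expect_equal(unname(pattern_distribution(params)$q), q_closed,
                   tolerance = 1e-6)
      # forced latent-CDF route
      if (r < 1) {
        expect_equal(unname(pattern_distribution(params, method = "mvn")$q),
                     q_closed, tolerance = 1e-6)
      }
    }
  }
})

test_that("exchangeable fast path agrees with the generic MVN route", {
  params <- bernoulli_params(0.4, n = 4, structure = "exchangeable", r = 0.5)
  q_fast <- pattern_distribution(params)$q
  q_mvn <- pattern_distribution(params, method = "mvn")$q
  expect_equal(q_fast, q_mvn, tolerance = 1e-8)
  # non-homogeneous marginals take the per-pattern integral branch
  params <- bernoulli_params(c(0.3, 0.5, 0.6), structure = "exchangeable",
                             r = 0.4)
  expect_equal(pattern_distribution(params)$q,
               pattern_distribution(params, method = "mvn")$q,
               tolerance = 1e-8)
})

test_that("degenerate sites are held constant with zero correlation", {
  params <- bernoulli_params(c(1, 0.5, 0), structure = "independent")
  q <- pattern_distribution(params)$q
  expect_equal(unname(q[c("100", "110")]), c(0.5, 0.5))
  expect_equal(sum(q), 1)
})

test_that("read sampling is deterministic, respects marginals and correlation", {
  params <- bernoulli_params(c(0.3, 0.6), structure = "exchangeable", r = 0.4)
  x1 <- sample_reads(params, 200, seed = 7)
  x2 <- sample_reads(params, 200, seed = 7)
  expect_identical(x1, x2)

  # perfect correlation: rows constant
  x <- sample_reads(bernoulli_params(0.5, n = 4, structure = "exchangeable",
                                     r = 1), 100, seed = 3)
  expect_true(all(rowSums(x) %in% c(0, 4)))

  # law of large numbers at m = 1e5
  x <- sample_reads(params, 100000, seed = 11)
  se_p <- sqrt(c(0.3 * 0.7, 0.6 * 0.4) / 100000)
  expect_true(all(abs(colMeans(x) - c(0.3, 0.6)) < 3 * se_p))
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.4), 0.02)
})

test_that("empirical pattern frequencies converge to the model distribution", {
  params <- bernoulli_params(c(0.3, 0.5, 0.7), structure = "ar1", r = 0.5)
  q <- pattern_distribution(params)$q
  x <- sample_reads(params, 100000, seed = 13)
  counts <- tabulate(as.integer(x %*% c(4, 2, 1)) + 1, nbins = 8)
  expect_gt(oracle_freq_gof_p(counts, q), 0.001)

  params <- bernoulli_params(0.4, n = 4, structure = "exchangeable", r = 0.6)
  q <- pattern_distribution(params)$q
  x <- sample_reads(params, 100000, seed = 17)
  counts <- tabulate(as.integer(x %*% c(8, 4, 2, 1)) + 1, nbins = 16)
  expect_gt(oracle_freq_gof_p(counts, q), 0.001)
})
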