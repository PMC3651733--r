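# build a synthetic trace with prescribed per-beta U samples
fake_trace <- function(betas, U, direction = "annealing", schedule = NULL) {
  samples <- lapply(U, function(u)
    matrix(c(u, u * 0, u * 0, u * 0, u), ncol = 5, nrow = length(u),
           dimnames = list(NULL, c("U", "ll0", "ll1", "k0", "k1"))))
  structure(list(betas = betas, direction = direction, mode = "ss", Q = 1L,
                 save_interval = 1L, schedule = schedule, samples = samples,
                 U_last = vapply(U, function(u) u[length(u)], numeric(1)),
                 prior_tags = c(NA, NA)),
            class = "bf_trace")
}

test_that("trapezoid estimator: constant potential, minimal path, exactness
           on linear potentials for any grid", {
  tr <- fake_trace(c(0, 0.5, 1), list(2.5, 2.5, 2.5))
  expect_equal(ps_estimate(tr)$log_bf, 2.5)
  tr1 <- fake_trace(c(0, 1), list(1, 3))
  expect_equal(ps_estimate(tr1)$log_bf, 2)        # (U0 + U1) / 2
  for (betas in list(c(0, 0.5, 1), sigmoid_schedule(7, 1, 9)$betas)) {
    trl <- fake_trace(betas, as.list(2 * betas - 0.3))
    expect_equal(ps_estimate(trl)$log_bf, sum(diff(betas^2)) - 0.3,
                 tolerance = 1e-12)              # exact integral of 2b - 0.3
  }
  trb <- fake_trace(c(0, 0.5, 1), as.list(c(0, 0.5, 1)))
  expect_equal(ps_estimate(trb)$log_bf, 0.5)
})

test_that("mean-of-samples estimator: single samples reduce to classic,
           duplication invariance", {
  tr <- fake_trace(c(0, 0.5, 1), list(0.1, 0.6, 1.4))
  expect_equal(ps_mean_estimate(tr)$log_bf, ps_estimate(tr)$log_bf)
  trd <- fake_trace(c(0, 0.5, 1),
                    list(c(0.1, 0.3), 0.6, c(1.2, 1.6)))
  trd2 <- fake_trace(c(0, 0.5, 1),
                     list(rep(c(0.1, 0.3), 2), rep(0.6, 2),
                          rep(c(1.2, 1.6), 2)))
  expect_equal(ps_mean_estimate(trd)$log_bf, ps_mean_estimate(trd2)$log_bf)
})

test_that("stepping-stone step ratio: zero width, single sample, eta
           factoring identity", {
  expect_identical(ss_step_log_ratio(c(1, 2, 3), 0.4, 0.4), 0)
  expect_equal(ss_step_log_ratio(2.2, 0.3, 0.55), 0.25 * 2.2)
  set.seed(51)
  for (i in 1:20) {
    ell <- rnorm(30, sd = runif(1, 0.1, 50))
    d <- runif(1, -0.3, 0.3)
    expect_equal(ss_step_log_ratio(ell, 0.5, 0.5 + d),
                 log(mean(exp(d * ell))), tolerance = 1e-10)
  }
  expect_error(ss_step_log_ratio(numeric(0), 0, 0.1), "empty")
})

test_that("stepping-stone estimator composes steps and orients melting runs", {
  tr0 <- fake_trace(c(0, 0.5, 1), list(0, 0, 0))
  expect_identical(ss_log_bf(tr0)$log_bf, 0)
  tr1 <- fake_trace(c(0, 1), list(1.7, 0))
  expect_equal(ss_log_bf(tr1)$log_bf, 1.7)      # K = 1, d = 1, one sample
  # a melting run of the same deterministic potential gives the same sign
  trm <- fake_trace(c(1, 0.5, 0), list(2, 2, 2), direction = "melting")
  tra <- fake_trace(c(0, 0.5, 1), list(2, 2, 2), direction = "annealing")
  expect_equal(ss_log_bf(trm)$log_bf, ss_log_bf(tra)$log_bf)
})

test_that("discretization error: constant potential, linear potential on a
           constant grid, nonnegativity", {
  trc <- fake_trace(c(0, 0.5, 1), list(3, 3, 3))
  expect_identical(discretization_error(trc), 0)
  for (K in c(2, 5, 20)) {
    b <- 0:K / K
    trl <- fake_trace(b, as.list(b))
    expect_equal(discretization_error(trl), 1 / (2 * K))
  }
  trm <- fake_trace(c(0, 0.3, 1), list(-2, 1, 1.5))
  expect_gte(discretization_error(trm), 0)
})

test_that("path-sampling variance formula: zero variances, worked K = 2
           value, linearity", {
  expect_identical(ps_sampling_variance(c(0, 0.5, 1), c(0, 0, 0)), 0)
  expect_equal(ps_sampling_variance(c(0, 0.5, 1), c(1, 1, 1)), 0.375)
  v <- runif(4)
  b <- c(0, 0.2, 0.7, 1)
  expect_equal(ps_sampling_variance(b, 2 * v),
               2 * ps_sampling_variance(b, v))
  expect_equal(ps_sampling_variance(b, v, tau = 3),
               3 * ps_sampling_variance(b, v))
  expect_error(ps_sampling_variance(b, c(-1, 1, 1, 1)), "negative")
})

test_that("stepping-stone variance: zero spread, two-point hand value,
           single-sample error", {
  trz <- fake_trace(c(0, 0.5, 1), list(c(2, 2), c(1, 1), c(0, 0)))
  expect_identical(ss_variance(trz), 0)
  # hand evaluation, one step (d = 1, samples 0 and log 3):
  # x = (1, 3), rhat = 2, Var = (1/n^2) sum (x - 2)^2 = 2/4, over rhat^2
  trh <- fake_trace(c(0, 1), list(c(0, log(3)), c(0, 0)))
  expect_equal(ss_variance(trh), (2 / 4) / 4)
  tr1 <- fake_trace(c(0, 1), list(1.2, 0))
  expect_error(ss_variance(tr1), "single sample")
})

test_that("harmonic mean estimators: constants, hand values, delta limit,
           independent fixed-point oracle", {
  expect_equal(hme(rep(-3.2, 50)), -3.2)
  expect_equal(hme(c(log(1), log(3))), log(1.5))
  expect_equal(shme(rep(-3.2, 50), 0.3), -3.2)
  expect_equal(shme(c(log(1), log(3)), 1e-8), hme(c(log(1), log(3))),
               tolerance = 1e-6)
  # brute-force scalar fixed point for delta = 0.01 on likelihoods {1, 3}
  d <- 0.01; L <- c(1, 3); n <- 2
  g <- function(z) (d * n / (1 - d) + sum(L / (d * z + (1 - d) * L))) /
    (d * n / ((1 - d) * z) + sum(1 / (d * z + (1 - d) * L)))
  z <- 1.5
  for (i in 1:500) z <- g(z)
  expect_equal(shme(c(log(1), log(3)), 0.01), log(z), tolerance = 1e-8)
  expect_error(hme(numeric(0)), "empty")
  expect_error(shme(c(1, 2), delta = 1.5), "delta")
})

test_that("split contributions are additive and validate boundaries", {
  sched <- add_splits(constant_schedule(10, 1), 5)
  tr <- fake_trace(sched$betas, as.list(sin(sched$betas * 3)),
                   schedule = sched)
  for (m in c("ps", "ss", "ps_mean")) {
    sc <- split_contributions(tr, sched, method = m)
    expect_equal(nrow(sc), 5)
    expect_equal(sum(sc$contribution),
                 switch(m, ps = ps_estimate(tr)$log_bf,
                        ps_mean = ps_mean_estimate(tr)$log_bf,
                        ss = ss_log_bf(tr)$log_bf), tolerance = 1e-10)
  }
  # a single interval reproduces the total
  s1 <- constant_schedule(4, 1); s1$splits <- numeric(0)
  tr1 <- fake_trace(s1$betas, as.list(s1$betas^2), schedule = s1)
  expect_equal(split_contributions(tr1, s1, "ps")$contribution,
               ps_estimate(tr1)$log_bf)
  # constant potential: interval [a, b] contributes c * (b - a)
  trc <- fake_trace(sched$betas, as.list(rep(2, 11)), schedule = sched)
  sc <- split_contributions(trc, sched, "ps")
  expect_equal(sc$contribution, 2 * (sc$hi - sc$lo))
  bad <- constant_schedule(10, 1); bad$splits <- 0.123
  expect_error(split_contributions(tr, bad, "ps"), "grid")
})

test_that("bidirectional summary: identical contributions, hand BDE, lag
           flag", {
  mk <- function(dir, contrib) {
    e <- pathstone:::new_bf_estimate(sum(contrib), "ss", dir)
    e$splits <- data.frame(lo = seq(0, 0.95, by = 0.05),
                           hi = seq(0.05, 1, by = 0.05),
                           contribution = contrib)
    e
  }
  ca <- rep(0.1, 20)
  b0 <- bidirectional_summary(mk("annealing", ca), mk("melting", ca))
  expect_identical(b0$bidirectional_error, 0)
  expect_equal(b0$log_bf, 2)
  b1 <- bidirectional_summary(mk("annealing", ca), mk("melting", ca + 0.1))
  expect_equal(b1$bidirectional_error, 2.0)
  expect_true(b1$thermic_lag)
  expect_error(bidirectional_summary(mk("annealing", ca),
                                     mk("annealing", ca)), "melting")
  bad <- mk("melting", rep(0.2, 10))
  bad$splits <- data.frame(lo = seq(0, 0.9, by = 0.1),
                           hi = seq(0.1, 1, by = 0.1),
                           contribution = rep(0.2, 10))
  expect_error(bidirectional_summary(mk("annealing", ca), bad), "mismatch")
})

test_that("evidence gradations follow the standard scale symmetrically", {
  expect_match(interpret_log_bf(0.5), "bare mention")
  expect_match(interpret_log_bf(2.0), "positive")
  expect_match(interpret_log_bf(2.0), "against M0")
  expect_match(interpret_log_bf(4.0), "^strong")
  expect_match(interpret_log_bf(6.0), "very strong")
  expect_match(interpret_log_bf(-6.0), "very strong")
  expect_match(interpret_log_bf(-2.0), "for M0")
  expect_error(interpret_log_bf(Inf), "finite")
})

test_that("variance comparison: zero covariance equalizes the two routes;
           warnings on unequal priors and single samples", {
  tr <- fake_trace(c(0, 0.5, 1),
                   list(c(0.2, 0.5, 0.1), c(1, 1.4, 0.8), c(0, 0, 0)))
  # ll0 column is zero in fake traces, so cov and var0 terms vanish and the
  # direct and ratio formulas agree when fed the same trace
  vc <- variance_comparison(tr, tr, tr)
  expect_identical(vc$cov_term, 0)      # ll0 is constant in this trace
  expect_equal(vc$var_direct, vc$var_ratio)
  expect_true(vc$direct_le_ratio)
  tr1 <- fake_trace(c(0, 1), list(0.3, 0))
  expect_warning(variance_comparison(tr1, tr1, tr1), "single-sample")
  trw <- tr
  trw$prior_tags <- c("beta(1,1)", "beta(2,2)")
  expect_warning(variance_comparison(trw, tr, tr), "priors differ")
})
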