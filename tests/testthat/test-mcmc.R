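test_that("update cycle targets the analytic posterior on the conjugate
           normal toy at beta = 0", {
  set.seed(41)
  y <- rnorm(8, 1, 1)
  s0 <- conjugate_normal_spec(y, sigma = 1, prior_mean = 0, prior_sd = 2)
  s1 <- conjugate_normal_spec(y, sigma = 1.5, prior_mean = 0, prior_sd = 2)
  pair <- toy_pair(s0, s1, proposal_sd = 1)
  prec <- 8 / 1 + 1 / 4
  post_mean <- sum(y) / prec
  st <- pair_init_state(pair)
  for (i in 1:200) st <- update_cycle(pair, st, 0)
  n <- 10000
  draws <- numeric(n)
  for (i in 1:n) { st <- update_cycle(pair, st, 0); draws[i] <- st$theta }
  tau <- effective_samples(draws)$tau
  mcse <- sd(draws) / sqrt(n / tau)
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse)
})

test_that("power-posterior chain passes a goodness-of-fit test against the
           analytic beta-binomial power posterior", {
  pair <- default_bb_pair()
  set.seed(42)
  st <- pair_init_state(pair)
  for (i in 1:500) st <- update_cycle(pair, st, 0.5)
  n <- 20000
  draws <- numeric(n)
  for (i in 1:n) {            # thin to decorrelate for the chi-square test
    for (j in 1:10) st <- update_cycle(pair, st, 0.5)
    draws[i] <- st$theta
  }
  ab <- bb_power_posterior(20, 14, 1, 1, 2, 2, 0.5)
  qs <- qbeta(seq(0.05, 0.95, by = 0.05), ab[1], ab[2])
  obs <- table(cut(draws, c(0, qs, 1)))
  chisq <- sum((obs - n / 20)^2 / (n / 20))
  expect_lt(chisq, qchisq(0.99, df = 19))
})

test_that("degenerate proposal scale keeps the state fixed; simplex and
           support invariants survive phylo cycles", {
  pair <- toy_pair(beta_binomial_spec(10, 4), beta_binomial_spec(10, 4, 2, 2),
                   proposal_sd = 0)
  st <- list(theta = 0.37)
  expect_identical(update_cycle(pair, st, 0.5)$theta, 0.37)

  aln <- simulate_alignment(simulation_spec(tree5(), 60, gtr_params(),
                                            seed = 43))
  pp <- phylo_pair(aln, tree5(), root_order = 1)
  set.seed(44)
  st <- pair_init_state(pp)
  for (i in 1:5) st <- update_cycle(pp, st, 0.6)
  expect_equal(sum(st$gtr$freqs), 1, tolerance = 1e-12)
  expect_true(all(st$branch_lengths > 0))
  expect_true(all(st$aug %in% c(1:4, NA)))
  expect_true(pathstone:::context_rows_valid(st$context))
  for (w in 1:4) for (y in 1:4) {
    pm <- st$context$psi[, , w, y]; diag(pm) <- 0
    expect_equal(sum(st$context$f[w, , y] * rowSums(pm)), 1,
                 tolerance = 1e-9)
  }
  expect_equal(rowSums(st$root_chain$trans), rep(1, 4), tolerance = 1e-12)
})

test_that("run_path contract: grid coverage, identical-model potential,
           seed determinism", {
  pair <- default_bb_pair()
  tr <- run_path(pair, constant_schedule(1, Q = 5), mode = "classic",
                 n_equil = 5, seed = 45)
  expect_length(tr$betas, 2)
  same <- toy_pair(beta_binomial_spec(20, 14, 2, 2),
                   beta_binomial_spec(20, 14, 2, 2))
  tr0 <- run_path(same, constant_schedule(3, Q = 4), mode = "ss",
                  n_equil = 4, save_interval = 2, seed = 46)
  expect_true(all(vapply(tr0$samples, function(m) all(m[, "U"] == 0),
                         logical(1))))
  s <- sigmoid_schedule(5, Q = 6, alpha = 8)
  t1 <- run_path(pair, s, mode = "ss", n_equil = 6, save_interval = 2,
                 seed = 47)
  t2 <- run_path(pair, s, mode = "ss", n_equil = 6, save_interval = 2,
                 seed = 47)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$U_last, t2$U_last)
  # melting traverses the reversed grid
  tm <- run_path(pair, reverse_schedule(s), mode = "classic", n_equil = 6,
                 seed = 48)
  expect_identical(tm$betas, rev(s$betas))
  expect_true(all(diff(tm$betas) < 0))
})

test_that("effective sample size: white noise, duplicated series, constant
           series", {
  set.seed(49)
  x <- rnorm(2000)
  es <- effective_samples(x)
  expect_lt(abs(es$tau - 1), 0.25)
  # strong positive autocorrelation halves the effective size or worse
  y <- rep(rnorm(50), each = 8)
  es2 <- effective_samples(y)
  expect_lte(es2$K_eff, length(y) / 2)
  expect_warning(es3 <- effective_samples(rep(3, 10)), "constant")
  expect_identical(es3$tau, 1)
  expect_error(effective_samples(1:5), "at least 10")
})

test_that("annealing underestimates and melting overestimates when the
           chain lags behind beta (thermic lag direction)", {
  # the prior-to-posterior path has a steep E_beta[U] profile, where a
  # too-short per-step chain (Q = 5) visibly lags behind the moving beta
  pair <- marginal_pair(beta_binomial_spec(200, 140))
  sched <- sigmoid_schedule(50, Q = 5, alpha = 10)
  la <- lm <- numeric(20)
  for (r in 1:20) {
    ta <- run_path(pair, sched, mode = "classic", seed = 400 + r)
    tm <- run_path(pair, reverse_schedule(sched), mode = "classic",
                   seed = 900 + r)
    la[r] <- ps_estimate(ta)$log_bf
    lm[r] <- ps_estimate(tm)$log_bf
  }
  expect_lt(mean(la), mean(lm))
})
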