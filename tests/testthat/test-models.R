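test_that("GTR transition probabilities: zero time, Jukes-Cantor closed form,
           reversibility", {
  p <- gtr_params()
  expect_equal(gtr_transition_probs(p, 0), diag(4), ignore_attr = TRUE)
  P <- gtr_transition_probs(p, 0.5)
  expect_equal(diag(P), rep(0.25 + 0.75 * exp(-4 * 0.5 / 3), 4),
               ignore_attr = TRUE, tolerance = 1e-12)
  p2 <- random_gtr(4)
  P2 <- gtr_transition_probs(p2, 1.0)
  expect_equal(rowSums(P2), rep(1, 4), ignore_attr = TRUE)
  bal <- p2$freqs * P2                  # pi_x P(x -> z)
  expect_equal(bal, t(bal), tolerance = 1e-12)
  # unit expected substitution rate at stationarity
  q <- gtr_rate_matrix(p2)
  expect_equal(-sum(p2$freqs * diag(q)), 1)
  expect_error(gtr_transition_probs(p, -1), "nonnegative")
  expect_error(gtr_params(freqs = c(0.5, 0.5, 0.2, 0.2)), "sum to 1")
})

test_that("psi lookup: gap rule, completion, strand symmetry", {
  m <- context_model_params()
  expect_identical(psi_lookup(m, "A", "C", "-", "T"), 1)
  expect_identical(psi_lookup(m, "A", "C", "G", "N"), 1)
  for (x in 1:4) for (w in 1:4) for (y in 1:4)
    expect_equal(sum(vapply(1:4, function(z) psi_lookup(m, x, z, w, y),
                            numeric(1))), 1)
  set.seed(11)
  ms <- context_model_params(array(runif(256), rep(4, 4)),
                             strand_symmetric = TRUE)
  cc <- c(4, 3, 2, 1)
  for (x in 1:4) for (z in 1:4) for (w in 1:4) for (y in 1:4) {
    if (x == z) next
    expect_equal(psi_lookup(ms, x, z, w, y),
                 psi_lookup(ms, cc[x], cc[z], cc[y], cc[w]))
  }
  expect_equal(psi_lookup(ms, "C", "T", "A", "G"),
               psi_lookup(ms, "G", "A", "C", "T"))
})

test_that("context normalization: scaling identity, idempotence,
           ratio preservation, zero-mass error", {
  # uniform f and equal off-diagonal weights scale to exactly 1/3
  f <- array(0.25, c(4, 4, 4))
  m <- context_model_params(array(1, rep(4, 4)), f = f)
  off <- m$psi; for (x in 1:4) off[x, x, , ] <- NA
  expect_equal(unique(stats::na.omit(as.vector(off))), 1 / 3)
  # the weighted sum is 1 in every context after normalization
  set.seed(12)
  m2 <- context_model_params(array(rexp(256), rep(4, 4)))
  for (w in 1:4) for (y in 1:4) {
    pm <- m2$psi[, , w, y]; diag(pm) <- 0
    expect_equal(sum(m2$f[w, , y] * rowSums(pm)), 1, tolerance = 1e-12)
  }
  m3 <- normalize_context_model(m2)
  expect_equal(m3$psi, m2$psi, tolerance = 1e-13)
  # within-context ratios survive normalization
  raw <- array(rexp(256), rep(4, 4))
  mr <- context_model_params(raw, normalize = FALSE)
  mn <- normalize_context_model(mr)
  r_raw <- raw[1, 2, 3, 3] / raw[2, 4, 3, 3]
  expect_equal(mn$psi[1, 2, 3, 3] / mn$psi[2, 4, 3, 3], r_raw)
  expect_error(context_model_params(array(0, rep(4, 4)), f = f,
                                    normalize = TRUE), "zero total")
})

test_that("free-parameter counts match the model definitions", {
  expect_identical(count_free_parameters("context"), 192L)
  expect_identical(count_free_parameters("context", strand_symmetric = TRUE),
                   96L)
  expect_identical(count_free_parameters("single_context"), 12L)
  expect_identical(count_free_parameters("gtr"), 8L)
  expect_error(count_free_parameters("codon"))
})

test_that("root chain log probabilities: uniform, gaps, hand-computed chain", {
  expect_equal(root_log_prob(root_markov_chain(0), rep("A", 8)),
               8 * log(0.25))
  for (ord in 0:2)
    expect_identical(root_log_prob(root_markov_chain(ord), rep("-", 6)), 0)
  tr <- matrix(c(.5, .2, .2, .1, .1, .6, .2, .1,
                 .25, .25, .25, .25, .4, .3, .2, .1), 4, 4, byrow = TRUE)
  rc <- root_markov_chain(1, trans = tr, init = c(.4, .3, .2, .1))
  expect_equal(root_log_prob(rc, c("A", "C", "G")), log(.4 * .2 * .2))
  # interior gap: its own factor and the next conditioning factor drop out
  expect_equal(root_log_prob(rc, c("A", "-", "G")), log(.4))
  expect_error(root_log_prob(rc, character(0)), "empty")
})

test_that("prior log density: flat Dirichlet constant, exponential and
           inverse-gamma terms, support", {
  expect_equal(exp(pathstone:::flat_dirichlet_log(rep(0.25, 4))), 6)
  expect_equal(exp(pathstone:::flat_dirichlet_log(rep(1 / 12, 12))),
               factorial(11))
  expect_equal(stats::dexp(0, rate = 1 / 2), 0.5)
  expect_equal(exp(dinvgamma_log(1, 2.1, 1.1)),
               1.1^2.1 / gamma(2.1) * exp(-1.1))
  pair <- phylo_pair(simulate_alignment(
    simulation_spec(tree5(), 20, gtr_params(), seed = 3)), tree5())
  st <- local({ set.seed(1); pair_init_state(pair) })
  lp <- prior_log_density(st, prior_config())
  expect_true(is.finite(lp))
  st$mu <- -1
  expect_identical(prior_log_density(st, prior_config()), -Inf)
  st$mu <- 1
  # 1-D slice over one branch length integrates to the exponential mass
  base <- prior_log_density(st, prior_config())
  t0 <- st$branch_lengths[1]
  dens <- function(t) vapply(t, function(ti) {
    st$branch_lengths[1] <- ti
    exp(prior_log_density(st, prior_config()) - base)
  }, numeric(1))
  mass <- stats::integrate(dens, 0, 5 * st$mu)$value
  st$branch_lengths[1] <- t0
  expected <- (stats::pexp(5 * st$mu, 1 / st$mu)) /
    stats::dexp(t0, 1 / st$mu)
  expect_equal(mass, expected, tolerance = 1e-6)
})
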