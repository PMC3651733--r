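#' Model pairs
#'
#' A model pair bundles two competing Bayesian models sharing the same data
#' and exposes the interface the path machinery needs: an initial state, the
#' two unnormalized posterior log kernels (likelihood + prior), and one
#' Metropolis-within-Gibbs update cycle targeting the power posterior
#' `q_beta = kernel_0^(1-beta) * kernel_1^beta`. The normalizing-constant
#' ratio of the endpoint kernels is the Bayes factor `Z_1 / Z_0`.
#'
#' @name model_pairs
NULL

#' @rdname model_pairs
#' @param pair a model pair object.
#' @export
pair_init_state <- function(pair) UseMethod("pair_init_state")

#' @rdname model_pairs
#' @param state a parameter state.
#' @param model 0 or 1.
#' @export
pair_log_kernel <- function(pair, state, model) UseMethod("pair_log_kernel")

#' @rdname model_pairs
#' @export
pair_log_lik <- function(pair, state, model) UseMethod("pair_log_lik")

#' One Metropolis-within-Gibbs update cycle at inverse temperature beta
#'
#' A cycle proposes an update for every model parameter (and, for the
#' phylogenetic pair, every branch length and every ancestral site).
#' Rejected proposals keep the current values, so all state invariants are
#' preserved.
#'
#' @param pair a model pair.
#' @param state current state.
#' @param beta inverse temperature in `[0, 1]`.
#' @return The updated state.
#' @export
update_cycle <- function(pair, state, beta) UseMethod("update_cycle")

#' Analytic toy model specifications
#'
#' Conjugate toys with closed-form marginal likelihoods, used as oracles for
#' the path estimators. `beta_binomial_spec`: `k` successes in `n`
#' Bernoulli trials with a Beta prior on the success probability.
#' `conjugate_normal_spec`: observations with known standard deviation
#' `sigma` and a normal prior on the mean.
#'
#' @param n,k trial and success counts.
#' @param shape1,shape2 Beta prior parameters.
#' @return Object of class `toy_spec`.
#' @export
beta_binomial_spec <- function(n, k, shape1 = 1, shape2 = 1) {
  stopifnot(n >= 1, k >= 0, k <= n, shape1 > 0, shape2 > 0)
  structure(list(family = "beta_binomial", n = n, k = k,
                 shape1 = shape1, shape2 = shape2),
            class = "toy_spec")
}

#' @rdname beta_binomial_spec
#' @param y numeric observations.
#' @param sigma known observation standard deviation.
#' @param prior_mean,prior_sd normal prior on the mean.
#' @export
conjugate_normal_spec <- function(y, sigma = 1, prior_mean = 0,
                                  prior_sd = 1) {
  stopifnot(length(y) >= 1, sigma > 0, prior_sd > 0)
  structure(list(family = "conjugate_normal", y = y, sigma = sigma,
                 prior_mean = prior_mean, prior_sd = prior_sd),
            class = "toy_spec")
}

toy_log_lik <- function(spec, theta) {
  switch(spec$family,
    beta_binomial = {
      if (theta <= 0 || theta >= 1) return(-Inf)
      stats::dbinom(spec$k, spec$n, theta, log = TRUE)
    },
    conjugate_normal =
      sum(stats::dnorm(spec$y, theta, spec$sigma, log = TRUE)))
}

toy_log_prior <- function(spec, theta) {
  switch(spec$family,
    beta_binomial = stats::dbeta(theta, spec$shape1, spec$shape2, log = TRUE),
    conjugate_normal =
      stats::dnorm(theta, spec$prior_mean, spec$prior_sd, log = TRUE))
}

toy_data_signature <- function(spec) {
  switch(spec$family,
    beta_binomial = paste0("bb:", spec$n, ":", spec$k),
    conjugate_normal = paste0("nm:", paste(signif(spec$y, 12), collapse = ",")))
}

toy_prior_signature <- function(spec) {
  switch(spec$family,
    beta_binomial = paste0("beta(", spec$shape1, ",", spec$shape2, ")"),
    conjugate_normal = paste0("normal(", spec$prior_mean, ",",
                              spec$prior_sd, ")"))
}

#' Toy model pair for direct Bayes factor estimation
#'
#' Both specs must describe the same observed data; they may differ in prior
#' (and, for the normal family, in the likelihood's `sigma`). Setting
#' `prior_reference = TRUE` replaces model 0's likelihood by the constant 1,
#' turning the model-switch path into the prior-to-posterior path of model 1
#' so the run estimates model 1's log marginal likelihood.
#'
#' @param spec0,spec1 [beta_binomial_spec()] / [conjugate_normal_spec()]
#'   objects sharing the same data.
#' @param proposal_sd random-walk proposal scale (logit scale for the
#'   beta-binomial success probability).
#' @param prior_reference logical (see above).
#' @return Object of class `toy_pair` (a `bf_pair`).
#' @export
toy_pair <- function(spec0, spec1, proposal_sd = 0.8,
                     prior_reference = FALSE) {
  stopifnot(inherits(spec0, "toy_spec"), inherits(spec1, "toy_spec"))
  if (spec0$family != spec1$family)
    stop("both specs must come from the same toy family")
  if (!identical(toy_data_signature(spec0), toy_data_signature(spec1)))
    stop("the two specs must share the same observed data")
  structure(list(spec0 = spec0, spec1 = spec1, proposal_sd = proposal_sd,
                 prior_reference = prior_reference,
                 prior_tags = c(toy_prior_signature(spec0),
                                toy_prior_signature(spec1))),
            class = c("toy_pair", "bf_pair"))
}

#' Marginal-likelihood path for a single toy model
#'
#' Convenience wrapper for [toy_pair()] with a prior-only reference model:
#' stepping-stone or path sampling on this pair estimates the log marginal
#' likelihood of `spec`.
#'
#' @param spec a `toy_spec`.
#' @inheritParams toy_pair
#' @return A `toy_pair` with `prior_reference = TRUE`.
#' @export
marginal_pair <- function(spec, proposal_sd = 0.8) {
  toy_pair(spec, spec, proposal_sd = proposal_sd, prior_reference = TRUE)
}

#' @export
pair_init_state.toy_pair <- function(pair) {
  spec <- pair$spec1
  theta <- switch(spec$family,
    beta_binomial = stats::rbeta(1, spec$shape1, spec$shape2),
    conjugate_normal = stats::rnorm(1, spec$prior_mean, spec$prior_sd))
  list(theta = theta)
}

#' @export
pair_log_lik.toy_pair <- function(pair, state, model) {
  if (model == 0 && pair$prior_reference) return(0)
  spec <- if (model == 0) pair$spec0 else pair$spec1
  toy_log_lik(spec, state$theta)
}

#' @export
pair_log_kernel.toy_pair <- function(pair, state, model) {
  spec <- if (model == 0) pair$spec0 else pair$spec1
  pair_log_lik(pair, state, model) + toy_log_prior(spec, state$theta)
}

toy_power_target <- function(pair, theta, beta) {
  st <- list(theta = theta)
  (1 - beta) * pair_log_kernel(pair, st, 0L) +
    beta * pair_log_kernel(pair, st, 1L)
}

#' @export
update_cycle.toy_pair <- function(pair, state, beta) {
  sd <- pair$proposal_sd
  if (sd <= 0) return(state)
  theta <- state$theta
  if (pair$spec1$family == "beta_binomial") {
    # random walk on the logit scale; Jacobian p(1-p) enters the ratio
    l <- stats::qlogis(theta)
    lp <- l + stats::rnorm(1, 0, sd)
    thetap <- stats::plogis(lp)
    if (thetap <= 0 || thetap >= 1) return(state)
    log_acc <- toy_power_target(pair, thetap, beta) -
      toy_power_target(pair, theta, beta) +
      log(thetap * (1 - thetap)) - log(theta * (1 - theta))
  } else {
    thetap <- theta + stats::rnorm(1, 0, sd)
    log_acc <- toy_power_target(pair, thetap, beta) -
      toy_power_target(pair, theta, beta)
  }
  if (is.finite(log_acc) && log(stats::runif(1)) < log_acc)
    state$theta <- thetap
  state
}
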