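#' Log Bayes factor estimates
#'
#' All path-based estimators return a `bf_estimate`: the log Bayes factor
#' `log Z_1 - log Z_0` (always oriented model 1 over model 0, whatever the
#' traversal direction), the method and direction tags, an estimated
#' simulation variance, the discretization error for path sampling, and
#' per-split-interval contributions when the schedule defines splits.
#'
#' @name bf_estimate
NULL

new_bf_estimate <- function(log_bf, method, direction, variance = NA_real_,
                            discretization_error = NA_real_,
                            bidirectional_error = NA_real_,
                            splits = NULL, thermic_lag = NA) {
  structure(list(log_bf = log_bf, method = method, direction = direction,
                 variance = variance,
                 discretization_error = discretization_error,
                 bidirectional_error = bidirectional_error,
                 splits = splits, thermic_lag = thermic_lag),
            class = "bf_estimate")
}

#' @export
print.bf_estimate <- function(x, ...) {
  cat(sprintf("<bf_estimate> log BF = %.4f  [%s, %s]\n",
              x$log_bf, x$method, x$direction))
  if (is.finite(x$variance))
    cat(sprintf("  simulation variance: %.4g (sd %.4g)\n",
                x$variance, sqrt(x$variance)))
  if (is.finite(x$discretization_error))
    cat(sprintf("  discretization error: %.4g\n", x$discretization_error))
  if (is.finite(x$bidirectional_error))
    cat(sprintf("  bidirectional error: %.4g\n", x$bidirectional_error))
  cat(" ", interpret_log_bf(x$log_bf), "\n")
  invisible(x)
}

# per-segment contributions oriented from beta = 0 to beta = 1.
# methods: classic trapezoid ("ps"), mean-of-samples trapezoid ("ps_mean"),
# stepping-stone importance ratios ("ss").
segment_terms <- function(trace, method = c("ps", "ps_mean", "ss")) {
  method <- match.arg(method)
  betas <- trace$betas
  K <- length(betas) - 1L
  if (K < 1) stop("trace needs at least one path step")
  if (method == "ss") {
    lr <- vapply(seq_len(K), function(j)
      ss_step_log_ratio(trace$samples[[j]][, "U"], betas[j], betas[j + 1]),
      numeric(1))
    lo <- pmin(betas[-(K + 1)], betas[-1])
    hi <- pmax(betas[-(K + 1)], betas[-1])
    contrib <- if (trace$direction == "annealing") lr else -lr
    ord <- order(lo)
    return(data.frame(lo = lo[ord], hi = hi[ord],
                      contribution = contrib[ord]))
  }
  ord <- trace_increasing(trace)
  b <- betas[ord]
  u <- if (method == "ps") trace$U_last[ord]
       else vapply(trace$samples[ord], function(m) mean(m[, "U"]), numeric(1))
  d <- diff(b)
  data.frame(lo = b[-length(b)], hi = b[-1],
             contribution = d * (u[-length(u)] + u[-1]) / 2)
}

attach_splits <- function(est, trace, method) {
  sched <- trace$schedule
  if (!is.null(sched) && length(sched$splits))
    est$splits <- split_contributions(trace, sched, method = method)
  est
}

#' Classic path-sampling estimate
#'
#' Trapezoid quadrature of the potential over the beta grid using the single
#' value saved before each beta update:
#' `sum_k (beta_{k+1} - beta_k) * (U_k + U_{k+1}) / 2`. Reduces to the
#' constant-increment Simpson triangulation on uniform grids.
#'
#' @param trace a `bf_trace` from [run_path()].
#' @return A `bf_estimate`.
#' @export
ps_estimate <- function(trace) {
  seg <- segment_terms(trace, "ps")
  est <- new_bf_estimate(sum(seg$contribution), "ps", trace$direction,
                         discretization_error = discretization_error(trace))
  attach_splits(est, trace, "ps")
}

#' Mean-of-samples path-sampling estimate
#'
#' The trapezoid rule applied to the per-beta sample means of the potential,
#' using every sample collected along the run instead of only the last state
#' at each beta.
#'
#' @param trace a `bf_trace` in `"mean"` or `"ss"` mode.
#' @return A `bf_estimate` with sampling variance (decorrelation-time
#'   corrected) when at least two samples per beta are available.
#' @export
ps_mean_estimate <- function(trace) {
  ns <- vapply(trace$samples, nrow, integer(1))
  if (any(ns < 1)) stop("a beta has zero samples")
  seg <- segment_terms(trace, "ps_mean")
  v <- tryCatch(ps_sampling_variance_trace(trace), error = function(e) NA_real_)
  est <- new_bf_estimate(sum(seg$contribution), "ps_mean", trace$direction,
                         variance = v,
                         discretization_error = discretization_error(trace))
  attach_splits(est, trace, "ps_mean")
}

#' One stepping-stone importance-sampling ratio
#'
#' Estimates `log(c_{beta_k} / c_{beta_prev})` from samples of the
#' log kernel ratio `ell_i = log q_1(theta_i) - log q_0(theta_i)` drawn at
#' `beta_prev`, with the largest sampled term factored out for numerical
#' stability:
#' `log r_k = d * log eta + log( mean exp(d * (ell_i - log eta)) )` with
#' `d = beta_k - beta_prev` and `log eta = max_i ell_i`. Algebraically
#' identical to the unfactored mean of `exp(d * ell_i)`.
#'
#' @param ell numeric vector of sampled log kernel ratios.
#' @param beta_prev,beta_k the step's endpoints.
#' @return The step's log ratio.
#' @export
ss_step_log_ratio <- function(ell, beta_prev, beta_k) {
  if (length(ell) < 1) stop("empty sample set")
  d <- beta_k - beta_prev
  if (d == 0) return(0)
  log_eta <- max(ell)
  d * log_eta + log(mean(exp(d * (ell - log_eta))))
}

#' Model-switch stepping-stone estimate of the log Bayes factor
#'
#' Sums the per-step log importance ratios over all K steps; on the natural
#' scale the product of the (independent, unbiased) step ratios is an
#' unbiased estimate of the Bayes factor, while the log transform introduces
#' a bias that shrinks as K grows.
#'
#' @param trace a `bf_trace` with samples at every grid point.
#' @return A `bf_estimate` with the delta-method simulation variance when at
#'   least two samples per step are available.
#' @export
ss_log_bf <- function(trace) {
  seg <- segment_terms(trace, "ss")
  v <- tryCatch(ss_variance(trace), error = function(e) NA_real_)
  est <- new_bf_estimate(sum(seg$contribution), "ss", trace$direction,
                         variance = v)
  attach_splits(est, trace, "ss")
}

#' Discretization error of a path-sampling run
#'
#' For a monotone `E_beta[U]`, the worst-case quadrature error is the area
#' between the piecewise-linear interpolant and the bounding step functions:
#' `sigma_d = | sum_k (beta_{k+1} - beta_k) (E_{k+1}[U] - E_k[U]) / 2 |`.
#' `E_beta[U]` is estimated by the per-beta sample mean (the single saved
#' value in classic mode).
#'
#' @param trace a `bf_trace`.
#' @return `sigma_d >= 0`.
#' @export
discretization_error <- function(trace) {
  ord <- trace_increasing(trace)
  b <- trace$betas[ord]
  if (length(b) < 2) stop("need at least two beta values")
  e <- vapply(trace$samples[ord], function(m) mean(m[, "U"]), numeric(1))
  abs(sum(diff(b) * diff(e) / 2))
}

#' Sampling variance of the trapezoid path-sampling estimator
#'
#' For independent draws,
#' `V = 1/4 * [ sum_k d_k^2 (V_k + V_{k+1}) + 2 sum_{k=1}^{K-1} d_k d_{k-1} V_k ]`
#' with `d_k = beta_{k+1} - beta_k` and `V_k` the variance of the potential
#' estimate at grid point `k`; the neighbor cross terms arise because each
#' interior grid point enters two trapezoids. Serially correlated samples
#' inflate the result by the decorrelation time `tau`.
#'
#' @param betas increasing beta grid.
#' @param per_beta_variances `V_k`, one per grid point (>= 0).
#' @param tau decorrelation time (>= 1), see [effective_samples()].
#' @return The sampling variance.
#' @export
ps_sampling_variance <- function(betas, per_beta_variances, tau = 1) {
  K <- length(betas) - 1L
  stopifnot(length(per_beta_variances) == K + 1, tau >= 1)
  if (any(per_beta_variances < 0)) stop("negative variance inputs")
  d <- diff(betas)
  v <- per_beta_variances
  s1 <- sum(d^2 * (v[-(K + 1)] + v[-1]))
  s2 <- if (K >= 2) 2 * sum(d[-1] * d[-K] * v[2:K]) else 0
  tau * (s1 + s2) / 4
}

# variance of the mean estimator from a samples-mode trace: V_k is the
# variance of the per-beta mean, tau averaged over grid points.
ps_sampling_variance_trace <- function(trace) {
  ord <- trace_increasing(trace)
  b <- trace$betas[ord]
  sam <- trace$samples[ord]
  ns <- vapply(sam, nrow, integer(1))
  if (any(ns < 2)) stop("need >= 2 samples per beta for a variance estimate")
  v <- vapply(sam, function(m) stats::var(m[, "U"]), numeric(1)) / ns
  taus <- vapply(sam, function(m) {
    if (nrow(m) >= 10 && stats::sd(m[, "U"]) > 0)
      effective_samples(m[, "U"])$tau else 1
  }, numeric(1))
  ps_sampling_variance(b, v, tau = mean(taus))
}

#' Delta-method simulation variance of the stepping-stone estimator
#'
#' `Var(log r) ~= sum_k Var(r_k) / r_k^2`, each step's term computed stably
#' after factoring out the largest sampled ratio
#' (`Var(r_k) = (1/n^2) sum_i (x_i - r_k)^2` over the sampled powered
#' ratios `x_i`).
#'
#' @param trace a `bf_trace` with >= 2 samples per step.
#' @return The variance estimate (direction-independent).
#' @export
ss_variance <- function(trace) {
  betas <- trace$betas
  K <- length(betas) - 1L
  total <- 0
  for (j in seq_len(K)) {
    ell <- trace$samples[[j]][, "U"]
    n <- length(ell)
    if (n < 2) stop("variance undefined with a single sample at a step")
    d <- betas[j + 1] - betas[j]
    w <- exp(d * (ell - max(ell)))
    m <- mean(w)
    total <- total + sum((w - m)^2) / (n^2 * m^2)
  }
  total
}

#' Harmonic mean estimator of the log marginal likelihood
#'
#' `log N - logsumexp(-loglik_i)` over posterior-sample log likelihoods; the
#' classical estimator that systematically overestimates the marginal
#' likelihood of parameter-rich models because posterior samples almost
#' never visit the low-likelihood region.
#'
#' @param log_likelihoods numeric vector of posterior-sample log likelihoods.
#' @return The log marginal likelihood estimate.
#' @export
hme <- function(log_likelihoods) {
  if (length(log_likelihoods) < 1) stop("empty input")
  log(length(log_likelihoods)) - logsumexp(-log_likelihoods)
}

#' Stabilized harmonic mean estimator
#'
#' The delta-mixture stabilization: the posterior sample is imagined mixed
#' with a fraction `delta` of prior draws whose likelihood equals the
#' current marginal-likelihood estimate, and the resulting self-consistency
#' equation is iterated to its fixed point. `delta -> 0` recovers [hme()].
#'
#' @param log_likelihoods numeric vector of posterior-sample log likelihoods.
#' @param delta mixture weight in (0, 1); default 0.01.
#' @param tol convergence tolerance on the log estimate.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return The stabilized log marginal likelihood estimate.
#' @export
shme <- function(log_likelihoods, delta = 0.01, tol = 1e-10,
                 max_iter = 1000L) {
  if (length(log_likelihoods) < 1) stop("empty input")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  ll <- log_likelihoods
  n <- length(ll)
  log_m <- log(delta) + log(n) - log1p(-delta)  # imaginary prior draws
  logz <- hme(ll)
  if (!is.finite(logz)) logz <- mean(ll)
  for (it in seq_len(max_iter)) {
    denom_i <- vapply(ll, function(l)
      logsumexp(c(log(delta) + logz, log1p(-delta) + l)), numeric(1))
    num <- logsumexp(c(log_m, ll - denom_i))
    den <- logsumexp(c(log_m - logz, -denom_i))
    logz_new <- num - den
    if (abs(logz_new - logz) < tol) return(logz_new)
    logz <- logz_new
  }
  stop("stabilized harmonic mean iteration did not converge after ",
       max_iter, " iterations")
}

#' Compare direct-path and ratio-of-marginals stepping-stone variances
#'
#' Under equal model priors, the delta-method variance of the direct
#' model-switch Bayes factor estimator differs from that of the ratio of two
#' independently estimated marginal likelihoods only by a covariance term
#' (the two likelihood powers are evaluated at the same draws on the direct
#' path), which is expected to be positive, making the direct path the
#' lower-variance route.
#'
#' @param direct_trace model-switch trace between the two models.
#' @param ml_trace_0,ml_trace_1 independent prior-to-posterior traces for
#'   each model (e.g. from [marginal_pair()] runs).
#' @return List with the direct-path relative variance (`var_direct`,
#'   including the covariance term), the ratio-based variance (`var_ratio`),
#'   the covariance term itself, and the ordering flag `direct_le_ratio`.
#' @export
variance_comparison <- function(direct_trace, ml_trace_0, ml_trace_1) {
  tags <- direct_trace$prior_tags
  if (!is.na(tags[1]) && !is.na(tags[2]) && !identical(tags[1], tags[2]))
    warning("model priors differ; the equal-prior variance comparison ",
            "assumption is violated")
  step_rel <- function(trace, col) {
    betas <- trace$betas
    vapply(seq_len(length(betas) - 1L), function(j) {
      v <- trace$samples[[j]][, col]
      n <- length(v)
      if (n < 2) return(NA_real_)
      d <- betas[j + 1] - betas[j]
      w <- exp(d * (v - max(v)))
      m <- mean(w)
      sum((w - m)^2) / (n^2 * m^2)
    }, numeric(1))
  }
  step_relcov <- function(trace) {
    betas <- trace$betas
    vapply(seq_len(length(betas) - 1L), function(j) {
      s <- trace$samples[[j]]
      n <- nrow(s)
      if (n < 2) return(NA_real_)
      d <- betas[j + 1] - betas[j]
      w <- exp(d * (s[, "ll1"] - max(s[, "ll1"])))
      u <- exp(d * (s[, "ll0"] - max(s[, "ll0"])))
      2 * sum((w - mean(w)) * (u - mean(u))) / (n^2 * mean(w) * mean(u))
    }, numeric(1))
  }
  rv1 <- step_rel(direct_trace, "ll1")
  rv0 <- step_rel(direct_trace, "ll0")
  rc <- step_relcov(direct_trace)
  if (anyNA(c(rv1, rv0, rc))) {
    warning("single-sample steps: variances undefined (n = 1)")
  }
  var_direct <- sum(rv1 + rv0 - rc)
  cov_term <- sum(rc)
  var_ratio <- sum(step_rel(ml_trace_0, "ll0")) +
    sum(step_rel(ml_trace_1, "ll1"))
  list(var_direct = var_direct, var_ratio = var_ratio,
       var_direct_no_cov = sum(rv1 + rv0), cov_term = cov_term,
       direct_le_ratio = isTRUE(var_direct <= var_ratio))
}

#' Combine annealing and melting estimates
#'
#' The bidirectional estimate is the mean of the two directional log Bayes
#' factors; the bidirectional error (BDE) is the sum over split intervals of
#' the absolute annealing-vs-melting contribution differences — a
#' repeatability diagnostic. The thermic-lag flag records whether the
#' annealing estimate fell below the melting estimate, the direction
#' expected when the chain lags behind the moving beta.
#'
#' @param annealing,melting `bf_estimate`s from the two traversal
#'   directions, with matching split boundaries (an estimate without splits
#'   is treated as a single interval).
#' @return A `bf_estimate` with direction `"bidirectional"`.
#' @export
bidirectional_summary <- function(annealing, melting) {
  stopifnot(inherits(annealing, "bf_estimate"),
            inherits(melting, "bf_estimate"))
  if (annealing$direction != "annealing" || melting$direction != "melting")
    stop("expected one annealing and one melting estimate")
  one_interval <- function(e)
    data.frame(lo = 0, hi = 1, contribution = e$log_bf)
  sa <- annealing$splits %||% one_interval(annealing)
  sm <- melting$splits %||% one_interval(melting)
  if (nrow(sa) != nrow(sm) ||
      any(abs(sa$lo - sm$lo) > 1e-9) || any(abs(sa$hi - sm$hi) > 1e-9))
    stop("mismatched split boundaries between directions")
  bde <- sum(abs(sa$contribution - sm$contribution))
  v <- if (is.finite(annealing$variance) && is.finite(melting$variance))
    (annealing$variance + melting$variance) / 4 else NA_real_
  new_bf_estimate((annealing$log_bf + melting$log_bf) / 2,
                  annealing$method, "bidirectional", variance = v,
                  bidirectional_error = bde,
                  splits = data.frame(
                    lo = sa$lo, hi = sa$hi,
                    contribution = (sa$contribution + sm$contribution) / 2),
                  thermic_lag = annealing$log_bf < melting$log_bf)
}

#' Interpret a log Bayes factor on the standard evidence scale
#'
#' Gradations for the log Bayes factor as evidence against model 0: values
#' in (0, 1] are not worth more than a bare mention, (1, 3] positive,
#' (3, 5] strong, above 5 very strong. Negative values are read
#' symmetrically as evidence for model 0.
#'
#' @param value finite log Bayes factor.
#' @return A character description.
#' @export
interpret_log_bf <- function(value) {
  if (!is.finite(value)) stop("value must be finite")
  if (value == 0) return("no evidence either way")
  a <- abs(value)
  grade <- if (a <= 1) "not worth more than a bare mention"
  else if (a <= 3) "positive"
  else if (a <= 5) "strong"
  else "very strong"
  target <- if (value > 0) "against M0 (supporting M1)"
  else "for M0 (against M1)"
  if (a <= 1) sprintf("evidence %s: %s", target, grade)
  else sprintf("%s evidence %s", grade, target)
}
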