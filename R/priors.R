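#' Prior configuration for the phylogenetic model pair
#'
#' Branch lengths are i.i.d. Exponential with mean `mu` given the
#' hyperparameter `mu`, which itself carries an inverse-gamma(shape, scale)
#' hyperprior (defaults 2.1 and 1.1). All frequency/probability simplex
#' blocks carry flat Dirichlet priors, whose log density is the constant
#' `log Gamma(dimension)`. The 5 free GTR exchangeabilities carry i.i.d.
#' Exponential(1) priors.
#'
#' @param mu_shape,mu_scale inverse-gamma hyperprior on the branch-length
#'   mean `mu`.
#' @param rate_mean mean of the exponential prior on free GTR
#'   exchangeabilities.
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(mu_shape = 2.1, mu_scale = 1.1, rate_mean = 1) {
  stopifnot(mu_shape > 0, mu_scale > 0, rate_mean > 0)
  structure(list(mu_shape = mu_shape, mu_scale = mu_scale,
                 rate_mean = rate_mean),
            class = "prior_config")
}

#' Inverse-gamma log density
#'
#' `q(x) = scale^shape / Gamma(shape) * x^{-(shape + 1)} * exp(-scale / x)`.
#'
#' @param x evaluation point (> 0).
#' @param shape,scale positive parameters.
#' @return Log density (`-Inf` outside the support).
#' @export
dinvgamma_log <- function(x, shape, scale) {
  ifelse(x > 0,
         shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x,
         -Inf)
}

# flat Dirichlet log density on a d-simplex: log Gamma(d) inside the support
flat_dirichlet_log <- function(x) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-8) return(-Inf)
  lgamma(length(x))
}

#' Joint prior log density of a phylogenetic model state
#'
#' Sums the exponential branch-length terms given `mu`, the inverse-gamma
#' term for `mu`, exponential terms for the free GTR exchangeabilities, and
#' the flat Dirichlet constants for every simplex block (GTR base
#' frequencies, the 16 context psi blocks, and every root-chain
#' distribution). Both competing models' parameter blocks always carry their
#' priors, so the power-posterior kernel is proper at both endpoints of the
#' path. A state outside the support (including a context row whose
#' no-substitution completion would be negative) yields `-Inf`.
#'
#' @param state a `phylo_state` (see [phylo_pair()]).
#' @param config a [prior_config()].
#' @return Log prior density.
#' @export
prior_log_density <- function(state, config = prior_config()) {
  mu <- state$mu
  tb <- state$branch_lengths
  if (!is.finite(mu) || mu <= 0 || any(tb < 0)) return(-Inf)
  lp <- dinvgamma_log(mu, config$mu_shape, config$mu_scale)
  lp <- lp + sum(stats::dexp(tb, rate = 1 / mu, log = TRUE))
  # GTR block
  g <- state$gtr
  if (any(g$rates[1:5] < 0)) return(-Inf)
  lp <- lp + sum(stats::dexp(g$rates[1:5], rate = 1 / config$rate_mean,
                             log = TRUE))
  lp <- lp + flat_dirichlet_log(g$freqs)
  # context psi blocks: flat Dirichlet(1^12) on each context's raw simplex;
  # support additionally requires valid completions after normalization
  ctx <- state$context
  if (!is.null(ctx)) {
    if (!context_rows_valid(ctx)) return(-Inf)
    for (w in 1:4) for (y in 1:4) {
      blk <- ctx$psi[, , w, y][upper.tri(matrix(0, 4, 4)) |
                               lower.tri(matrix(0, 4, 4))]
      if (any(blk < 0)) return(-Inf)
      lp <- lp + lgamma(12)
    }
  }
  # root chain rows
  rc <- state$root_chain
  if (!is.null(rc)) {
    blocks <- root_chain_blocks(rc)
    for (b in blocks) {
      d <- flat_dirichlet_log(b)
      if (!is.finite(d)) return(-Inf)
      lp <- lp + d
    }
  }
  lp
}

# list of all simplex rows of a root chain (transition rows + initial dists)
root_chain_blocks <- function(chain) {
  if (chain$order == 0) return(list(chain$trans))
  if (chain$order == 1)
    return(c(list(chain$init), lapply(1:4, function(v) chain$trans[v, ])))
  c(list(chain$init$p1),
    lapply(1:4, function(v) chain$init$p2[v, ]),
    unlist(lapply(1:4, function(v) lapply(1:4, function(w)
      chain$trans[v, w, ])), recursive = FALSE))
}
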