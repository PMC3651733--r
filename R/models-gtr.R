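#' General time-reversible (GTR) model parameters
#'
#' The site-independent reference model: 5 free exchangeabilities (the sixth,
#' G<->T, is fixed at 1 as the scale reference) and 3 free base frequencies.
#' The implied rate matrix is rescaled so that one unit of time corresponds to
#' one expected substitution per site at stationarity.
#'
#' @param rates numeric(6), nonnegative relative exchangeabilities in the
#'   order AC, AG, AT, CG, CT, GT; `rates[6]` is the scale reference and is
#'   normalized to 1.
#' @param freqs numeric(4) base frequencies (A, C, G, T), summing to 1.
#' @return An object of class `gtr_params`.
#' @export
#' @examples
#' p <- gtr_params(rates = c(1, 2, 1, 1, 2, 1), freqs = rep(0.25, 4))
#' gtr_transition_probs(p, t = 0.1)
gtr_params <- function(rates = rep(1, 6), freqs = rep(0.25, 4)) {
  stopifnot(length(rates) == 6, length(freqs) == 4)
  if (any(rates < 0)) stop("exchangeabilities must be nonnegative")
  if (rates[6] <= 0) stop("reference exchangeability (GT) must be positive")
  if (any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8)
    stop("base frequencies must be positive and sum to 1")
  structure(list(rates = rates / rates[6], freqs = freqs / sum(freqs)),
            class = "gtr_params")
}

# unscaled symmetric exchangeability matrix
gtr_exch_matrix <- function(rates) {
  s <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  s["A", "C"] <- rates[1]; s["A", "G"] <- rates[2]; s["A", "T"] <- rates[3]
  s["C", "G"] <- rates[4]; s["C", "T"] <- rates[5]; s["G", "T"] <- rates[6]
  s + t(s)
}

#' GTR rate matrix, scaled to one expected substitution per unit time
#'
#' @param params a [gtr_params()] object.
#' @return 4x4 rate matrix with rows summing to 0.
#' @export
gtr_rate_matrix <- function(params) {
  s <- gtr_exch_matrix(params$rates)
  q <- s * rep(params$freqs, each = 4)  # q[x,z] = s[x,z] * pi_z
  diag(q) <- -rowSums(q)
  rate <- -sum(params$freqs * diag(q))
  q / rate
}

# symmetrized eigendecomposition of the scaled reversible rate matrix;
# reused across branches when pruning a whole tree
gtr_eigen <- function(params) {
  q <- gtr_rate_matrix(params)
  sp <- sqrt(params$freqs)
  b <- q * (sp %o% (1 / sp))
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, sp = sp)
}

gtr_probs_from_eigen <- function(eig, t) {
  p <- (1 / eig$sp) *
    (eig$vectors %*% (exp(t * eig$values) * t(eig$vectors))) *
    rep(eig$sp, each = 4)
  p[p < 0] <- 0
  p / rowSums(p)
}

#' GTR transition probabilities over a branch
#'
#' Matrix exponential of the scaled reversible rate matrix, computed through
#' the symmetrized eigendecomposition (exact for reversible matrices).
#'
#' @param params a [gtr_params()] object.
#' @param t branch length (>= 0), in expected substitutions per site.
#' @return 4x4 stochastic matrix `P[x, z] = P(x -> z | t)`.
#' @export
gtr_transition_probs <- function(params, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("branch length t must be a single nonnegative number")
  if (t == 0) {
    p <- diag(4); dimnames(p) <- list(BASES, BASES); return(p)
  }
  p <- gtr_probs_from_eigen(gtr_eigen(params), t)
  dimnames(p) <- list(BASES, BASES)
  p
}
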