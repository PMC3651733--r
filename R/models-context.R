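#' First-order context-dependent substitution model
#'
#' `psi[x, z, w, y]` is the probability that, in one unit of time, base `x`
#' at a site mutates to `z` given left neighbor `w` and right neighbor `y`.
#' The 16 neighbor combinations (contexts) each carry their own 12
#' off-diagonal probabilities; the diagonal is the no-substitution completion
#' `psi(x -> x | wy) = 1 - sum_{z != x} psi(x -> z | wy)`. One unit of time is
#' calibrated per context so that one change per base is expected:
#' `sum_x sum_{z != x} f[w, x, y] * psi(x -> z | wy) = 1`, where `f` is the
#' context frequency distribution. By default `f` is derived from `psi` as
#' the stationary distribution of each context's substitution chain (which is
#' invariant to the normalization scale); an explicit `f` may be supplied
#' instead.
#'
#' With `strand_symmetric = TRUE` complementary events are constrained equal,
#' `psi(x -> z | wy) = psi(x^c -> z^c | y^c w^c)` (complemented bases,
#' neighbor order reversed), halving the free parameter count from 192 to 96.
#'
#' @param psi 4x4x4x4 array indexed `[x, z, w, y]` of nonnegative raw
#'   substitution weights; diagonal (`z == x`) entries are ignored on input
#'   and recomputed. Defaults to equal weights.
#' @param f optional 4x4x4 array `[w, x, y]`: frequency of base `x` in
#'   context `(w, y)`, each context slice a point on the 4-simplex. If `NULL`
#'   (default), derived from `psi` per context.
#' @param strand_symmetric logical; enforce complementary-strand symmetry by
#'   averaging each orbit pair.
#' @param normalize logical; rescale to the one-change-per-unit-time
#'   calibration (default `TRUE`).
#' @return An object of class `context_model`.
#' @export
#' @examples
#' m <- context_model_params()           # Jukes-Cantor-like: all psi equal 1/3
#' psi_lookup(m, "A", "C", "G", "T")
context_model_params <- function(psi = NULL, f = NULL,
                                 strand_symmetric = FALSE, normalize = TRUE) {
  if (is.null(psi)) psi <- array(1, dim = c(4, 4, 4, 4))
  stopifnot(identical(dim(psi), rep(4L, 4)) || identical(dim(psi), rep(4, 4)))
  if (any(psi[offdiag_mask()] < 0)) stop("raw psi values must be nonnegative")
  for (x in 1:4) psi[x, x, , ] <- 0
  if (strand_symmetric) psi <- symmetrize_psi(psi)
  f_given <- !is.null(f)
  if (f_given) {
    stopifnot(identical(dim(f), c(4L, 4L, 4L)) || identical(dim(f), rep(4, 3)))
    for (w in 1:4) for (y in 1:4) {
      s <- sum(f[w, , y])
      if (abs(s - 1) > 1e-8) stop("each f[w, , y] must sum to 1")
      f[w, , y] <- f[w, , y] / s
    }
  } else {
    f <- derive_context_freqs(psi)
  }
  obj <- structure(list(psi = psi, f = f, f_derived = !f_given,
                        strand_symmetric = strand_symmetric),
                   class = "context_model")
  if (normalize) obj <- normalize_context_model(obj)
  else obj$psi <- fill_completion(obj$psi)
  obj
}

offdiag_mask <- function() {
  m <- array(TRUE, dim = rep(4, 4))
  for (x in 1:4) m[x, x, , ] <- FALSE
  m
}

# orbit map of strand symmetry: (x,z,w,y) -> (xc, zc, yc, wc)
symmetrize_psi <- function(psi) {
  out <- psi
  cc <- COMPLEMENT_IDX
  for (x in 1:4) for (z in 1:4) for (w in 1:4) for (y in 1:4)
    out[x, z, w, y] <- (psi[x, z, w, y] + psi[cc[x], cc[z], cc[y], cc[w]]) / 2
  out
}

# stationary distribution of the per-context substitution chain; invariant to
# scaling of psi's off-diagonal entries.
derive_context_freqs <- function(psi) {
  f <- array(NA_real_, dim = c(4, 4, 4))
  for (w in 1:4) for (y in 1:4) {
    a <- psi[, , w, y]             # off-diagonal weights
    diag(a) <- 0
    diag(a) <- -rowSums(a)
    if (all(abs(a) < 1e-300))
      stop("context with zero total substitution mass cannot be normalized")
    m <- cbind(a, 1)               # solve pi A = 0, sum(pi) = 1
    sol <- tryCatch(qr.solve(t(m), c(rep(0, 4), 1)),
                    error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)) || any(sol < -1e-9))
      stop("context chain has no unique stationary distribution")
    sol[sol < 0] <- 0
    f[w, , y] <- sol / sum(sol)
  }
  f
}

fill_completion <- function(psi) {
  for (x in 1:4) psi[x, x, , ] <- 0
  for (x in 1:4) for (w in 1:4) for (y in 1:4)
    psi[x, x, w, y] <- 1 - sum(psi[x, , w, y])
  psi
}

#' Normalize a context model to one expected change per unit time
#'
#' Rescales each context's substitution probabilities so that
#' `sum_x sum_{z != x} f[w, x, y] * psi(x -> z | wy) = 1`. Idempotent, and
#' preserves ratios of probabilities within a context.
#'
#' @param params a `context_model`.
#' @return The rescaled `context_model` (diagonal completion refreshed).
#' @export
normalize_context_model <- function(params) {
  stopifnot(inherits(params, "context_model"))
  psi <- params$psi
  for (x in 1:4) psi[x, x, , ] <- 0
  for (w in 1:4) for (y in 1:4) {
    s <- sum(params$f[w, , y] * rowSums(psi[, , w, y]))
    if (s <= 0)
      stop("context with zero total substitution mass cannot be normalized")
    psi[, , w, y] <- psi[, , w, y] / s
  }
  params$psi <- fill_completion(psi)
  params
}

#' Look up a context-dependent substitution probability
#'
#' Returns `psi(x -> z | wy)` per unit time. For `z == x` the no-substitution
#' completion is returned. If any of the four bases is a gap (`"-"`, `NA`,
#' or `"N"`), the factor is 1 by the model's gap rule.
#'
#' @param params a `context_model`.
#' @param x,z,w,y single bases (`"A"/"C"/"G"/"T"`), gaps (`"-"`, `"N"`), or
#'   integer codes 1..4 / `NA`.
#' @return A probability.
#' @export
psi_lookup <- function(params, x, z, w, y) {
  idx <- lapply(list(x, z, w, y), function(b) {
    if (is.character(b)) encode_bases(b)[1] else as.integer(b)
  })
  if (any(vapply(idx, is.na, logical(1)))) return(1)
  params$psi[idx[[1]], idx[[2]], idx[[3]], idx[[4]]]
}

# TRUE when every no-substitution completion is a valid probability
context_rows_valid <- function(params) {
  all(apply(params$psi, c(3, 4), function(m) all(diag(m) >= 0)))
}

#' Count free continuous parameters of a substitution model
#'
#' Counts exclude branch lengths and the ancestral root chain.
#'
#' @param model `"context"` (first-order context-dependent),
#'   `"gtr"`, or `"single_context"` (a site-independent unrestricted
#'   substitution block, i.e. one context).
#' @param strand_symmetric logical; halves the context-model count.
#' @return Integer count: 192 for the unconstrained first-order context
#'   model, 96 under strand symmetry, 12 for a single context, 8 for GTR
#'   (5 exchangeabilities + 3 frequencies).
#' @export
count_free_parameters <- function(model = c("context", "gtr", "single_context"),
                                  strand_symmetric = FALSE) {
  model <- match.arg(model)
  switch(model,
    context = if (strand_symmetric) 96L else 192L,
    gtr = 8L,
    single_context = 12L)
}

#' Per-branch context-dependent transition probabilities
#'
#' `psi` is calibrated per unit time; over a branch of length `t` the
#' substitution probability is `t * psi(x -> z | wy)`, with each row
#' truncated (rescaled) if needed so the no-substitution completion stays a
#' valid probability. Neighbors are those of the parent sequence and are held
#' fixed across the branch.
#'
#' @param params a normalized `context_model`.
#' @param t branch length (>= 0).
#' @param max_row_prob cap on a row's total substitution probability.
#' @return 4x4x4x4 array `[x, z, w, y]` of per-branch probabilities,
#'   including the diagonal completion.
#' @export
context_branch_probs <- function(params, t, max_row_prob = 1 - 1e-8) {
  stopifnot(inherits(params, "context_model"), t >= 0)
  p <- params$psi * t
  for (x in 1:4) p[x, x, , ] <- 0
  rs <- apply(p, c(1, 3, 4), sum)                   # [x, w, y] row sums
  sc <- ifelse(rs > max_row_prob, max_row_prob / rs, 1)
  p <- p * aperm(array(sc, c(4, 4, 4, 4)), c(1, 4, 2, 3))
  comp <- 1 - pmin(rs, max_row_prob)
  for (x in 1:4) p[x, x, , ] <- comp[x, , ]
  p
}
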