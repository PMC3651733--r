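#' Likelihood evaluation
#'
#' GTR likelihoods are computed by Felsenstein pruning (internal states
#' marginalized; a gap at a tip is missing data). The context-dependent
#' likelihood is evaluated against explicit augmented ancestral sequences:
#' it is the root-chain probability of the root sequence plus, over every
#' branch and site, the log per-branch substitution probability
#' `P(parent -> child | parent's neighbors)`, neighbors held fixed at the
#' parent across the branch. Any factor involving a gap (including the
#' missing neighbor at the two sequence boundaries) contributes 0 on the log
#' scale.
#'
#' @name likelihood
NULL

# postorder edge table and bookkeeping for a rooted ape::phylo tree
tree_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  list(tree = tr, n_tip = n_tip, n_node = tr$Nnode,
       root = n_tip + 1L,
       parent = tr$edge[, 1], child = tr$edge[, 2],
       lengths = tr$edge.length, labels = tr$tip.label)
}

align_to_tree <- function(alignment, ti) {
  a <- if (is.character(alignment)) encode_bases(alignment) else alignment
  if (is.null(rownames(a)))
    stop("alignment must have row names matching the tree's tip labels")
  missing <- setdiff(ti$labels, rownames(a))
  if (length(missing))
    stop("alignment is missing tips: ", paste(missing, collapse = ", "))
  a[ti$labels, , drop = FALSE]
}

#' GTR log likelihood of an alignment on a fixed rooted tree
#'
#' Felsenstein pruning; tip gaps are missing data (partial vectors of ones).
#'
#' @param alignment character or integer matrix, rows named by tip label.
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param params a [gtr_params()] object.
#' @return Log likelihood summed over sites.
#' @export
gtr_tree_loglik <- function(alignment, tree, params) {
  ti <- tree_index(tree)
  tips <- align_to_tree(alignment, ti)
  gtr_loglik_idx(tips, ti, params)
}

gtr_loglik_idx <- function(tips, ti, params) {
  n_sites <- ncol(tips)
  if (n_sites == 0) stop("zero-length alignment")
  n_all <- ti$n_tip + ti$n_node
  partials <- vector("list", n_all)
  for (i in seq_len(ti$n_tip)) {
    m <- matrix(0, 4, n_sites)
    b <- tips[i, ]
    obs <- !is.na(b)
    m[cbind(b[obs], which(obs))] <- 1
    m[, !obs] <- 1
    partials[[i]] <- m
  }
  eig <- gtr_eigen(params)
  for (e in seq_along(ti$parent)) {
    p <- ti$parent[e]; ch <- ti$child[e]
    P <- gtr_probs_from_eigen(eig, ti$lengths[e])
    contrib <- P %*% partials[[ch]]
    if (is.null(partials[[p]])) partials[[p]] <- contrib
    else partials[[p]] <- partials[[p]] * contrib
  }
  sum(log(colSums(params$freqs * partials[[ti$root]])))
}

# per-edge context log factors, vectorized over sites. parent/child are
# integer vectors; logp is log(context_branch_probs(...)) as a flat array.
ctx_edge_site_logp <- function(parent, child, logp) {
  L <- length(parent)
  w <- c(NA_integer_, parent[-L])
  y <- c(parent[-1], NA_integer_)
  ok <- !(is.na(parent) | is.na(child) | is.na(w) | is.na(y))
  out <- numeric(L)
  idx <- parent[ok] + 4L * (child[ok] - 1L) + 16L * (w[ok] - 1L) +
    64L * (y[ok] - 1L)
  out[ok] <- logp[idx]
  out
}

#' Context-dependent log likelihood with augmented ancestral sequences
#'
#' @param alignment tip sequences (character or integer matrix, rows named
#'   by tip label).
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param params a normalized `context_model`.
#' @param chain a [root_markov_chain()] for the root sequence.
#' @param aug integer or character matrix of ancestral sequences, one row per
#'   internal node in ape node order (row 1 = root, i.e. node `n_tip + 1`).
#' @return Log likelihood (root chain + all branch factors).
#' @export
context_loglik <- function(alignment, tree, params, chain, aug) {
  ti <- tree_index(tree)
  tips <- align_to_tree(alignment, ti)
  if (is.character(aug)) aug <- encode_bases(aug)
  if (nrow(aug) != ti$n_node || ncol(aug) != ncol(tips))
    stop("aug must cover every internal node with alignment-length rows")
  logp_edges <- lapply(ti$lengths, function(t)
    log(context_branch_probs(params, t)))
  context_loglik_idx(tips, aug, ti, chain, logp_edges)
}

node_seq <- function(tips, aug, ti, node) {
  if (node <= ti$n_tip) tips[node, ] else aug[node - ti$n_tip, ]
}

context_loglik_idx <- function(tips, aug, ti, chain, logp_edges) {
  ll <- sum(root_site_log_probs(chain, aug[1, ], seq_len(ncol(aug)),
                                aug[1, ]))
  for (e in seq_along(ti$parent)) {
    ll <- ll + sum(ctx_edge_site_logp(
      node_seq(tips, aug, ti, ti$parent[e]),
      node_seq(tips, aug, ti, ti$child[e]),
      logp_edges[[e]]))
  }
  ll
}

#' Potential U and the power-posterior kernel
#'
#' `compute_U` evaluates
#' `U = log f(y | theta, M1) + log Pi(theta | M1) - log f(y | theta, M0) - log Pi(theta | M0)`,
#' the log ratio of the two competing models' unnormalized posterior kernels
#' at the current state. `power_log_kernel` evaluates the geometric bridge
#' `(1 - beta) * [loglik_0 + logprior_0] + beta * [loglik_1 + logprior_1]`,
#' which interpolates between the two posteriors as `beta` runs from 0 to 1.
#'
#' @param pair a model pair (see [toy_pair()] / [phylo_pair()]) holding both
#'   models and the shared data.
#' @param state a parameter state valid for the pair.
#' @param beta inverse temperature in `[0, 1]`.
#' @return A single numeric value.
#' @export
compute_U <- function(pair, state) {
  pair_log_kernel(pair, state, 1L) - pair_log_kernel(pair, state, 0L)
}

#' @rdname compute_U
#' @export
power_log_kernel <- function(pair, state, beta) {
  if (!is.numeric(beta) || beta < 0 || beta > 1)
    stop("beta must lie in [0, 1]")
  (1 - beta) * pair_log_kernel(pair, state, 0L) +
    beta * pair_log_kernel(pair, state, 1L)
}
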