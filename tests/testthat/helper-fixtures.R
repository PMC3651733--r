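# shared fixtures and independent oracles, built in code at test time

TREE5 <- "(((cow:0.1,sheep:0.1):0.1,pig:0.1):0.1,(horse:0.1,donkey:0.1):0.1);"
TREE3 <- "((A:0.2,B:0.3):0.1,C:0.4);"

tree5 <- function() ape::read.tree(text = TREE5)
tree3 <- function() ape::read.tree(text = TREE3)

random_gtr <- function(seed = 1) {
  set.seed(seed)
  f <- rgamma(4, 2); f <- f / sum(f)
  gtr_params(rates = c(rexp(5) + 0.2, 1), freqs = f)
}

# exhaustive-enumeration GTR likelihood: sums over all internal-node state
# assignments, site by site; independent of the pruning implementation
brute_gtr_loglik <- function(alignment, tree, params) {
  ti <- pathstone:::tree_index(tree)
  tips <- pathstone:::align_to_tree(alignment, ti)
  Plist <- lapply(ti$lengths, function(t) gtr_transition_probs(params, t))
  n_int <- ti$n_node
  grids <- do.call(expand.grid, rep(list(1:4), n_int))
  total <- 0
  for (s in seq_len(ncol(tips))) {
    site_p <- 0
    for (g in seq_len(nrow(grids))) {
      states <- c(tips[, s], unlist(grids[g, ]))
      pr <- params$freqs[states[ti$root]]
      if (is.na(pr)) pr <- 1  # root gap impossible here; guard anyway
      for (e in seq_along(ti$parent)) {
        a <- states[ti$parent[e]]; b <- states[ti$child[e]]
        pr <- pr * if (is.na(b)) 1 else Plist[[e]][a, b]
      }
      site_p <- site_p + pr
    }
    total <- total + log(site_p)
  }
  total
}

# independent context-model likelihood: explicit loops over branches/sites
# through psi_lookup and scalar root-chain factors
brute_context_loglik <- function(alignment, tree, params, chain, aug) {
  ti <- pathstone:::tree_index(tree)
  tips <- pathstone:::align_to_tree(alignment, ti)
  if (is.character(aug)) aug <- pathstone:::encode_bases(aug)
  L <- ncol(tips)
  get_seq <- function(node)
    if (node <= ti$n_tip) tips[node, ] else aug[node - ti$n_tip, ]
  total <- root_log_prob(chain, aug[1, ])
  for (e in seq_along(ti$parent)) {
    par <- get_seq(ti$parent[e]); ch <- get_seq(ti$child[e])
    P <- context_branch_probs(params, ti$lengths[e])
    for (i in seq_len(L)) {
      w <- if (i > 1) par[i - 1] else NA
      y <- if (i < L) par[i + 1] else NA
      if (any(is.na(c(par[i], ch[i], w, y)))) next
      total <- total + log(P[par[i], ch[i], w, y])
    }
  }
  total
}

# analytic power posterior of the Beta(a0,b0)-vs-Beta(a1,b1) beta-binomial
# model-switch path: a Beta distribution in the success probability
bb_power_posterior <- function(n, k, a0, b0, a1, b1, beta) {
  c(shape1 = k + 1 + (1 - beta) * (a0 - 1) + beta * (a1 - 1),
    shape2 = n - k + 1 + (1 - beta) * (b0 - 1) + beta * (b1 - 1))
}

default_bb_pair <- function() {
  toy_pair(beta_binomial_spec(20, 14, 1, 1), beta_binomial_spec(20, 14, 2, 2))
}

# fast vectorized normal log likelihood over many theta values
normal_ll_vec <- function(y, theta, sigma) {
  n <- length(y)
  -n / 2 * log(2 * pi * sigma^2) -
    (sum(y^2) - 2 * theta * sum(y) + n * theta^2) / (2 * sigma^2)
}
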