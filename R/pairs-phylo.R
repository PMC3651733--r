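#' Phylogenetic model pair: GTR versus the context-dependent model
#'
#' Builds the model-switch pair between the site-independent GTR model
#' (model 0) and the first-order context-dependent model with an ancestral
#' root Markov chain (model 1) on a fixed rooted tree. The two models'
#' substitution parameter blocks are disjoint; branch lengths and the
#' branch-length hyperparameter `mu` are shared, and every block carries its
#' prior under both power-posterior endpoint kernels so both endpoints are
#' proper. The context model's likelihood is evaluated against augmented
#' ancestral sequences; under the GTR kernel the augmented sequences carry a
#' uniform reference distribution (1/4 per non-gap site), which leaves the
#' Bayes factor between the two models unchanged.
#'
#' Ancestral-node gap pattern is fixed by the data: a site is a gap at an
#' internal node exactly when it is a gap in all descendant tips. Gap sites
#' are never resampled and contribute factor 1 throughout.
#'
#' @param alignment character or integer matrix of tip sequences, rows named
#'   by tip label (gaps `-`, `N` treated as gap).
#' @param tree rooted `ape::phylo`; missing branch lengths are initialized
#'   at the prior mean of `mu` (1.0).
#' @param root_order order (0, 1, 2) of the ancestral root Markov chain.
#' @param strand_symmetric constrain complementary substitution events equal
#'   (96 instead of 192 free context parameters).
#' @param priors a [prior_config()].
#' @param proposal named list of proposal scales: `rate_sd`, `bl_sd`,
#'   `mu_sd` (log-scale random-walk standard deviations), `freq_conc`,
#'   `psi_conc`, `root_conc` (Dirichlet perturbation concentrations).
#' @return Object of class `phylo_pair` (a `bf_pair`).
#' @export
phylo_pair <- function(alignment, tree, root_order = 0,
                       strand_symmetric = TRUE, priors = prior_config(),
                       proposal = list()) {
  ti <- tree_index(tree)
  tips <- align_to_tree(alignment, ti)
  n_int <- ti$n_node
  L <- ncol(tips)
  prop <- utils::modifyList(
    list(rate_sd = 0.3, bl_sd = 0.3, mu_sd = 0.5,
         freq_conc = 300, psi_conc = 300, root_conc = 300), proposal)
  # gap at an internal node iff all descendant tips are gaps (postorder AND)
  allgap <- matrix(FALSE, ti$n_tip + n_int, L)
  for (i in seq_len(ti$n_tip)) allgap[i, ] <- is.na(tips[i, ])
  seen <- logical(ti$n_tip + n_int)
  for (e in seq_along(ti$parent)) {
    p <- ti$parent[e]; ch <- ti$child[e]
    if (!seen[p]) { allgap[p, ] <- allgap[ch, ]; seen[p] <- TRUE }
    else allgap[p, ] <- allgap[p, ] & allgap[ch, ]
  }
  aug_gap <- allgap[ti$n_tip + seq_len(n_int), , drop = FALSE]
  # edges incident to each internal node
  node_in_edge <- rep(NA_integer_, ti$n_tip + n_int)
  node_out_edges <- vector("list", ti$n_tip + n_int)
  for (e in seq_along(ti$parent)) {
    node_in_edge[ti$child[e]] <- e
    node_out_edges[[ti$parent[e]]] <- c(node_out_edges[[ti$parent[e]]], e)
  }
  # flat Dirichlet constants for every simplex block (identical under both
  # kernels, so they cancel in U but keep each kernel a proper density)
  rc0 <- root_markov_chain(root_order)
  lp_dir_const <- lgamma(4) + 16 * lgamma(12) +
    sum(vapply(root_chain_blocks(rc0), function(b) lgamma(length(b)),
               numeric(1)))
  structure(list(ti = ti, tips = tips, L = L, n_int = n_int,
                 root_order = root_order,
                 strand_symmetric = strand_symmetric,
                 priors = priors, prop = prop, aug_gap = aug_gap,
                 aug_unif_mass = log(0.25) * sum(!aug_gap),
                 lp_dir_const = lp_dir_const,
                 node_in_edge = node_in_edge,
                 node_out_edges = node_out_edges,
                 prior_tags = c("gtr-block", "context-block")),
            class = c("phylo_pair", "bf_pair"))
}

#' @export
pair_init_state.phylo_pair <- function(pair) {
  ti <- pair$ti
  st <- new.env(parent = emptyenv())
  st$gtr <- gtr_params()
  st$context <- context_model_params(strand_symmetric = pair$strand_symmetric)
  st$root_chain <- root_markov_chain(pair$root_order)
  st$branch_lengths <- ti$lengths
  st$mu <- 1
  # majority-base initialization of ancestral sequences (postorder votes)
  votes <- array(0L, dim = c(ti$n_tip + pair$n_int, 4, pair$L))
  for (i in seq_len(ti$n_tip)) {
    b <- pair$tips[i, ]; obs <- which(!is.na(b))
    votes[cbind(i, b[obs], obs)] <- 1L
  }
  for (e in seq_along(ti$parent))
    votes[ti$parent[e], , ] <- votes[ti$parent[e], , ] + votes[ti$child[e], , ]
  aug <- matrix(NA_integer_, pair$n_int, pair$L)
  for (v in seq_len(pair$n_int)) {
    m <- votes[ti$n_tip + v, , ]
    aug[v, ] <- max.col(t(m), ties.method = "first")
  }
  aug[pair$aug_gap] <- NA_integer_
  st$aug <- aug
  class(st) <- c("phylo_state", "environment")
  refresh_phylo_caches(pair, st)
  st
}

refresh_phylo_caches <- function(pair, st) {
  ti <- pair$ti
  st$gtr_ll <- gtr_loglik_idx(pair$tips, ti_with_lengths(ti, st$branch_lengths),
                              st$gtr)
  st$logp_edges <- lapply(st$branch_lengths, function(t)
    log(context_branch_probs(st$context, t)))
  st$ctx_edge_ll <- vapply(seq_along(ti$parent), function(e)
    ctx_edge_ll_one(pair, st, e), numeric(1))
  st$root_ll <- sum(root_site_log_probs(st$root_chain, st$aug[1, ],
                                        seq_len(pair$L), st$aug[1, ]))
  st$lp_mu <- dinvgamma_log(st$mu, pair$priors$mu_shape, pair$priors$mu_scale)
  st$lp_branch <- sum(stats::dexp(st$branch_lengths, 1 / st$mu, log = TRUE))
  st$lp_rates <- sum(stats::dexp(st$gtr$rates[1:5],
                                 1 / pair$priors$rate_mean, log = TRUE))
  invisible(st)
}

ti_with_lengths <- function(ti, lengths) { ti$lengths <- lengths; ti }

phylo_node_seq <- function(pair, st, node) {
  if (node <= pair$ti$n_tip) pair$tips[node, ]
  else st$aug[node - pair$ti$n_tip, ]
}

ctx_edge_ll_one <- function(pair, st, e) {
  ti <- pair$ti
  sum(ctx_edge_site_logp(phylo_node_seq(pair, st, ti$parent[e]),
                         phylo_node_seq(pair, st, ti$child[e]),
                         st$logp_edges[[e]]))
}

#' @export
pair_log_lik.phylo_pair <- function(pair, state, model) {
  if (model == 0) state$gtr_ll + pair$aug_unif_mass
  else state$root_ll + sum(state$ctx_edge_ll)
}

#' @export
pair_log_kernel.phylo_pair <- function(pair, state, model) {
  pair_log_lik(pair, state, model) + state$lp_mu + state$lp_branch +
    state$lp_rates + pair$lp_dir_const
}

# Dirichlet perturbation proposal with a small concentration floor; returns
# the proposal and its Hastings log ratio
propose_simplex <- function(x, conc) {
  a_fwd <- conc * x + 0.1
  xp <- rdirichlet1(a_fwd)
  if (any(xp <= 0)) return(NULL)
  a_rev <- conc * xp + 0.1
  list(x = xp,
       hastings = ddirichlet_log(x, a_rev) - ddirichlet_log(xp, a_fwd))
}

mh_accept <- function(log_ratio) {
  is.finite(log_ratio) && log(stats::runif(1)) < log_ratio
}

# contexts to propose on: all 16 unconstrained, or one representative per
# complementary-strand orbit (w,y) ~ (y^c, w^c); 4 contexts are self-paired
context_update_set <- function(strand_symmetric) {
  ids <- expand.grid(w = 1:4, y = 1:4)
  keep <- rep(TRUE, nrow(ids))
  if (strand_symmetric) {
    cc <- COMPLEMENT_IDX
    for (i in seq_len(nrow(ids))) {
      pw <- cc[ids$y[i]]; py <- cc[ids$w[i]]
      if (pw < ids$w[i] || (pw == ids$w[i] && py < ids$y[i]))
        keep[i] <- FALSE
    }
  }
  lapply(which(keep), function(i) c(ids$w[i], ids$y[i]))
}

# propose a new raw simplex block for one context (and its strand-symmetric
# partner). Self-paired contexts are proposed on the 6-dimensional reduced
# simplex of entry-pair sums so the internal (x,z) ~ (x^c,z^c) tie is exact.
# Returns NULL (reject early), or list(ctx = updated model, hastings = ...).
propose_context_block <- function(ctx, ctx_id, conc, strand_symmetric) {
  w <- ctx_id[1]; y <- ctx_id[2]
  cc <- COMPLEMENT_IDX
  od <- !diag(4)
  slab <- ctx$psi[, , w, y]; slab[!od] <- 0
  raw <- slab[od] / sum(slab[od])
  self_paired <- strand_symmetric && w == cc[y] && y == cc[w]
  if (self_paired) {
    # representative entries: (x, z) with x < x^c (i.e. x in {A, C})
    rs <- matrix(0, 4, 4); rs[od] <- raw
    reps <- which(outer(1:4, 1:4, function(x, z) x != z & x < cc[x]))
    u <- 2 * rs[reps]
    pr <- propose_simplex(u, conc)
    if (is.null(pr)) return(NULL)
    rs_new <- matrix(0, 4, 4)
    rs_new[reps] <- pr$x / 2
    rs_new <- rs_new + rs_new[cc, cc]      # mirror partners inside the block
    new_raw <- rs_new
  } else {
    pr <- propose_simplex(raw, conc)
    if (is.null(pr)) return(NULL)
    new_raw <- matrix(0, 4, 4); new_raw[od] <- pr$x
  }
  ctx$psi[, , w, y] <- new_raw
  if (strand_symmetric && !self_paired)
    ctx$psi[, , cc[y], cc[w]] <- new_raw[cc, cc]
  out <- tryCatch({
    if (ctx$f_derived) ctx$f <- derive_context_freqs(ctx$psi)
    normalize_context_model(ctx)
  }, error = function(e) NULL)
  if (is.null(out) || !context_rows_valid(out)) return(NULL)
  list(ctx = out, hastings = pr$hastings)
}

#' @export
update_cycle.phylo_pair <- function(pair, state, beta) {
  st <- state
  ti <- pair$ti
  prop <- pair$prop
  n_edge <- length(ti$parent)

  # --- GTR exchangeabilities (5 free; GT fixed at 1) ------------------
  for (r in 1:5) {
    rates_p <- st$gtr$rates
    mult <- exp(stats::rnorm(1, 0, prop$rate_sd))
    rates_p[r] <- rates_p[r] * mult
    gtr_p <- st$gtr; gtr_p$rates <- rates_p
    ll_p <- gtr_loglik_idx(pair$tips, ti_with_lengths(ti, st$branch_lengths),
                           gtr_p)
    lp_rates_p <- sum(stats::dexp(rates_p[1:5], 1 / pair$priors$rate_mean,
                                  log = TRUE))
    if (mh_accept((1 - beta) * (ll_p - st$gtr_ll) +
                  (lp_rates_p - st$lp_rates) + log(mult))) {
      st$gtr <- gtr_p; st$gtr_ll <- ll_p; st$lp_rates <- lp_rates_p
    }
  }

  # --- GTR base frequencies -------------------------------------------
  pr <- propose_simplex(st$gtr$freqs, prop$freq_conc)
  if (!is.null(pr)) {
    gtr_p <- st$gtr; gtr_p$freqs <- pr$x
    ll_p <- gtr_loglik_idx(pair$tips, ti_with_lengths(ti, st$branch_lengths),
                           gtr_p)
    if (mh_accept((1 - beta) * (ll_p - st$gtr_ll) + pr$hastings)) {
      st$gtr <- gtr_p; st$gtr_ll <- ll_p
    }
  }

  # --- context psi blocks (one Dirichlet proposal per context orbit) ---
  for (ctx_id in context_update_set(pair$strand_symmetric)) {
    pr <- propose_context_block(st$context, ctx_id, prop$psi_conc,
                                pair$strand_symmetric)
    if (is.null(pr)) next
    ctx_p <- pr$ctx
    logp_p <- lapply(st$branch_lengths, function(t)
      log(context_branch_probs(ctx_p, t)))
    ll_p <- vapply(seq_len(n_edge), function(e) {
      sum(ctx_edge_site_logp(phylo_node_seq(pair, st, ti$parent[e]),
                             phylo_node_seq(pair, st, ti$child[e]),
                             logp_p[[e]]))
    }, numeric(1))
    if (mh_accept(beta * (sum(ll_p) - sum(st$ctx_edge_ll)) + pr$hastings)) {
      st$context <- ctx_p; st$logp_edges <- logp_p; st$ctx_edge_ll <- ll_p
    }
  }

  # --- root chain rows -------------------------------------------------
  st_root_update(pair, st, beta)

  # --- branch lengths --------------------------------------------------
  for (e in seq_len(n_edge)) {
    mult <- exp(stats::rnorm(1, 0, prop$bl_sd))
    t_p <- st$branch_lengths[e] * mult
    bl_p <- st$branch_lengths; bl_p[e] <- t_p
    gtr_ll_p <- gtr_loglik_idx(pair$tips, ti_with_lengths(ti, bl_p), st$gtr)
    logp_e_p <- log(context_branch_probs(st$context, t_p))
    ctx_ll_e_p <- sum(ctx_edge_site_logp(
      phylo_node_seq(pair, st, ti$parent[e]),
      phylo_node_seq(pair, st, ti$child[e]), logp_e_p))
    lp_branch_p <- st$lp_branch -
      stats::dexp(st$branch_lengths[e], 1 / st$mu, log = TRUE) +
      stats::dexp(t_p, 1 / st$mu, log = TRUE)
    if (mh_accept((1 - beta) * (gtr_ll_p - st$gtr_ll) +
                  beta * (ctx_ll_e_p - st$ctx_edge_ll[e]) +
                  (lp_branch_p - st$lp_branch) + log(mult))) {
      st$branch_lengths <- bl_p; st$gtr_ll <- gtr_ll_p
      st$logp_edges[[e]] <- logp_e_p; st$ctx_edge_ll[e] <- ctx_ll_e_p
      st$lp_branch <- lp_branch_p
    }
  }

  # --- branch-length hyperparameter mu ---------------------------------
  mult <- exp(stats::rnorm(1, 0, prop$mu_sd))
  mu_p <- st$mu * mult
  lp_mu_p <- dinvgamma_log(mu_p, pair$priors$mu_shape, pair$priors$mu_scale)
  lp_branch_p <- sum(stats::dexp(st$branch_lengths, 1 / mu_p, log = TRUE))
  if (mh_accept((lp_mu_p - st$lp_mu) + (lp_branch_p - st$lp_branch) +
                log(mult))) {
    st$mu <- mu_p; st$lp_mu <- lp_mu_p; st$lp_branch <- lp_branch_p
  }

  # --- augmented ancestral sequences (every non-gap site) --------------
  for (v in seq_len(pair$n_int)) st_aug_update(pair, st, v, beta)
  st
}

st_root_update <- function(pair, st, beta) {
  conc <- pair$prop$root_conc
  propose_row <- function(getter, setter) {
    cur <- getter(st$root_chain)
    pr <- propose_simplex(cur, conc)
    if (is.null(pr)) return()
    chain_p <- setter(st$root_chain, pr$x)
    root_ll_p <- sum(root_site_log_probs(chain_p, st$aug[1, ],
                                         seq_len(pair$L), st$aug[1, ]))
    if (mh_accept(beta * (root_ll_p - st$root_ll) + pr$hastings)) {
      st$root_chain <- chain_p; st$root_ll <- root_ll_p
    }
  }
  ord <- st$root_chain$order
  if (ord == 0) {
    propose_row(function(c) c$trans,
                function(c, x) { c$trans <- x; c })
  } else if (ord == 1) {
    propose_row(function(c) c$init, function(c, x) { c$init <- x; c })
    for (v in 1:4)
      propose_row(function(c) c$trans[v, ],
                  function(c, x) { c$trans[v, ] <- x; c })
  } else {
    propose_row(function(c) c$init$p1,
                function(c, x) { c$init$p1 <- x; c })
    for (v in 1:4)
      propose_row(function(c) c$init$p2[v, ],
                  function(c, x) { c$init$p2[v, ] <- x; c })
    for (v in 1:4) for (w in 1:4)
      propose_row(function(c) c$trans[v, w, ],
                  function(c, x) { c$trans[v, w, ] <- x; c })
  }
}

safe_at <- function(s, idx) {
  out <- rep(NA_integer_, length(idx))
  ok <- idx >= 1 & idx <= length(s)
  out[ok] <- s[idx[ok]]
  out
}

edge_factor_vec <- function(logp, x, z, w, y) {
  out <- numeric(length(x))
  ok <- !(is.na(x) | is.na(z) | is.na(w) | is.na(y))
  out[ok] <- logp[x[ok] + 4L * (z[ok] - 1L) + 16L * (w[ok] - 1L) +
                  64L * (y[ok] - 1L)]
  out
}

# local context/root log factors touched by the bases `cand` at `sites` of
# internal node v; other sequence positions read from the current state.
aug_local_logp <- function(pair, st, v, sites, cand) {
  ti <- pair$ti
  node <- ti$n_tip + v
  seqv <- st$aug[v, ]
  seqv_cand <- seqv; seqv_cand[sites] <- cand
  total <- numeric(length(sites))
  e_in <- pair$node_in_edge[node]
  if (!is.na(e_in)) {
    par <- phylo_node_seq(pair, st, ti$parent[e_in])
    total <- total + edge_factor_vec(st$logp_edges[[e_in]],
                                     safe_at(par, sites), cand,
                                     safe_at(par, sites - 1L),
                                     safe_at(par, sites + 1L))
  }
  for (e in pair$node_out_edges[[node]]) {
    ch <- phylo_node_seq(pair, st, ti$child[e])
    lp <- st$logp_edges[[e]]
    for (off in -1L:1L) {
      j <- sites + off
      total <- total + edge_factor_vec(lp,
                                       safe_at(seqv_cand, j),
                                       safe_at(ch, j),
                                       safe_at(seqv_cand, j - 1L),
                                       safe_at(seqv_cand, j + 1L))
    }
  }
  if (v == 1L) {  # root node: chain terms whose window includes the site
    for (off in 0L:st$root_chain$order) {
      j <- sites + off
      ok <- j <= pair$L
      if (any(ok))
        total[ok] <- total[ok] +
          root_site_log_probs(st$root_chain, seqv_cand, j[ok],
                              seqv_cand[j[ok]])
    }
  }
  total
}

st_aug_update <- function(pair, st, v, beta) {
  ti <- pair$ti
  node <- ti$n_tip + v
  nongap <- which(!pair$aug_gap[v, ])
  if (!length(nongap)) return()
  for (m in 0:2) {
    sites <- nongap[nongap %% 3L == m]
    if (!length(sites)) next
    cur <- st$aug[v, sites]
    cand <- sample.int(4L, length(sites), replace = TRUE)
    delta <- aug_local_logp(pair, st, v, sites, cand) -
      aug_local_logp(pair, st, v, sites, cur)
    acc <- log(stats::runif(length(sites))) < beta * delta
    if (any(acc)) st$aug[v, sites[acc]] <- cand[acc]
  }
  # refresh cached sums for the edges incident to this node
  for (e in c(pair$node_in_edge[node], pair$node_out_edges[[node]])) {
    if (!is.na(e)) st$ctx_edge_ll[e] <- ctx_edge_ll_one(pair, st, e)
  }
  if (v == 1L)
    st$root_ll <- sum(root_site_log_probs(st$root_chain, st$aug[1, ],
                                          seq_len(pair$L), st$aug[1, ]))
  invisible(st)
}
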