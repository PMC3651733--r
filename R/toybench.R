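#' Closed-form marginal likelihoods for the conjugate toys
#'
#' Beta-binomial: `log C(n, k) + log B(k + a, n - k + b) - log B(a, b)`.
#' Conjugate normal (known sigma): evaluated exactly through the conjugate
#' identity `log m(y) = log f(y | theta) + log pi(theta) - log p(theta | y)`
#' at the posterior mean.
#'
#' @param spec a [beta_binomial_spec()] or [conjugate_normal_spec()].
#' @return The exact log marginal likelihood.
#' @export
analytic_log_marginal <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  switch(spec$family,
    beta_binomial =
      lchoose(spec$n, spec$k) +
      lbeta(spec$k + spec$shape1, spec$n - spec$k + spec$shape2) -
      lbeta(spec$shape1, spec$shape2),
    conjugate_normal = {
      n <- length(spec$y)
      prec <- n / spec$sigma^2 + 1 / spec$prior_sd^2
      post_mean <- (sum(spec$y) / spec$sigma^2 +
                    spec$prior_mean / spec$prior_sd^2) / prec
      sum(stats::dnorm(spec$y, post_mean, spec$sigma, log = TRUE)) +
        stats::dnorm(post_mean, spec$prior_mean, spec$prior_sd, log = TRUE) -
        stats::dnorm(post_mean, post_mean, 1 / sqrt(prec), log = TRUE)
    },
    stop("unsupported toy family"))
}

#' Analytic log Bayes factor between two toy specs sharing the same data
#'
#' @param spec0,spec1 toy specs with identical observed data.
#' @return `analytic_log_marginal(spec1) - analytic_log_marginal(spec0)`.
#' @export
analytic_log_bf <- function(spec0, spec1) {
  if (!identical(toy_data_signature(spec0), toy_data_signature(spec1)))
    stop("the two specs must share the same observed data")
  analytic_log_marginal(spec1) - analytic_log_marginal(spec0)
}

#' Exact posterior draws from a conjugate toy
#'
#' Used for harmonic-mean experiments, which only need posterior samples.
#'
#' @param spec a toy spec.
#' @param n number of draws.
#' @return Numeric vector of posterior parameter draws.
#' @export
toy_posterior_sample <- function(spec, n) {
  switch(spec$family,
    beta_binomial = stats::rbeta(n, spec$shape1 + spec$k,
                                 spec$shape2 + spec$n - spec$k),
    conjugate_normal = {
      m <- length(spec$y)
      prec <- m / spec$sigma^2 + 1 / spec$prior_sd^2
      post_mean <- (sum(spec$y) / spec$sigma^2 +
                    spec$prior_mean / spec$prior_sd^2) / prec
      stats::rnorm(n, post_mean, 1 / sqrt(prec))
    })
}

#' Sequence simulation specification
#'
#' @param tree rooted `ape::phylo` (or Newick string) with branch lengths.
#' @param length_out number of sites.
#' @param model a [gtr_params()] or `context_model`.
#' @param root_chain a [root_markov_chain()]; required for context-model
#'   simulation, optional for GTR (defaults to the stationary base
#'   frequencies).
#' @param gap_mask optional logical matrix (tips x sites) of gap positions
#'   copied through the simulation; or a single logical vector applied to
#'   the root and inherited everywhere.
#' @param seed optional integer seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, length_out, model, root_chain = NULL,
                            gap_mask = NULL, seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), length_out >= 1)
  structure(list(tree = tree, length_out = as.integer(length_out),
                 model = model, root_chain = root_chain,
                 gap_mask = gap_mask, seed = seed),
            class = "simulation_spec")
}

#' Simulate a gapped alignment on a fixed rooted tree
#'
#' The root sequence is drawn from the root chain (GTR: from the stationary
#' base frequencies). Each branch then evolves every site independently:
#' under GTR by the transition matrix over the branch; under the context
#' model by the per-branch substitution probability with the neighbors held
#' fixed at the parent sequence (matching the likelihood's assumption). Gap
#' positions are copied through unchanged.
#'
#' @param spec a [simulation_spec()].
#' @return Character matrix of tip sequences (rows named by tip label).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ti <- tree_index(spec$tree)
  L <- spec$length_out
  n_all <- ti$n_tip + ti$n_node
  gap_root <- if (is.null(spec$gap_mask)) rep(FALSE, L)
  else if (is.matrix(spec$gap_mask)) rep(FALSE, L) else spec$gap_mask
  seqs <- vector("list", n_all)
  is_gtr <- inherits(spec$model, "gtr_params")
  root_seq <- if (is_gtr && is.null(spec$root_chain)) {
    s <- sample.int(4L, L, replace = TRUE, prob = spec$model$freqs)
    s[gap_root] <- NA_integer_
    s
  } else {
    if (is.null(spec$root_chain))
      stop("context-model simulation needs a root chain")
    simulate_root_sequence(spec$root_chain, L, gap_root)
  }
  seqs[[ti$root]] <- root_seq
  eig <- if (is_gtr) gtr_eigen(spec$model)
  # preorder: reverse of the postorder edge list
  for (e in rev(seq_along(ti$parent))) {
    par <- seqs[[ti$parent[e]]]
    child <- rep(NA_integer_, L)
    ok <- which(!is.na(par))
    if (is_gtr) {
      P <- gtr_probs_from_eigen(eig, ti$lengths[e])
      for (b in 1:4) {
        i <- ok[par[ok] == b]
        if (length(i))
          child[i] <- sample.int(4L, length(i), replace = TRUE, prob = P[b, ])
      }
    } else {
      P <- context_branch_probs(spec$model, ti$lengths[e])
      w <- c(NA_integer_, par[-L]); y <- c(par[-1], NA_integer_)
      for (i in ok) {
        if (is.na(w[i]) || is.na(y[i])) { child[i] <- par[i]; next }
        child[i] <- sample.int(4L, 1L, prob = P[par[i], , w[i], y[i]])
      }
    }
    seqs[[ti$child[e]]] <- child
  }
  out <- do.call(rbind, seqs[seq_len(ti$n_tip)])
  rownames(out) <- ti$labels
  if (is.matrix(spec$gap_mask)) {
    gm <- spec$gap_mask[ti$labels, , drop = FALSE]
    out[gm] <- NA_integer_
  }
  decode_bases(out)
}

#' Recovery experiments against analytic or qualitative oracles
#'
#' Runs the full pipeline at desk scale: simulate or construct data, run the
#' path in one or both directions, and report per-replicate estimates next
#' to the analytic value when one exists.
#'
#' `kind = "toy"` runs annealing + melting over a toy pair and reports
#' classic path sampling, mean path sampling and stepping-stone estimates
#' with bidirectional summaries. `kind = "gtr_vs_context"` simulates
#' alignments under GTR and reports the stepping-stone log Bayes factor of
#' the context model versus GTR (expected non-positive on average, as the
#' context model is penalized when the data carry no context signal).
#'
#' @param kind `"toy"` or `"gtr_vs_context"`.
#' @param n_replicates number of independent replicates (0 gives an empty
#'   report).
#' @param schedule a `bf_schedule` (annealing; the melting run reverses it).
#' @param pair toy pair for `kind = "toy"` (default: the
#'   Beta(1,1)-vs-Beta(2,2) beta-binomial pair with n = 20, k = 14).
#' @param sim_spec for `kind = "gtr_vs_context"`: a [simulation_spec()]
#'   under GTR (default: 5 taxa, 2000 sites, branch lengths 0.1).
#' @param root_order,strand_symmetric context-model settings for the
#'   comparison pair.
#' @param save_interval,n_equil forwarded to [run_path()].
#' @param directions `"both"` or `"annealing"` only.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data.frame, one row per replicate.
#' @export
recovery_experiment <- function(kind = c("toy", "gtr_vs_context"),
                                n_replicates = 1,
                                schedule = sigmoid_schedule(50, Q = 200,
                                                            alpha = 10),
                                pair = NULL, sim_spec = NULL,
                                root_order = 0, strand_symmetric = TRUE,
                                save_interval = 10L, n_equil = NULL,
                                directions = c("both", "annealing"),
                                seed = 1L) {
  kind <- match.arg(kind)
  directions <- match.arg(directions)
  if (n_replicates == 0)
    return(data.frame(replicate = integer(0), method = character(0),
                      log_bf = numeric(0)))
  rows <- list()
  for (r in seq_len(n_replicates)) {
    if (kind == "toy") {
      p <- pair %||% toy_pair(beta_binomial_spec(20, 14, 1, 1),
                              beta_binomial_spec(20, 14, 2, 2))
      truth <- analytic_log_bf(p$spec0, p$spec1)
      tr_a <- run_path(p, schedule, mode = "ss", n_equil = n_equil,
                       save_interval = save_interval, seed = seed + r)
      ests <- list(ps = ps_estimate(tr_a), ps_mean = ps_mean_estimate(tr_a),
                   ss = ss_log_bf(tr_a))
      if (directions == "both") {
        tr_m <- run_path(p, reverse_schedule(schedule), mode = "ss",
                         n_equil = n_equil, save_interval = save_interval,
                         seed = seed + r + 500000L)
        ests <- list(
          ps = bidirectional_summary(ests$ps, ps_estimate(tr_m)),
          ps_mean = bidirectional_summary(ests$ps_mean,
                                          ps_mean_estimate(tr_m)),
          ss = bidirectional_summary(ests$ss, ss_log_bf(tr_m)))
      }
      for (m in names(ests)) {
        e <- ests[[m]]
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, method = m, direction = e$direction,
          log_bf = e$log_bf, variance = e$variance,
          bde = e$bidirectional_error, analytic = truth,
          error = e$log_bf - truth)
      }
    } else {
      sp <- sim_spec %||% simulation_spec(
        tree = "(((cow:0.1,sheep:0.1):0.1,pig:0.1):0.1,(horse:0.1,donkey:0.1):0.1);",
        length_out = 2000, model = gtr_params())
      sp$seed <- seed + r
      aln <- simulate_alignment(sp)
      p <- phylo_pair(aln, sp$tree, root_order = root_order,
                      strand_symmetric = strand_symmetric)
      tr_a <- run_path(p, schedule, mode = "ss", n_equil = n_equil,
                       save_interval = save_interval,
                       seed = seed + r + 100000L)
      e <- ss_log_bf(tr_a)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = "ss", direction = e$direction,
        log_bf = e$log_bf, variance = e$variance, bde = NA_real_,
        analytic = NA_real_, error = NA_real_)
    }
  }
  do.call(rbind, rows)
}
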