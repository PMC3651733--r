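#' Traverse a power-posterior path and record a trace
#'
#' Implements the annealing/melting traversal protocol: the chain is
#' equilibrated at the starting endpoint of the schedule (`beta = 0` for
#' annealing, `beta = 1` for melting), then visits every grid point in order,
#' running `Q` update cycles at each. The state at the end of each grid
#' point's cycles (i.e. the point saved before each update of `beta`) is the
#' classic path-sampling sample; in `"mean"` and `"ss"` modes additional
#' samples are collected every `save_interval` cycles, skipping the first
#' `save_interval` cycles after a `beta` switch when `Q > 2 * save_interval`.
#'
#' @param pair a model pair ([toy_pair()] or [phylo_pair()]).
#' @param schedule a `bf_schedule`; its `direction` decides the traversal.
#' @param mode `"classic"` (one potential value per grid point), `"mean"` or
#'   `"ss"` (per-grid-point sample sets; the two modes record the same trace,
#'   they differ in the estimator applied afterwards).
#' @param n_equil equilibration cycles at the starting endpoint
#'   (default `10 * Q`).
#' @param save_interval cycles between sample collections (default 10).
#' @param seed optional integer; when given, `set.seed` is called so reruns
#'   are bit-identical.
#' @param init_state optional starting state (defaults to
#'   [pair_init_state()]).
#' @return A `bf_trace`: traversal-ordered `betas`, per-beta sample matrices
#'   (columns `U`, `ll0`, `ll1`, `k0`, `k1`), the classic `U_last` values,
#'   and run metadata.
#' @export
run_path <- function(pair, schedule, mode = c("ss", "mean", "classic"),
                     n_equil = NULL, save_interval = 10L, seed = NULL,
                     init_state = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "bf_schedule"))
  if (!is.null(seed)) set.seed(seed)
  Q <- schedule$Q
  n_equil <- n_equil %||% (10L * Q)
  collect <- mode != "classic"
  betas <- if (schedule$direction == "annealing") schedule$betas
           else rev(schedule$betas)
  state <- init_state %||% pair_init_state(pair)
  k0 <- pair_log_kernel(pair, state, 0L)
  k1 <- pair_log_kernel(pair, state, 1L)
  if (!is.finite(k0) || !is.finite(k1))
    stop("non-finite kernel at initialization")
  for (i in seq_len(n_equil)) state <- update_cycle(pair, state, betas[1])
  save_at <- if (collect) {
    start <- if (Q > 2L * save_interval) save_interval else 0L
    cc <- seq_len(Q)
    sort(unique(c(cc[cc > start & cc %% save_interval == 0L], Q)))
  } else Q
  n_pts <- length(betas)
  samples <- vector("list", n_pts)
  U_last <- numeric(n_pts)
  for (j in seq_len(n_pts)) {
    b <- betas[j]
    rows <- matrix(NA_real_, length(save_at), 5,
                   dimnames = list(NULL, c("U", "ll0", "ll1", "k0", "k1")))
    r <- 1L
    for (cyc in seq_len(Q)) {
      state <- update_cycle(pair, state, b)
      if (cyc %in% save_at) {
        k0 <- pair_log_kernel(pair, state, 0L)
        k1 <- pair_log_kernel(pair, state, 1L)
        rows[r, ] <- c(k1 - k0,
                       pair_log_lik(pair, state, 0L),
                       pair_log_lik(pair, state, 1L), k0, k1)
        r <- r + 1L
      }
    }
    if (any(!is.finite(rows[, "U"])))
      stop("non-finite potential sampled at beta = ", b)
    samples[[j]] <- rows
    U_last[j] <- rows[nrow(rows), "U"]
  }
  structure(list(betas = betas, direction = schedule$direction, mode = mode,
                 Q = Q, save_interval = as.integer(save_interval),
                 n_equil = n_equil, schedule = schedule, samples = samples,
                 U_last = U_last,
                 prior_tags = pair$prior_tags %||% c(NA, NA)),
            class = "bf_trace")
}

#' @export
print.bf_trace <- function(x, ...) {
  cat(sprintf("<bf_trace> %s, %s, K=%d, Q=%d, %d saved values\n",
              x$mode, x$direction, length(x$betas) - 1L, x$Q,
              sum(vapply(x$samples, nrow, integer(1)))))
  invisible(x)
}

trace_grid <- function(trace) sort(trace$betas)

# index mapping traversal order -> increasing-beta order
trace_increasing <- function(trace) order(trace$betas)

#' Effective sample size and decorrelation time
#'
#' Autocorrelation-based effective sample size with Geyer-style truncation
#' (sum of autocorrelations up to the first negative lag). The decorrelation
#' time `tau = n / n_eff >= 1` multiplies the path-sampling variance when
#' samples are serially correlated.
#'
#' @param values numeric series (length >= 10).
#' @return list with `K_eff` and `tau`.
#' @export
effective_samples <- function(values) {
  n <- length(values)
  if (n < 10) stop("need at least 10 values")
  if (stats::sd(values) == 0) {
    warning("constant series; reporting tau = 1")
    return(list(K_eff = n, tau = 1))
  }
  rho <- stats::acf(values, lag.max = min(n - 1L, 200L),
                    plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  tau <- max(1, 1 + 2 * sum(rho))
  list(K_eff = n / tau, tau = tau)
}
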