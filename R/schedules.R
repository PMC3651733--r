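#' Power-posterior schedules
#'
#' A schedule is the ordered grid of inverse-temperature values
#' `beta_0 = 0 < beta_1 < ... < beta_K = 1` at which the model-switch path
#' between two competing models is visited, together with the number of MCMC
#' cycles `Q` spent at each grid point, a traversal direction, and optional
#' split-interval boundaries used for parallel runs and for the bidirectional
#' (repeatability) error.
#'
#' @name schedules
NULL

new_schedule <- function(betas, Q, direction, kind, alpha = NA_real_,
                         splits = numeric(0)) {
  stopifnot(Q >= 1)
  direction <- match.arg(direction, c("annealing", "melting"))
  if (is.unsorted(betas, strictly = TRUE))
    stop("schedule grid must be strictly increasing")
  structure(
    list(betas = betas, K = length(betas) - 1L, Q = as.integer(Q),
         direction = direction, kind = kind, alpha = alpha, splits = splits),
    class = "bf_schedule")
}

validate_unit_schedule <- function(betas) {
  if (abs(betas[1]) > 0 || abs(betas[length(betas)] - 1) > 0)
    stop("schedule must start at beta = 0 and end at beta = 1 exactly")
}

#' Constant-increment schedule
#'
#' Grid with `beta_k = k/K`: the original constant-increment path.
#'
#' @param K number of path steps (the grid has `K + 1` points).
#' @param Q MCMC update cycles run at each grid point.
#' @param direction `"annealing"` (0 to 1) or `"melting"` (1 to 0).
#' @param n_splits optional number of split intervals; boundaries are placed
#'   at equal step-index spacing (equal work per interval) and recorded on the
#'   beta axis.
#' @return A `bf_schedule` object.
#' @export
#' @examples
#' constant_schedule(4, Q = 10)$betas  # 0 0.25 0.5 0.75 1
constant_schedule <- function(K, Q = 100, direction = "annealing",
                              n_splits = NULL) {
  if (K < 1) stop("K must be >= 1")
  betas <- seq.int(0L, K) / K
  betas[1] <- 0; betas[K + 1] <- 1
  s <- new_schedule(betas, Q, direction, "constant")
  if (!is.null(n_splits)) s <- add_splits(s, n_splits)
  s
}

#' Sigmoid schedule
#'
#' Maps the uniform step index through a rescaled logistic
#' `g(u) = 1 / (1 + exp(-alpha * (2u - 1)))` so that, for large `alpha`, grid
#' points concentrate near both endpoints of the path, where the power
#' posterior changes fastest (one model is close to its prior there). The grid
#' is symmetric: `beta_{K-k} = 1 - beta_k`.
#'
#' @inheritParams constant_schedule
#' @param alpha sigmoid shape (> 0); values around 9-12 concentrate points
#'   strongly near the endpoints, `alpha -> 0` recovers the constant grid.
#' @return A `bf_schedule` object.
#' @export
sigmoid_schedule <- function(K, Q = 100, alpha, direction = "annealing",
                             n_splits = NULL) {
  if (K < 2) stop("K must be >= 2 for a sigmoid schedule")
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  u <- seq.int(0L, K) / K
  g <- stats::plogis(alpha * (2 * u - 1))
  betas <- (g - g[1]) / (g[K + 1] - g[1])
  betas[1] <- 0; betas[K + 1] <- 1
  # enforce exact symmetry against floating-point drift
  betas <- (betas + rev(1 - betas)) / 2
  s <- new_schedule(betas, Q, direction, "sigmoid", alpha = alpha)
  if (!is.null(n_splits)) s <- add_splits(s, n_splits)
  s
}

#' Flexible-increment schedule
#'
#' Piecewise-constant increments: the unit interval is partitioned by
#' `boundaries` and interval `i` receives `per_interval_K[i]` equal steps.
#' Interval boundaries are recorded as split points.
#'
#' @param boundaries increasing vector starting at 0 and ending at 1.
#' @param per_interval_K integer vector, one entry per interval, each >= 1.
#' @inheritParams constant_schedule
#' @return A `bf_schedule` object.
#' @export
flexible_schedule <- function(boundaries, per_interval_K, Q = 100,
                              direction = "annealing") {
  if (is.unsorted(boundaries, strictly = TRUE) ||
      boundaries[1] != 0 || boundaries[length(boundaries)] != 1)
    stop("boundaries must strictly increase from 0 to 1")
  n_int <- length(boundaries) - 1L
  if (length(per_interval_K) != n_int || any(per_interval_K < 1))
    stop("per_interval_K must give one count >= 1 per interval")
  betas <- unlist(lapply(seq_len(n_int), function(i) {
    lo <- boundaries[i]; hi <- boundaries[i + 1]; k <- per_interval_K[i]
    lo + (hi - lo) * seq.int(0L, k - 1L) / k
  }))
  betas <- c(betas, 1)
  s <- new_schedule(betas, Q, direction, "flexible",
                    splits = boundaries[c(-1, -length(boundaries))])
  s
}

#' Add split-interval boundaries to a schedule
#'
#' Boundaries are placed at equal step-index spacing and snapped to the beta
#' grid, so each interval holds (nearly) the same number of steps.
#'
#' @param schedule a `bf_schedule`.
#' @param n_splits number of intervals (>= 1).
#' @return The schedule with interior boundaries recorded in `$splits`.
#' @export
add_splits <- function(schedule, n_splits) {
  stopifnot(inherits(schedule, "bf_schedule"), n_splits >= 1)
  K <- schedule$K
  if (n_splits > K) stop("cannot split into more intervals than steps")
  idx <- round(seq(0, K, length.out = n_splits + 1)) + 1L
  schedule$splits <- schedule$betas[idx[c(-1, -length(idx))]]
  schedule
}

#' Reverse a schedule's traversal direction
#'
#' @param schedule a `bf_schedule`.
#' @return The same grid with direction flipped (annealing <-> melting).
#' @export
reverse_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "bf_schedule"))
  schedule$direction <-
    if (schedule$direction == "annealing") "melting" else "annealing"
  schedule
}

#' @export
print.bf_schedule <- function(x, ...) {
  cat(sprintf("<bf_schedule> kind=%s K=%d Q=%d direction=%s%s%s\n",
              x$kind, x$K, x$Q, x$direction,
              if (!is.na(x$alpha)) sprintf(" alpha=%g", x$alpha) else "",
              if (length(x$splits)) sprintf(" splits=%d", length(x$splits) + 1L)
              else ""))
  invisible(x)
}

# schedule restricted to [lo, hi]; used for independent split-interval runs.
# lo/hi must lie on the grid. Returned object keeps Q/direction/kind.
subset_schedule <- function(schedule, lo, hi) {
  b <- schedule$betas
  i <- which(abs(b - lo) < 1e-12); j <- which(abs(b - hi) < 1e-12)
  if (length(i) != 1 || length(j) != 1 || i >= j)
    stop("split boundaries must lie on the schedule grid")
  s <- schedule
  s$betas <- b[i:j]
  s$K <- length(s$betas) - 1L
  s$splits <- numeric(0)
  s
}

# interval index (1-based) for a sub-segment [lo,hi] of the path, given
# interior boundaries; segments never straddle boundaries because boundaries
# are snapped to the grid.
segment_interval <- function(lo, boundaries) {
  findInterval(lo + 1e-13, c(0, boundaries))
}

#' Per-interval contributions of a path run
#'
#' Decomposes a whole-path estimate into additive contributions of the
#' schedule's split intervals (the integral over `[0,1]` written as a sum of
#' sub-integrals). Contributions are oriented from beta = 0 towards beta = 1
#' regardless of the traversal direction, and sum exactly to the whole-path
#' estimate.
#'
#' @param trace a `bf_trace` from [run_path()].
#' @param schedule schedule carrying the split boundaries (defaults to the
#'   trace's own schedule).
#' @param method `"ps"`, `"ps_mean"` or `"ss"`: which estimator's per-step
#'   terms to aggregate.
#' @return data.frame with columns `lo`, `hi`, `contribution`.
#' @export
split_contributions <- function(trace, schedule = trace$schedule,
                                method = c("ss", "ps", "ps_mean")) {
  method <- match.arg(method)
  seg <- segment_terms(trace, method)
  bounds <- schedule$splits
  if (!all(vapply(bounds, function(b)
    any(abs(trace_grid(trace) - b) < 1e-12), logical(1))))
    stop("split boundaries do not lie on the trace's beta grid")
  iv <- segment_interval(seg$lo, bounds)
  n_int <- length(bounds) + 1L
  contrib <- vapply(seq_len(n_int),
                    function(i) sum(seg$contribution[iv == i]), numeric(1))
  edges <- c(0, bounds, 1)
  data.frame(lo = edges[-length(edges)], hi = edges[-1],
             contribution = contrib)
}
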