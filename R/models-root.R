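#' Ancestral root sequence Markov chain
#'
#' The root sequence is modeled as an inhomogeneous Markov chain of order 0,
#' 1 or 2 over \{A, C, G, T\}: `Pi(x)`, `Pi(x | v)` or `Pi(x | v, w)` where
#' `v`, `w` are the immediately preceding bases. Positions whose focal or
#' conditioning base is a gap contribute a factor of 1. Leading positions
#' with insufficient history use explicit lower-order initial distributions,
#' keeping the chain a proper distribution over sequences.
#'
#' @param order 0, 1 or 2.
#' @param trans transition parameters: for order 0 a length-4 probability
#'   vector; for order 1 a 4x4 matrix with `trans[v, x]` and rows summing to
#'   1; for order 2 a 4x4x4 array `trans[v, w, x]` with
#'   `trans[v, w, ]` summing to 1 (v precedes w, w immediately precedes x).
#' @param init initial distribution(s): order 1 needs a length-4 vector for
#'   the first position; order 2 a list with `$p1` (length-4) and `$p2`
#'   (4x4 matrix `[v, x]`). Defaults are uniform.
#' @return Object of class `root_chain`.
#' @export
root_markov_chain <- function(order, trans = NULL, init = NULL) {
  stopifnot(order %in% 0:2)
  u4 <- rep(0.25, 4)
  if (order == 0) {
    trans <- trans %||% u4
    stopifnot(length(trans) == 4, abs(sum(trans) - 1) < 1e-8)
    init <- NULL
  } else if (order == 1) {
    trans <- trans %||% matrix(0.25, 4, 4)
    stopifnot(all(dim(trans) == c(4, 4)),
              all(abs(rowSums(trans) - 1) < 1e-8))
    init <- init %||% u4
    stopifnot(length(init) == 4, abs(sum(init) - 1) < 1e-8)
  } else {
    trans <- trans %||% array(0.25, dim = c(4, 4, 4))
    stopifnot(all(dim(trans) == c(4, 4, 4)),
              all(abs(apply(trans, c(1, 2), sum) - 1) < 1e-8))
    init <- init %||% list(p1 = u4, p2 = matrix(0.25, 4, 4))
    stopifnot(abs(sum(init$p1) - 1) < 1e-8,
              all(abs(rowSums(init$p2) - 1) < 1e-8))
  }
  structure(list(order = as.integer(order), trans = trans, init = init),
            class = "root_chain")
}

#' Log probability of a root sequence under the root chain
#'
#' @param chain a [root_markov_chain()].
#' @param sequence character vector over A/C/G/T/- (or integer codes with
#'   `NA` gaps).
#' @return Sum of log conditional probabilities; gap factors contribute 0.
#' @export
root_log_prob <- function(chain, sequence) {
  stopifnot(inherits(chain, "root_chain"))
  s <- if (is.character(sequence)) encode_bases(sequence) else as.integer(sequence)
  n <- length(s)
  if (n == 0) stop("empty sequence")
  sum(root_site_log_probs(chain, s, seq_len(n), s))
}

# per-position log factors for positions `pos`, where `cand` supplies the
# focal base at those positions and `s` the full sequence for conditioning.
# Vectorized; gap (NA) in focal or conditioning base gives 0.
root_site_log_probs <- function(chain, s, pos, cand) {
  n <- length(s)
  x <- cand
  out <- numeric(length(pos))
  if (chain$order == 0) {
    ok <- !is.na(x)
    out[ok] <- log(chain$trans[x[ok]])
    return(out)
  }
  v <- ifelse(pos >= 2, s[pmax(pos - 1, 1)], NA)
  if (chain$order == 1) {
    first <- pos == 1
    ok1 <- first & !is.na(x)
    out[ok1] <- log(chain$init[x[ok1]])
    ok <- !first & !is.na(x) & !is.na(v)
    out[ok] <- log(chain$trans[cbind(v[ok], x[ok])])
    return(out)
  }
  w <- v                               # base immediately preceding x
  v2 <- ifelse(pos >= 3, s[pmax(pos - 2, 1)], NA)
  p1 <- pos == 1; p2 <- pos == 2
  ok1 <- p1 & !is.na(x)
  out[ok1] <- log(chain$init$p1[x[ok1]])
  ok2 <- p2 & !is.na(x) & !is.na(w)
  out[ok2] <- log(chain$init$p2[cbind(w[ok2], x[ok2])])
  ok <- !p1 & !p2 & !is.na(x) & !is.na(w) & !is.na(v2)
  out[ok] <- log(chain$trans[cbind(v2[ok], w[ok], x[ok])])
  out
}

#' Sample a root sequence from the root chain
#'
#' @param chain a [root_markov_chain()].
#' @param length_out sequence length.
#' @param gap_mask optional logical vector marking gap positions; gaps are
#'   emitted as `NA` and skipped as conditioning history is still positional
#'   (a gap conditioning base simply draws from a uniform fallback, matching
#'   the factor-1 rule).
#' @return integer vector (1..4, `NA` at gaps).
#' @export
simulate_root_sequence <- function(chain, length_out, gap_mask = NULL) {
  s <- integer(length_out)
  gap <- gap_mask %||% rep(FALSE, length_out)
  u4 <- rep(0.25, 4)
  for (i in seq_len(length_out)) {
    if (gap[i]) { s[i] <- NA_integer_; next }
    p <- if (chain$order == 0) chain$trans
    else if (chain$order == 1) {
      if (i == 1) chain$init
      else if (is.na(s[i - 1])) u4 else chain$trans[s[i - 1], ]
    } else {
      if (i == 1) chain$init$p1
      else if (i == 2) { if (is.na(s[1])) u4 else chain$init$p2[s[1], ] }
      else if (is.na(s[i - 1]) || is.na(s[i - 2])) u4
      else chain$trans[s[i - 2], s[i - 1], ]
    }
    s[i] <- sample.int(4L, 1L, prob = p)
  }
  s
}
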