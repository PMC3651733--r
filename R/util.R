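BASES <- c("A", "C", "G", "T")
COMPLEMENT_IDX <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G

#' Encode / decode nucleotide sequences
#'
#' Internal representation: integers 1..4 for A,C,G,T and `NA` for a gap.
#' `N` is treated as a gap on input.
#'
#' @param x character vector of single letters, or a character matrix.
#' @return integer vector/matrix with `NA` at gaps.
#' @keywords internal
encode_bases <- function(x) {
  up <- toupper(x)
  bad <- !(up %in% c(BASES, "-", "N"))
  if (any(bad))
    stop("illegal characters in sequence: ",
         paste(unique(up[bad]), collapse = ", "))
  out <- match(up, BASES)  # '-' and 'N' -> NA
  if (is.matrix(x)) dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

decode_bases <- function(x) {
  out <- ifelse(is.na(x), "-", BASES[x])
  if (is.matrix(x)) dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Dirichlet density / sampler used by simplex proposal kernels
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

ddirichlet_log <- function(x, alpha) {
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
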