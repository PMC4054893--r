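#' Multinomial negative log-likelihood (constant term dropped)
#'
#' Computes `-sum(r * log(p))`, the negative log-likelihood of observing the
#' read depth vector `r` under a multinomial model with parameter `p`, up to
#' the additive constant that depends only on `r` (the multinomial
#' coefficient, which cancels in all comparisons). `r` may be real valued,
#' which arises after the inverse weight transform. Positions with
#' `r[j] == 0` contribute nothing (`0 * log(0) == 0`); a zero `p[j]` against
#' positive `r[j]` yields `Inf`.
#'
#' @param r Non-negative numeric vector of (possibly transformed) read counts.
#' @param p Multinomial parameter on the unit simplex, same length as `r`.
#' @return Non-negative real number (possibly `Inf`).
#' @examples
#' multinomial_nll(c(1, 1), c(0.5, 0.5)) # 2 log 2
#' @export
multinomial_nll <- function(r, p) {
  if (length(r) != length(p)) stop("r and p must have equal length")
  if (any(r < 0)) stop("negative read counts")
  act <- r > 0
  if (any(p[act] <= 0)) return(Inf)
  -sum(r[act] * log(p[act]))
}

#' Unconstrained maximum-likelihood multinomial parameter
#'
#' The parameter minimizing the multinomial negative log-likelihood over the
#' whole simplex is the normalized read depth vector \code{r / sum(r)}.
#'
#' @param r Non-negative numeric vector with positive sum.
#' @return Numeric vector on the unit simplex.
#' @export
unconstrained_mle <- function(r) normalize_l1(r)

#' Multinomial parameter of a genome mixture
#'
#' The probability that a read falls in interval `j` is proportional to
#' `w_j * (C mu)_j`: the interval weight times the amount of DNA from that
#' interval across the mixed genomes.
#'
#' @param C Interval count matrix (m x n), column 1 the all-2 normal genome.
#' @param mu Genome mixing vector on the unit simplex, length `ncol(C)`.
#' @param w Positive interval weights (defaults to all ones).
#' @return Numeric vector on the unit simplex, length `nrow(C)`.
#' @export
mixture_parameter <- function(C, mu, w = rep(1, nrow(C))) {
  C <- as.matrix(C)
  if (length(mu) != ncol(C)) stop("mu must have one entry per genome")
  if (length(w) != nrow(C)) stop("w must have one entry per interval")
  x <- w * as.vector(C %*% mu)
  if (sum(x) <= 0) stop("degenerate mixture: C mu is identically zero")
  normalize_l1(x)
}

#' Inverse weight transform of a read depth vector
#'
#' Maps the observed read depth vector into the equal-weight coordinate
#' system: `normalize(r / w)`, rescaled to preserve the original total
#' `sum(r)` so that quantities depending on the total read count are
#' unchanged. Solving the unweighted decomposition on the transformed vector
#' solves the weighted problem.
#'
#' @param r Non-negative numeric vector of read counts.
#' @param w Positive interval weights, same length as `r`.
#' @return Real-valued transformed read depth vector with `sum == sum(r)`.
#' @export
inverse_weight_transform <- function(r, w) {
  if (length(r) != length(w)) stop("r and w must have equal length")
  if (any(w <= 0)) stop("interval weights must be positive")
  normalize_l1(r / w) * sum(r)
}
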