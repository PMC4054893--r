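#' Decompose a tumor sample into subpopulation genomes and mixing fractions
#'
#' Finds the maximum-likelihood interval count matrix `C` (integer copy
#' numbers per interval per subpopulation genome, with column 1 fixed to the
#' diploid normal) and genome mixing vector `mu` for a segmented tumor /
#' matched-normal read count profile. The observed tumor read depth vector is
#' modelled as multinomial with parameter proportional to `w * (C mu)`, where
#' the weights `w` are the matched-normal counts. The search enumerates
#' candidate tumor columns restricted to those with compatible order with the
#' inverse-weight-transformed read depths, solves a convex subproblem in the
#' mixing vector for each candidate, and returns the complete set of
#' solutions tied (within `tie_tol`) with the optimum.
#'
#' @param counts A data frame of interval read counts with columns `id`,
#'   `chromosome`, `start`, `end`, `tumor_count`, `normal_count` (see
#'   [read_interval_counts()]). Rows must have positive `normal_count`.
#' @param n Number of distinct subpopulation genomes including the normal:
#'   2 (one tumor population) or 3 (two tumor subpopulations).
#' @param k Maximum copy number considered (integer `>= 2`).
#' @param bounds Optional data frame with columns `id`, `lower`, `upper`
#'   giving per-interval copy number bounds (e.g. from
#'   [infer_baseline_bounds()]). Defaults to `[0, k]` everywhere.
#' @param expected_ploidy Optional expected average tumor ploidy; when given,
#'   the effective bounds are rescaled by `expected_ploidy / 2` (rounded
#'   outward, clamped to `[0, k]`) to steer the search toward solutions with
#'   that ploidy.
#' @param tie_tol Solutions within this absolute tolerance of the optimal
#'   negative log-likelihood are all returned.
#' @param opt_tol Convergence tolerance of the per-candidate convex
#'   optimization (in the internal mixing coordinate).
#' @param order_pruning Use the compatible-order restriction of the candidate
#'   space (the default). Setting `FALSE` forces exhaustive enumeration over
#'   all columns within bounds; only feasible for small instances.
#' @return An object of class `mixture_fit`; see [tidy.mixture_fit()],
#'   [glance.mixture_fit()] and [autoplot.mixture_fit()].
#' @examples
#' sim <- simulate_tumor_sample(sim_config(m = 10, k = 2, phi = 0), seed = 1)
#' fit <- decompose_mixture(sim$counts, n = 2, k = 2)
#' glance(fit)
#' @export
decompose_mixture <- function(counts, n = 2, k = 3, bounds = NULL,
                              expected_ploidy = NULL,
                              tie_tol = 1e-6, opt_tol = 1e-12,
                              order_pruning = TRUE) {
  counts <- validate_counts(counts)
  if (!n %in% c(2L, 3L)) stop("n must be 2 or 3")
  if (k < 2) stop("k must be at least 2")
  m <- nrow(counts)
  if (m < n) stop("need at least n intervals")

  r <- as.numeric(counts$tumor_count)
  w <- as.numeric(counts$normal_count)
  r_trans <- inverse_weight_transform(r, w)

  bt <- resolve_bounds(counts, bounds, k)
  if (!is.null(expected_ploidy)) {
    bt <- apply_ploidy_rescaling(bt, expected_ploidy, k = k)
  }

  t0 <- proc.time()[["elapsed"]]
  if (n == 2L) {
    res <- cpp_solve_n2(r_trans, bt$lower, bt$upper, as.integer(k),
                        tie_tol, opt_tol, FALSE, order_pruning)
  } else {
    res <- cpp_solve_n3(r_trans, bt$lower, bt$upper, as.integer(k),
                        tie_tol, opt_tol, order_pruning)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  if (res$count == 0 || length(res$solutions) == 0) {
    stop("infeasible bounds: empty candidate space")
  }

  sols <- purrr::map(res$solutions, function(s) {
    if (n == 2L) {
      C <- cbind(normal = rep(2L, m), tumor = as.integer(s$c2))
      mu_int <- c(1 - s$mu2_internal, s$mu2_internal)
    } else {
      C <- cbind(normal = rep(2L, m), tumor1 = as.integer(s$c2),
                 tumor2 = as.integer(s$c3))
      mu_int <- s$mu_internal
    }
    mu <- if (all(colSums(C)[mu_int > 0] > 0)) internal_to_mu(C, mu_int)
          else c(1, rep(0, n - 1))
    can <- canonicalize_solution(C, mu)
    list(C = can$C, mu = can$mu,
         p = mixture_parameter(can$C, can$mu, w),
         nll = s$nll)
  })

  # Theorem-2 part 1: any optimum's transformed-space parameter has
  # compatible order with the transformed read depths; drop numerically
  # incompatible tie members (tolerance guards optimizer round-off).
  keep <- purrr::map_lgl(sols, function(s) {
    p_hat <- normalize_l1(as.vector(s$C %*% s$mu))
    compatible_order_tol(r_trans, p_hat, 1e-9)
  })
  if (any(keep)) sols <- sols[keep]

  # deduplicate on canonical (C, mu rounded at 1e-6)
  key <- purrr::map_chr(sols, function(s) {
    paste(paste(s$C, collapse = ","), paste(round(s$mu, 6), collapse = ","))
  })
  sols <- sols[!duplicated(key)]

  fit <- structure(
    list(solutions = sols,
         counts = counts,
         n = as.integer(n), k = as.integer(k), m = m,
         bounds = bt,
         tie_tol = tie_tol,
         candidates = res$count,
         best_nll = res$best_nll,
         total_tumor_reads = sum(r),
         total_reads = sum(r) + sum(w),
         order_pruning = order_pruning,
         elapsed = elapsed),
    class = "mixture_fit")
  fit$representative <- select_representative_index(
    sols, counts$end - counts$start)
  fit
}

# tolerance-aware weak compatible order: violation only when a strict
# increase in a meets a drop in b larger than tol
compatible_order_tol <- function(a, b, tol = 0) {
  ord <- order(a)
  a <- a[ord]
  b <- b[ord]
  run_max <- -Inf
  i <- 1L
  m <- length(a)
  while (i <= m) {
    j <- i
    while (j < m && a[j + 1L] == a[i]) j <- j + 1L
    if (min(b[i:j]) < run_max - tol) return(FALSE)
    run_max <- max(run_max, b[i:j])
    i <- j + 1L
  }
  TRUE
}

validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("id", "chromosome", "start", "end", "tumor_count", "normal_count")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop("counts is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(counts) < 2) stop("need at least two intervals")
  if (any(counts$end <= counts$start)) stop("intervals must have start < end")
  if (any(counts$tumor_count < 0) || any(counts$normal_count < 0)) {
    stop("read counts must be non-negative")
  }
  if (any(counts$normal_count == 0)) {
    stop("intervals with zero normal coverage must be removed upstream")
  }
  counts
}

resolve_bounds <- function(counts, bounds, k) {
  m <- nrow(counts)
  if (is.null(bounds)) {
    return(tibble::tibble(id = counts$id, lower = rep(0L, m),
                          upper = rep(as.integer(k), m)))
  }
  bounds <- tibble::as_tibble(bounds)
  if (!all(c("id", "lower", "upper") %in% names(bounds))) {
    stop("bounds must have columns id, lower, upper")
  }
  idx <- match(counts$id, bounds$id)
  if (anyNA(idx)) stop("bounds missing for some intervals")
  bt <- tibble::tibble(id = counts$id,
                       lower = as.integer(bounds$lower[idx]),
                       upper = as.integer(bounds$upper[idx]))
  if (any(bt$lower < 0) || any(bt$upper > k) || any(bt$lower > bt$upper)) {
    stop("infeasible bounds")
  }
  bt
}

#' Rescale copy number bounds toward an expected tumor ploidy
#'
#' Bounds centered on the diploid baseline are scaled by
#' `expected_ploidy / baseline_ploidy`, rounding the lower bound down and the
#' upper bound up, then clamped to `[0, k]`.
#'
#' @param bounds Data frame with columns `id`, `lower`, `upper`.
#' @param expected_ploidy Positive expected average tumor ploidy.
#' @param k Maximum copy number to clamp to.
#' @param baseline_ploidy Ploidy the input bounds refer to (default 2).
#' @return Bounds data frame with rescaled `lower` and `upper`.
#' @export
apply_ploidy_rescaling <- function(bounds, expected_ploidy, k,
                                   baseline_ploidy = 2) {
  if (expected_ploidy <= 0 || baseline_ploidy <= 0) {
    stop("ploidy must be positive")
  }
  s <- expected_ploidy / baseline_ploidy
  dplyr::mutate(
    tibble::as_tibble(bounds),
    lower = pmin(pmax(as.integer(floor(.data$lower * s)), 0L), as.integer(k)),
    upper = pmin(pmax(as.integer(ceiling(.data$upper * s)), 0L), as.integer(k))
  )
}

#' Enumerate candidate tumor copy-number columns (n = 2)
#'
#' Lists every integer vector in `{0..k}^m` that has compatible order with
#' the (transformed) read depth vector and lies within the per-interval
#' bounds. Without bounds the number of candidates is `choose(m + k, k)`.
#' Intended for small instances and testing; [decompose_mixture()] streams
#' the same space without materializing it.
#'
#' @param r_transformed Numeric vector of transformed read depths.
#' @param k Maximum copy number.
#' @param bounds Optional data frame with columns `lower`, `upper` (row
#'   order matching `r_transformed`).
#' @return Integer matrix with one candidate column per row.
#' @export
enumerate_tumor_columns <- function(r_transformed, k, bounds = NULL) {
  m <- length(r_transformed)
  lo <- if (is.null(bounds)) rep(0L, m) else as.integer(bounds$lower)
  hi <- if (is.null(bounds)) rep(as.integer(k), m) else as.integer(bounds$upper)
  cpp_enumerate_n2(r_transformed, lo, hi, as.integer(k))
}

#' Count candidate tumor copy-number columns (n = 2)
#'
#' @inheritParams enumerate_tumor_columns
#' @return Number of order-compatible columns within bounds.
#' @export
count_tumor_columns <- function(r_transformed, k, bounds = NULL) {
  m <- length(r_transformed)
  lo <- if (is.null(bounds)) rep(0L, m) else as.integer(bounds$lower)
  hi <- if (is.null(bounds)) rep(as.integer(k), m) else as.integer(bounds$upper)
  res <- cpp_solve_n2(r_transformed, lo, hi, as.integer(k),
                      1e-6, 1e-12, TRUE, TRUE)
  res$count
}

#' Optimize the mixing vector for a fixed interval count matrix
#'
#' Minimizes the multinomial negative log-likelihood of `r` over the convex
#' hull of the L1-normalized columns of `C` (the internal mixing
#' coordinates). Exposed mainly for testing; the solver performs this
#' optimization per enumerated candidate in compiled code.
#'
#' @param C Interval count matrix (m x n), n = 2 or 3.
#' @param r Read depth vector (may be real valued).
#' @param opt_tol Convergence tolerance in the internal coordinate.
#' @return List with `mu_internal` (on the simplex) and `nll`.
#' @export
optimize_mu_for_C <- function(C, r, opt_tol = 1e-12) {
  C <- as.matrix(C)
  m <- nrow(C)
  n <- ncol(C)
  Chat <- apply(C, 2, normalize_l1)
  if (n == 2L) {
    f <- function(t) multinomial_nll(r, (1 - t) * Chat[, 1] + t * Chat[, 2])
    opt <- optimize(f, c(0, 1), tol = opt_tol)
    cand <- rbind(c(opt$minimum, f(opt$minimum)), c(0, f(0)), c(1, f(1)))
    bi <- which.min(cand[, 2])
    list(mu_internal = c(1 - cand[bi, 1], cand[bi, 1]), nll = cand[bi, 2])
  } else if (n == 3L) {
    a <- 1 / 3; b <- 1 / 2
    nll <- Inf
    for (it in 1:500) {
      fa <- function(t) {
        multinomial_nll(r, (1 - t) * ((1 - b) * Chat[, 1] + b * Chat[, 3]) +
                          t * Chat[, 2])
      }
      a <- line_min(fa, opt_tol)
      fb <- function(t) {
        multinomial_nll(r, (1 - t) * ((1 - a) * Chat[, 1] + a * Chat[, 2]) +
                          t * ((1 - a) * Chat[, 3] + a * Chat[, 2]))
      }
      b <- line_min(fb, opt_tol)
      new_nll <- fb(b)
      if (it > 1 && nll - new_nll < 1e-10) { nll <- min(nll, new_nll); break }
      nll <- new_nll
    }
    list(mu_internal = c((1 - a) * (1 - b), a, (1 - a) * b), nll = nll)
  } else {
    stop("n must be 2 or 3")
  }
}

line_min <- function(f, tol) {
  opt <- optimize(f, c(0, 1), tol = tol)
  cand <- c(opt$minimum, 0, 1)
  cand[which.min(c(opt$objective, f(0), f(1)))]
}
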