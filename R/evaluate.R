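#' Exact equality of interval count matrices up to tumor-column alignment
#'
#' Tumor columns are aligned canonically (by decreasing mixing fraction when
#' mixing vectors are supplied); if two tumor fractions tie within 1e-6 both
#' alignments are tried, because column labels are not identifiable.
#'
#' @param C_hat,C_true Interval count matrices of identical shape.
#' @param mu_hat,mu_true Optional mixing vectors used to canonicalize the
#'   tumor-column order of each matrix before comparing.
#' @return Logical scalar.
#' @export
exact_match <- function(C_hat, C_true, mu_hat = NULL, mu_true = NULL) {
  C_hat <- as.matrix(C_hat); C_true <- as.matrix(C_true)
  if (!all(dim(C_hat) == dim(C_true))) stop("matrices must have equal shape")
  if (!is.null(mu_hat)) C_hat <- canonicalize_solution(C_hat, mu_hat)$C
  if (!is.null(mu_true)) C_true <- canonicalize_solution(C_true, mu_true)$C
  if (all(C_hat == C_true)) return(TRUE)
  n <- ncol(C_hat)
  if (n == 3L) {
    tie_hat <- !is.null(mu_hat) && abs(mu_hat[2] - mu_hat[3]) <= 1e-6
    tie_true <- !is.null(mu_true) && abs(mu_true[2] - mu_true[3]) <= 1e-6
    if (tie_hat || tie_true || (is.null(mu_hat) && is.null(mu_true))) {
      return(all(C_hat[, c(1, 3, 2)] == C_true))
    }
  }
  FALSE
}

#' Average per-entry copy number error
#'
#' Euclidean (Frobenius) distance between the tumor columns of two interval
#' count matrices divided by the number of estimated entries `m * (n - 1)`.
#'
#' @inheritParams exact_match
#' @return Non-negative real; 0 iff the matrices match exactly.
#' @export
copy_number_error <- function(C_hat, C_true, mu_hat = NULL, mu_true = NULL) {
  C_hat <- as.matrix(C_hat); C_true <- as.matrix(C_true)
  if (!all(dim(C_hat) == dim(C_true))) stop("matrices must have equal shape")
  if (!is.null(mu_hat)) C_hat <- canonicalize_solution(C_hat, mu_hat)$C
  if (!is.null(mu_true)) C_true <- canonicalize_solution(C_true, mu_true)$C
  m <- nrow(C_hat); n <- ncol(C_hat)
  d <- sqrt(sum((C_hat[, -1, drop = FALSE] - C_true[, -1, drop = FALSE])^2))
  if (n == 3L) {
    d2 <- sqrt(sum((C_hat[, c(3, 2), drop = FALSE] -
                      C_true[, -1, drop = FALSE])^2))
    tie_hat <- !is.null(mu_hat) && abs(mu_hat[2] - mu_hat[3]) <= 1e-6
    tie_true <- !is.null(mu_true) && abs(mu_true[2] - mu_true[3]) <= 1e-6
    if (tie_hat || tie_true || (is.null(mu_hat) && is.null(mu_true))) {
      d <- min(d, d2)
    }
  }
  d / (m * (n - 1))
}

#' Absolute error in tumor purity
#'
#' The distance between true and inferred tumor purity `1 - mu[1]`; invariant
#' to how the tumor mass is split among clones.
#'
#' @param mu_hat,mu_true Genome mixing vectors on the unit simplex.
#' @return Non-negative real.
#' @export
purity_error <- function(mu_hat, mu_true) {
  abs((1 - mu_hat[1]) - (1 - mu_true[1]))
}

#' Pick a representative solution from a tie set
#'
#' Among equally likely solutions, selects the one maximizing the total
#' genomic length carried at copy number 2 in the tumor genomes (the expected
#' normal copy number), breaking ties by larger normal fraction and then by
#' canonical (lexicographic) column order.
#'
#' @param solutions Non-empty list of solutions, each a list with elements
#'   `C` and `mu` (as stored in a `mixture_fit`).
#' @param interval_lengths Positive interval lengths (bp).
#' @return The selected solution (list with `C`, `mu`, ...).
#' @export
select_representative <- function(solutions, interval_lengths) {
  solutions[[select_representative_index(solutions, interval_lengths)]]
}

select_representative_index <- function(solutions, interval_lengths) {
  if (length(solutions) == 0) stop("empty solution set")
  score <- purrr::map_dbl(solutions, function(s) {
    sum(interval_lengths * (s$C[, -1, drop = FALSE] == 2))
  })
  mu1 <- purrr::map_dbl(solutions, ~ .x$mu[1])
  key <- purrr::map_chr(solutions, ~ paste(.x$C, collapse = ","))
  order(-score, -mu1, key)[1]
}

#' Correct a read depth ratio for normal admixture
#'
#' Linear rescaling of a tumor/normal read depth ratio so that, after
#' removing the contribution of the admixed normal cells, a clonal copy
#' number `c` sits at ratio `c / 2` (peaks at multiples of 0.5).
#'
#' @param ratio Observed read depth ratio (diploid = 1).
#' @param normal_fraction Fraction of normal cells in the sample, in `[0, 1)`.
#' @return Corrected ratio.
#' @examples
#' corrected_ratio(0.64, 0.28) # clonal het deletion at purity 0.72 -> 0.5
#' @export
corrected_ratio <- function(ratio, normal_fraction) {
  if (any(normal_fraction < 0) || any(normal_fraction >= 1)) {
    stop("normal_fraction must be in [0, 1)")
  }
  (ratio - normal_fraction) / (1 - normal_fraction)
}

#' Expected read depth ratio of an aberration in a fraction of cells
#'
#' For an aberration with copy number `copy_number` carried by a fraction
#' `aberration_fraction` of the sample cells (the remainder diploid), the
#' expected ratio is `(1 - f) + f * c / 2`. The rest of the genome is assumed
#' diploid (no genome-length renormalization).
#'
#' @param copy_number Integer copy number of the aberration.
#' @param aberration_fraction Fraction of cells carrying it, in `[0, 1]`.
#' @return Expected read depth ratio.
#' @export
expected_ratio <- function(copy_number, aberration_fraction) {
  if (any(aberration_fraction < 0) || any(aberration_fraction > 1)) {
    stop("aberration_fraction must be in [0, 1]")
  }
  (1 - aberration_fraction) + aberration_fraction * copy_number / 2
}

# lower-median convention: for an even number of values take the smaller of
# the two central order statistics
lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Run the simulation benchmark
#'
#' For each row of the parameter grid, simulates `replicates` tumor/normal
#' samples, decomposes each, scores the representative solution against the
#' truth, and aggregates: percentage of exactly recovered count matrices,
#' (lower-)median copy number error, and median and mean purity error.
#'
#' @param grid Data frame with any of the columns `m`, `n`, `k`, `phi`
#'   (missing columns take the [sim_config()] defaults).
#' @param replicates Simulated datasets per grid row (default 20).
#' @param seed_base Integer; replicate `i` of grid row `g` uses seed
#'   `seed_base + 1000 * g + i`.
#' @param ... Further arguments passed to [decompose_mixture()].
#' @return A tibble with one row per grid cell: the grid parameters,
#'   `replicates`, `seed_base`, `pct_correct_C`, `median_cn_error`,
#'   `median_purity_error`, `mean_purity_error`.
#' @export
run_benchmark <- function(grid, replicates = 20, seed_base = 0, ...) {
  grid <- tibble::as_tibble(grid)
  defaults <- list(m = 39, n = 2, k = 3, phi = 0.03)
  for (nm in names(defaults)) {
    if (!nm %in% names(grid)) grid[[nm]] <- defaults[[nm]]
  }
  purrr::imap_dfr(split(grid, seq_len(nrow(grid))), function(row, g) {
    g <- as.integer(g)
    trials <- purrr::map_dfr(seq_len(replicates), function(i) {
      cfg <- sim_config(m = row$m, n = row$n, k = row$k, phi = row$phi)
      sim <- simulate_tumor_sample(cfg, seed = seed_base + 1000L * g + i)
      fit <- decompose_mixture(sim$counts, n = row$n, k = row$k, ...)
      sol <- fit$solutions[[fit$representative]]
      tibble::tibble(
        correct_C = exact_match(sol$C, sim$C, sol$mu, sim$mu),
        cn_error = copy_number_error(sol$C, sim$C, sol$mu, sim$mu),
        purity_err = purity_error(sol$mu, sim$mu))
    })
    tibble::tibble(
      m = row$m, n = row$n, k = row$k, phi = row$phi,
      replicates = replicates, seed_base = seed_base,
      pct_correct_C = 100 * mean(trials$correct_C),
      median_cn_error = lower_median(trials$cn_error),
      median_purity_error = lower_median(trials$purity_err),
      mean_purity_error = mean(trials$purity_err))
  })
}
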