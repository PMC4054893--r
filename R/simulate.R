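# Approximate hg19 non-acrocentric autosome arm table: chromosome length and
# centromere position (UCSC cytoband, rounded to 0.1 Mb). The five acrocentric
# autosomes (13, 14, 15, 21, 22) contribute only their q arm, giving the 39
# arms used as default simulation intervals.
hg19_autosomes <- function() {
  tibble::tribble(
    ~chromosome, ~length, ~centromere,
    "chr1", 249250621, 125000000,
    "chr2", 243199373, 93300000,
    "chr3", 198022430, 91000000,
    "chr4", 191154276, 50400000,
    "chr5", 180915260, 48400000,
    "chr6", 171115067, 61000000,
    "chr7", 159138663, 59900000,
    "chr8", 146364022, 45600000,
    "chr9", 141213431, 49000000,
    "chr10", 135534747, 40200000,
    "chr11", 135006516, 53700000,
    "chr12", 133851895, 35800000,
    "chr13", 115169878, 17900000,
    "chr14", 107349540, 17600000,
    "chr15", 102531392, 19000000,
    "chr16", 90354753, 36600000,
    "chr17", 81195210, 24000000,
    "chr18", 78077248, 17200000,
    "chr19", 59128983, 26500000,
    "chr20", 63025520, 27500000,
    "chr21", 48129895, 13200000,
    "chr22", 51304566, 14700000)
}

#' Non-acrocentric autosome arms (hg19, approximate)
#'
#' The 39 chromosome arms used as default simulation intervals: both arms of
#' the 17 metacentric/submetacentric autosomes plus the q arm of the five
#' acrocentric autosomes. Coordinates are approximate (centromere positions
#' rounded to 0.1 Mb) and 0-based half-open.
#'
#' @return A tibble with columns `id`, `chromosome`, `start`, `end`.
#' @export
autosome_arms <- function() {
  acro <- c("chr13", "chr14", "chr15", "chr21", "chr22")
  tab <- hg19_autosomes()
  purrr::pmap_dfr(tab, function(chromosome, length, centromere) {
    chrnum <- sub("chr", "", chromosome)
    q <- tibble::tibble(id = paste0(chrnum, "q"), chromosome = chromosome,
                        start = centromere, end = length)
    if (chromosome %in% acro) return(q)
    dplyr::bind_rows(
      tibble::tibble(id = paste0(chrnum, "p"), chromosome = chromosome,
                     start = 0, end = centromere),
      q)
  })
}

#' Chromosome-arm interval weights
#'
#' Lengths in bp of the 39 non-acrocentric autosome arms (see
#' [autosome_arms()]), used as the default interval weight vector for
#' simulations.
#'
#' @return Named numeric vector of length 39, all entries positive.
#' @export
arm_weights <- function() {
  arms <- autosome_arms()
  stats::setNames(arms$end - arms$start, arms$id)
}

#' Simulation configuration
#'
#' Bundles the parameters of the benchmark generator: random arm-level copy
#' numbers, a random mixing vector, and read depths with multiplicative
#' Gaussian noise whose coefficient of variation is the read depth
#' estimation error `phi`.
#'
#' @param m Number of intervals (default 39, the non-acrocentric autosome
#'   arms).
#' @param n Number of subpopulation genomes (2 or 3).
#' @param k Maximum copy number; tumor copy numbers are drawn uniformly from
#'   `{0, ..., k}`.
#' @param phi Read depth estimation error (coefficient of variation of the
#'   per-interval count noise); real data puts it around 0.01-0.04.
#' @param total_reads Expected total tumor read count (default 1e7).
#' @param purity_range Range `(low, high)` from which the normal fraction
#'   `mu[1]` is drawn uniformly.
#' @param min_clone_fraction For `n = 3`, the minimum fraction of the sample
#'   each tumor clone must occupy (default 0.05).
#' @param weights Positive interval weight vector of length `m` (interval
#'   lengths). Defaults to [arm_weights()] when `m == 39`, all ones
#'   otherwise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 39, n = 2, k = 3, phi = 0.03, total_reads = 1e7,
                       purity_range = c(0.1, 0.9),
                       min_clone_fraction = 0.05, weights = NULL) {
  if (phi < 0) stop("phi must be non-negative")
  if (!(purity_range[1] >= 0 && purity_range[1] < purity_range[2] &&
        purity_range[2] <= 1)) {
    stop("purity_range must satisfy 0 <= low < high <= 1")
  }
  if (n == 3 && 1 - purity_range[2] < 2 * min_clone_fraction - 1e-12) {
    stop("purity_range upper limit leaves no room for two clones")
  }
  if (is.null(weights)) {
    weights <- if (m == 39) unname(arm_weights()) else rep(1, m)
  }
  if (length(weights) != m || any(weights <= 0)) {
    stop("weights must be m positive values")
  }
  structure(list(m = as.integer(m), n = as.integer(n), k = as.integer(k),
                 phi = phi, total_reads = total_reads,
                 purity_range = purity_range,
                 min_clone_fraction = min_clone_fraction,
                 weights = weights),
            class = "sim_config")
}

#' Draw a random interval count matrix
#'
#' Column 1 is the all-2 normal genome; each tumor-column entry is drawn
#' i.i.d. uniformly from `{0, ..., k}`. For `n = 3` the two tumor columns are
#' redrawn until distinct.
#'
#' @param config A [sim_config()].
#' @return Integer matrix (m x n).
#' @export
simulate_count_matrix <- function(config) {
  m <- config$m; k <- config$k
  C <- matrix(2L, nrow = m, ncol = config$n)
  draw_column <- function() {
    repeat {
      x <- sample(0:k, m, replace = TRUE)
      if (sum(x) > 0) return(x)  # an empty (all-deleted) genome is degenerate
    }
  }
  C[, 2] <- draw_column()
  if (config$n == 3L) {
    repeat {
      C[, 3] <- draw_column()
      if (!identical(C[, 2], C[, 3])) break
    }
  }
  colnames(C) <- c("normal", paste0("tumor", seq_len(config$n - 1L)))
  C
}

#' Draw a random genome mixing vector
#'
#' The normal fraction `mu[1]` is uniform on `purity_range`; for `n = 3` the
#' remaining mass is split uniformly between the two clones subject to each
#' clone holding at least `min_clone_fraction` of the sample, and clones are
#' ordered by decreasing fraction.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of length `n` on the unit simplex.
#' @export
simulate_mixing <- function(config) {
  mu1 <- runif(1, config$purity_range[1], config$purity_range[2])
  if (config$n == 2L) return(c(mu1, 1 - mu1))
  lo <- config$min_clone_fraction
  mu2 <- runif(1, lo, max(lo, 1 - mu1 - lo))
  tum <- sort(c(mu2, 1 - mu1 - mu2), decreasing = TRUE)
  c(mu1, tum)
}

#' Simulate a tumor read depth vector for a mixture
#'
#' Expected counts are `total_reads` times the mixture multinomial parameter;
#' observed counts are the expectations perturbed by multiplicative Gaussian
#' noise with standard deviation `phi`, rounded, and truncated at zero.
#'
#' @param C Interval count matrix.
#' @param mu Genome mixing vector.
#' @param config A [sim_config()].
#' @return Integer-valued numeric vector of simulated tumor read counts.
#' @export
simulate_read_depth <- function(C, mu, config) {
  p <- mixture_parameter(C, mu, config$weights)
  e <- config$total_reads * p
  pmax(0, round(e * (1 + rnorm(config$m, 0, config$phi))))
}

#' Simulate a complete benchmark tumor/normal sample
#'
#' Draws a count matrix and mixing vector, simulates tumor read depths with
#' noise `phi`, and pairs them with noiseless matched-normal counts
#' proportional to the interval weights. Intervals are the autosome arms when
#' `m == 39`, otherwise synthetic intervals with lengths equal to the weight
#' vector (scaled to Mb).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return List with `counts` (interval tibble suitable for
#'   [decompose_mixture()]), the true `C` and `mu`, `config`, and `seed`.
#' @export
simulate_tumor_sample <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- simulate_count_matrix(config)
  mu <- simulate_mixing(config)
  r <- simulate_read_depth(C, mu, config)
  w_norm <- pmax(1, round(config$total_reads * normalize_l1(config$weights)))
  if (config$m == 39L && identical(unname(config$weights),
                                   unname(arm_weights()))) {
    arms <- autosome_arms()
  } else {
    len <- round(config$weights * 1e6 / mean(config$weights))
    arms <- tibble::tibble(id = sprintf("iv%02d", seq_len(config$m)),
                           chromosome = "sim1",
                           start = cumsum(c(0, head(len, -1))),
                           end = cumsum(len))
  }
  counts <- tibble::tibble(id = arms$id, chromosome = arms$chromosome,
                           start = arms$start, end = arms$end,
                           tumor_count = r, normal_count = w_norm)
  list(counts = counts, C = C, mu = mu, config = config, seed = seed)
}
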