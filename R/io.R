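#' Read a tab-delimited interval count file
#'
#' Expects a header and columns `id`, `chromosome`, `start`, `end`,
#' `tumor_count`, `normal_count` with 0-based half-open coordinates (BED
#' convention). Rows with zero normal coverage are dropped with a warning;
#' negative counts are an error.
#'
#' @param path Path to the file.
#' @return Interval tibble suitable for [decompose_mixture()].
#' @export
read_interval_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  counts <- readr::read_tsv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      chromosome = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double(),
      tumor_count = readr::col_double(),
      normal_count = readr::col_double()))
  probs <- readr::problems(counts)
  if (nrow(probs) > 0) {
    stop("malformed interval count file at line ", probs$row[1] + 1L)
  }
  if (nrow(counts) == 0) stop("empty interval count file")
  if (anyNA(counts)) {
    bad <- which(!stats::complete.cases(counts))[1]
    stop("malformed row at line ", bad + 1L)
  }
  if (any(counts$tumor_count < 0) || any(counts$normal_count < 0)) {
    stop("negative read count")
  }
  if (any(counts$end <= counts$start)) stop("interval with start >= end")
  drop <- counts$normal_count == 0
  if (any(drop)) {
    warning(sum(drop), " interval(s) with zero normal coverage skipped")
    counts <- counts[!drop, ]
  }
  counts
}

#' Write an interval count tibble to a tab-delimited file
#'
#' @param counts Interval tibble (see [read_interval_counts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_counts <- function(counts, path) {
  readr::write_tsv(counts[, c("id", "chromosome", "start", "end",
                              "tumor_count", "normal_count")], path)
  invisible(path)
}

#' Filter intervals by minimum length
#'
#' Keeps intervals strictly longer than `min_length` (default 50 kb),
#' focusing the decomposition on intervals whose read depth has low variance.
#' Order is preserved.
#'
#' @param counts Interval tibble.
#' @param min_length Length threshold in bp; intervals with
#'   `end - start > min_length` are kept.
#' @return Filtered interval tibble.
#' @export
filter_intervals <- function(counts, min_length = 50000) {
  if (min_length < 0) stop("min_length must be non-negative")
  out <- dplyr::filter(counts, .data$end - .data$start > min_length)
  if (nrow(out) == 0) stop("all intervals removed by the length filter")
  out
}

#' Infer copy number bounds from the modal read depth ratio
#'
#' Assumes most of the genome is not aberrant, so the mode of the per-interval
#' tumor/normal read depth ratio marks the diploid baseline. The mode is found
#' with a histogram (bin width `bin_width`) weighted by interval length;
#' intervals whose ratio falls within `mode_window` of the mode get tight
#' bounds around copy number 2 (`[2, 2]`, or `[1, 3]` with `relax = TRUE`),
#' intervals above get `[2, k]`, intervals below get `[0, 2]`.
#'
#' @param counts Interval tibble.
#' @param k Maximum copy number.
#' @param bin_width Histogram bin width on the ratio axis.
#' @param mode_window Half-width of the baseline window around the mode.
#' @param relax Use `[1, 3]` instead of `[2, 2]` for baseline intervals.
#' @return Bounds tibble with columns `id`, `lower`, `upper`.
#' @export
infer_baseline_bounds <- function(counts, k, bin_width = 0.05,
                                  mode_window = 0.1, relax = FALSE) {
  if (nrow(counts) < 2) stop("need at least two intervals")
  r <- counts$tumor_count
  w <- counts$normal_count
  len <- counts$end - counts$start
  ratio <- (r / sum(r)) / (w / sum(w))
  breaks <- seq(0, max(ratio) + bin_width, by = bin_width)
  bin <- findInterval(ratio, breaks, rightmost.closed = TRUE)
  bw <- tapply(len, bin, sum)
  if (length(unique(round(bw, 9))) == 1L && length(bw) > 1L) {
    warning("no modal ratio bin; falling back to the weighted median ratio")
    ord <- order(ratio)
    cum <- cumsum(len[ord]) / sum(len)
    mode_ratio <- ratio[ord][which(cum >= 0.5)[1]]
  } else {
    top <- as.integer(names(bw)[which.max(bw)])
    mode_ratio <- breaks[top] + bin_width / 2
  }
  base <- abs(ratio - mode_ratio) <= mode_window
  lower <- ifelse(base, if (relax) 1L else 2L,
                  ifelse(ratio > mode_ratio, 2L, 0L))
  upper <- ifelse(base, if (relax) 3L else 2L,
                  ifelse(ratio > mode_ratio, as.integer(k), 2L))
  tibble::tibble(id = counts$id, lower = as.integer(lower),
                 upper = as.integer(pmin(upper, k)))
}

#' Read a tab-delimited bounds file
#'
#' Columns `id`, `lower`, `upper`; overrides inferred bounds per interval.
#'
#' @param path Path to the file.
#' @return Bounds tibble.
#' @export
read_bounds <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    lower = readr::col_integer(),
    upper = readr::col_integer()))
}

#' Write the tie set of a fit to a tab-delimited solutions file
#'
#' One row per solution: the negative log-likelihood, the mixing vector
#' (comma-joined), and the tumor copy numbers (per interval, colon-joined
#' across tumor genomes, comma-joined across intervals).
#'
#' @param fit A `mixture_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solutions <- function(fit, path) {
  rows <- purrr::map_dfr(fit$solutions, function(s) {
    tum <- s$C[, -1, drop = FALSE]
    tibble::tibble(
      nll = s$nll,
      mu = paste(format(s$mu, digits = 12, trim = TRUE), collapse = ","),
      C = paste(apply(tum, 1, paste, collapse = ":"), collapse = ","))
  })
  readr::write_tsv(rows, path)
  invisible(path)
}

#' Read a solutions file back into (C, mu) form
#'
#' @param path Path written by [write_solutions()].
#' @return List of solutions, each with elements `C` (including the normal
#'   column), `mu`, and the stored `nll`.
#' @export
read_solutions <- function(path) {
  rows <- readr::read_tsv(path, col_types = readr::cols(
    nll = readr::col_double(),
    mu = readr::col_character(),
    C = readr::col_character()))
  purrr::pmap(rows, function(nll, mu, C) {
    muv <- as.numeric(strsplit(mu, ",", fixed = TRUE)[[1]])
    tum <- do.call(rbind, lapply(strsplit(C, ",", fixed = TRUE)[[1]],
                                 function(x) {
                                   as.integer(strsplit(x, ":",
                                                       fixed = TRUE)[[1]])
                                 }))
    list(C = cbind(normal = rep(2L, nrow(tum)), tum), mu = muv, nll = nll)
  })
}

#' Re-score a solution against an interval count table
#'
#' Computes the negative log-likelihood that [decompose_mixture()] ranks
#' solutions by: the multinomial nll of the inverse-weight-transformed tumor
#' counts under the normalized mixture `C mu`.
#'
#' @param counts Interval tibble.
#' @param C Interval count matrix (with normal column).
#' @param mu Genome mixing vector.
#' @return The negative log-likelihood (constant dropped).
#' @export
score_solution <- function(counts, C, mu) {
  r_trans <- inverse_weight_transform(counts$tumor_count,
                                      counts$normal_count)
  multinomial_nll(r_trans, normalize_l1(as.vector(as.matrix(C) %*% mu)))
}
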