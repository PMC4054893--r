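#' @export
print.mixture_fit <- function(x, ...) {
  rep_sol <- x$solutions[[x$representative]]
  cat("Mixture decomposition (", x$n - 1L,
      if (x$n == 2L) " tumor population + normal)\n"
      else " tumor subpopulations + normal)\n", sep = "")
  cat("  intervals:", x$m, " max copy number:", x$k, "\n")
  cat("  candidate matrices:", format(x$candidates, big.mark = ","),
      " tie-set size:", length(x$solutions), "\n")
  cat("  optimal nll:", format(x$best_nll, digits = 10), "\n")
  cat("  representative solution: normal fraction ",
      sprintf("%.3f", rep_sol$mu[1]), ", tumor purity ",
      sprintf("%.3f", 1 - rep_sol$mu[1]), "\n", sep = "")
  invisible(x)
}

#' Tidy the solutions of a mixture decomposition
#'
#' Returns one row per interval, per tumor genome, per tie-set solution, with
#' the inferred integer copy number and the mixing fraction of that genome.
#'
#' @param x A `mixture_fit` from [decompose_mixture()].
#' @param ... Unused.
#' @return A tibble with columns `solution`, `id`, `chromosome`, `start`,
#'   `end`, `genome`, `mixing_fraction`, `copy_number`, `nll`, and
#'   `representative` (logical).
#' @export
tidy.mixture_fit <- function(x, ...) {
  purrr::imap_dfr(x$solutions, function(s, i) {
    n <- ncol(s$C)
    purrr::map_dfr(2:n, function(h) {
      tibble::tibble(
        solution = i,
        id = x$counts$id,
        chromosome = x$counts$chromosome,
        start = x$counts$start,
        end = x$counts$end,
        genome = paste0("tumor", h - 1L),
        mixing_fraction = s$mu[h],
        copy_number = s$C[, h],
        nll = s$nll,
        representative = i == x$representative)
    })
  })
}

#' One-row summary of a mixture decomposition
#'
#' @param x A `mixture_fit` from [decompose_mixture()].
#' @param ... Unused.
#' @return A tibble with the model size, optimum, tie-set size, and the
#'   representative solution's normal fraction and tumor purity.
#' @export
glance.mixture_fit <- function(x, ...) {
  s <- x$solutions[[x$representative]]
  tibble::tibble(
    n = x$n, k = x$k, m = x$m,
    nll = x$best_nll,
    loglik = -x$best_nll,
    n_solutions = length(x$solutions),
    candidates = x$candidates,
    normal_fraction = s$mu[1],
    purity = 1 - s$mu[1],
    total_reads = x$total_reads,
    elapsed = x$elapsed)
}

#' Plot observed read-depth ratios against the fitted mixture
#'
#' Shows the per-interval tumor/normal read depth ratio (scaled so the
#' diploid state sits at 1) and overlays the representative solution's
#' integer copy numbers mapped to their expected ratios given the inferred
#' mixing fractions.
#'
#' @param object A `mixture_fit` from [decompose_mixture()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_fit <- function(object, ...) {
  cts <- object$counts
  ratio <- (cts$tumor_count / sum(cts$tumor_count)) /
    (cts$normal_count / sum(cts$normal_count))
  s <- object$solutions[[object$representative]]
  expected <- as.vector(s$C %*% s$mu) / 2
  df <- tibble::tibble(index = seq_len(nrow(cts)),
                       chromosome = cts$chromosome,
                       observed = ratio, fitted = expected)
  long <- tidyr::pivot_longer(df, c("observed", "fitted"),
                              names_to = "series", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$ratio,
                                     colour = .data$series,
                                     shape = .data$series)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "interval", y = "read depth ratio (diploid = 1)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
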