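#' Normalize a non-negative vector to unit L1 norm
#'
#' @param v Numeric vector with non-negative entries, at least one positive.
#' @return Numeric vector proportional to `v` summing to 1.
#' @examples
#' normalize_l1(c(1, 3))
#' @export
normalize_l1 <- function(v) {
  stopifnot(is.numeric(v))
  if (any(v < 0)) stop("negative entries in vector to normalize")
  s <- sum(v)
  if (s <= 0) stop("degenerate vector: all entries are zero")
  v / s
}

#' Test whether two vectors have compatible order
#'
#' Two vectors `a`, `b` have compatible order when no pair of positions is
#' strictly increasing in one and strictly decreasing in the other, i.e.
#' `a[i] < a[j]` implies `b[i] <= b[j]`. Exact ties in either vector impose
#' no constraint, so a constant vector is compatible with every vector.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Logical scalar.
#' @examples
#' compatible_order(c(1, 2, 3), c(0, 0, 2))
#' compatible_order(c(1, 2, 3), c(1, 0, 2))
#' @export
compatible_order <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  ord <- order(a)
  a <- a[ord]
  b <- b[ord]
  # after sorting by a, any strict increase in a must not see a drop in b
  # relative to the running maximum over strictly smaller a values
  run_max <- -Inf
  i <- 1L
  m <- length(a)
  while (i <= m) {
    j <- i
    while (j < m && a[j + 1L] == a[i]) j <- j + 1L
    if (min(b[i:j]) < run_max) return(FALSE)
    run_max <- max(run_max, b[i:j])
    i <- j + 1L
  }
  TRUE
}

#' Map a genome mixing vector to its internal (normalized-column) coordinates
#'
#' For a fixed interval count matrix `C` the multinomial parameter satisfies
#' `normalize(C mu) = Chat mu'` where `Chat` has L1-normalized columns and
#' `mu'_h = mu_h * ||c_h||_1 / sum_j mu_j * ||c_j||_1`. Optimization is done
#' in the `mu'` coordinates; [internal_to_mu()] inverts the map.
#'
#' @param C Integer matrix (m x n), column 1 the all-2 normal genome.
#' @param mu Genome mixing vector on the unit simplex.
#' @return Internal mixing vector `mu'` on the unit simplex.
#' @export
mu_to_internal <- function(C, mu) {
  norms <- unname(colSums(C))
  if (any(norms == 0 & mu > 0)) stop("zero column with positive mixing mass")
  normalize_l1(mu * norms)
}

#' Map internal mixing coordinates back to the genome mixing vector
#'
#' Inverse of [mu_to_internal()]: `mu_h` is proportional to
#' `mu'_h / ||c_h||_1`, renormalized to the simplex.
#'
#' @param C Integer matrix (m x n).
#' @param mu_internal Internal mixing vector on the unit simplex.
#' @return Genome mixing vector on the unit simplex.
#' @export
internal_to_mu <- function(C, mu_internal) {
  norms <- unname(colSums(C))
  x <- ifelse(mu_internal > 0, mu_internal / norms, 0)
  normalize_l1(x)
}

# Order tumor columns by decreasing mixing fraction; among equal fractions,
# lexicographic column order. Returns list(C, mu).
canonicalize_solution <- function(C, mu) {
  n <- ncol(C)
  if (n <= 2L) return(list(C = C, mu = mu))
  tum <- 2:n
  key <- order(-mu[tum],
               apply(C[, tum, drop = FALSE], 2, paste, collapse = ","))
  list(C = cbind(C[, 1L, drop = FALSE], C[, tum, drop = FALSE][, key]),
       mu = c(mu[1L], mu[tum][key]))
}
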