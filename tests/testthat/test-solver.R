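# Reference solver: materialize every in-bounds tumor column, optimize the
# mixing fraction for each with the R-side optimizer, return the minimum nll.
reference_min_nll_n2 <- function(r_trans, k, bounds = NULL) {
  m <- length(r_trans)
  lo <- if (is.null(bounds)) rep(0L, m) else bounds$lower
  hi <- if (is.null(bounds)) rep(as.integer(k), m) else bounds$upper
  grid <- do.call(expand.grid, lapply(seq_len(m), function(j) lo[j]:hi[j]))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    c2 <- as.integer(grid[i, ])
    C <- cbind(rep(2L, m), c2)
    if (sum(c2) == 0) {
      nll <- multinomial_nll(r_trans, rep(1 / m, m))
    } else {
      nll <- optimize_mu_for_C(C, r_trans)$nll
    }
    best <- min(best, nll)
  }
  best
}

make_counts <- function(tumor, normal = rep(1000, length(tumor))) {
  m <- length(tumor)
  tibble::tibble(id = sprintf("iv%02d", 1:m), chromosome = "sim1",
                 start = (0:(m - 1)) * 1e6, end = (1:m) * 1e6,
                 tumor_count = tumor, normal_count = normal)
}

test_that("order-restricted solve equals exhaustive reference on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    m <- sample(3:5, 1)
    k <- 2
    r <- as.numeric(sample(50:500, m))
    counts <- make_counts(r)
    fit <- decompose_mixture(counts, n = 2, k = k)
    ref <- reference_min_nll_n2(inverse_weight_transform(r, counts$normal_count), k)
    expect_equal(fit$best_nll, ref, tolerance = 1e-8)
  }
})

test_that("pruned and unpruned enumeration attain the same optimum", {
  set.seed(55)
  r <- as.numeric(sample(100:900, 5))
  counts <- make_counts(r)
  fit_p <- decompose_mixture(counts, n = 2, k = 3, order_pruning = TRUE)
  fit_e <- decompose_mixture(counts, n = 2, k = 3, order_pruning = FALSE)
  expect_equal(fit_p$best_nll, fit_e$best_nll, tolerance = 1e-9)
  expect_lt(fit_p$candidates, fit_e$candidates)
  expect_equal(fit_e$candidates, 4^5)
})

test_that("per-interval bounds are respected and infeasible bounds error", {
  r <- c(100, 400, 800)
  counts <- make_counts(r)
  bounds <- tibble::tibble(id = counts$id, lower = c(2L, 2L, 2L),
                           upper = c(2L, 3L, 3L))
  fit <- decompose_mixture(counts, n = 2, k = 3, bounds = bounds)
  for (s in fit$solutions) {
    expect_true(all(s$C[, 2] >= bounds$lower & s$C[, 2] <= bounds$upper))
  }
  bad <- tibble::tibble(id = counts$id, lower = c(0L, 3L, 0L),
                        upper = c(3L, 2L, 3L))
  expect_error(decompose_mixture(counts, n = 2, k = 3, bounds = bad),
               "infeasible")
})

test_that("tie sets survive a new best arriving (self-move regression)", {
  # This exact draw once crashed the solver: compacting the tie set after a
  # new best self-move-assigned surviving payloads, emptying their copy
  # vectors. The fit must return intact solutions with consistent nll.
  sim <- simulate_tumor_sample(sim_config(m = 8, n = 3, k = 3, phi = 0.02),
                               seed = 6)
  b <- suppressWarnings(infer_baseline_bounds(sim$counts, 3, relax = TRUE))
  fit <- decompose_mixture(sim$counts, n = 2, k = 3, bounds = b)
  for (s in fit$solutions) {
    expect_equal(dim(s$C), c(8L, 2L))
    expect_equal(score_solution(sim$counts, s$C, s$mu), s$nll,
                 tolerance = 1e-6)
  }
})

test_that("exact ties are all returned: symmetric two-interval instance", {
  # r proportional to (1, 3) with k = 3: tumor columns (0,1)*a and any
  # scalar multiple give identical mixture parameters, so several candidates
  # tie at the optimum; each returned solution must reproduce the same nll.
  counts <- make_counts(c(1000, 3000))
  fit <- decompose_mixture(counts, n = 2, k = 3, tie_tol = 1e-9)
  expect_gt(length(fit$solutions), 1)
  nlls <- vapply(fit$solutions, function(s) s$nll, numeric(1))
  expect_lt(max(nlls) - min(nlls), 1e-9 + 1e-12)
})

test_that("n = 3 solve matches a brute-force search on a tiny instance", {
  set.seed(9)
  sim <- simulate_tumor_sample(sim_config(m = 4, n = 3, k = 2, phi = 0),
                               seed = 12)
  fit <- decompose_mixture(sim$counts, n = 3, k = 2)
  r_trans <- inverse_weight_transform(sim$counts$tumor_count,
                                      sim$counts$normal_count)
  # brute force over all unordered pairs of tumor columns
  grid <- as.matrix(expand.grid(rep(list(0:2), 4)))
  grid <- grid[rowSums(grid) > 0, ]
  best <- Inf
  for (a in seq_len(nrow(grid))) {
    for (b in a:nrow(grid)) {
      C <- cbind(rep(2L, 4), grid[a, ], grid[b, ])
      best <- min(best, optimize_mu_for_C(C, r_trans)$nll)
    }
  }
  expect_equal(fit$best_nll, best, tolerance = 1e-6)
})

test_that("candidate counting matches materialized enumeration", {
  set.seed(21)
  r <- as.numeric(sample(100:999, 6))
  cols <- enumerate_tumor_columns(r, 2)
  expect_equal(count_tumor_columns(r, 2), nrow(cols))
  # every enumerated column is order-compatible, and none is duplicated
  expect_true(all(apply(cols, 1, function(b) compatible_order(r, b))))
  expect_equal(anyDuplicated(cols), 0L)
})

test_that("expected_ploidy rescales bounds outward and clamps", {
  b <- tibble::tibble(id = c("a", "b"), lower = c(1L, 2L), upper = c(2L, 3L))
  out <- apply_ploidy_rescaling(b, expected_ploidy = 3, k = 4)
  expect_equal(out$lower, c(1L, 3L))
  expect_equal(out$upper, c(3L, 4L))  # ceiling(4.5) clamped to k
  expect_error(apply_ploidy_rescaling(b, -1, k = 4), "positive")
})

test_that("decompose_mixture validates its input", {
  counts <- make_counts(c(100, 200, 300))
  expect_error(decompose_mixture(counts, n = 4), "n must be 2 or 3")
  expect_error(decompose_mixture(counts, n = 2, k = 1), "at least 2")
  expect_error(decompose_mixture(counts[, -5], n = 2), "missing columns")
  bad <- counts; bad$normal_count[2] <- 0
  expect_error(decompose_mixture(bad, n = 2), "zero normal coverage")
})

test_that("fit methods: tidy, glance, autoplot and print are consistent", {
  sim <- simulate_tumor_sample(sim_config(m = 6, n = 2, k = 2, phi = 0.01),
                               seed = 3)
  fit <- decompose_mixture(sim$counts, n = 2, k = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$genome), "tumor1")
  expect_equal(nrow(td), length(fit$solutions) * fit$m * (fit$n - 1))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$nll, fit$best_nll)
  expect_equal(gl$normal_fraction + gl$purity, 1)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Mixture decomposition")
})
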