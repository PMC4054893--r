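test_that("autosome arm table has 39 arms with positive lengths", {
  arms <- autosome_arms()
  expect_equal(nrow(arms), 39)
  expect_true(all(arms$end > arms$start))
  w <- arm_weights()
  expect_length(w, 39)
  expect_true(all(w > 0))
  # acrocentric autosomes contribute no p arm
  expect_false(any(c("13p", "14p", "15p", "21p", "22p") %in% names(w)))
})

test_that("sim_config validates its arguments", {
  expect_error(sim_config(phi = -0.1), "non-negative")
  expect_error(sim_config(purity_range = c(0.5, 0.2)), "purity_range")
  expect_error(sim_config(n = 3, purity_range = c(0.1, 0.95),
                          min_clone_fraction = 0.2), "no room")
  expect_error(sim_config(m = 5, weights = c(1, 2)), "m positive values")
  # the boundary case high purity + exactly-fitting clones is allowed
  expect_s3_class(sim_config(n = 3, purity_range = c(0.1, 0.9),
                             min_clone_fraction = 0.05), "sim_config")
})

test_that("simulate_tumor_sample is reproducible under a seed", {
  a <- simulate_tumor_sample(sim_config(m = 10, k = 3, phi = 0.02), seed = 5)
  b <- simulate_tumor_sample(sim_config(m = 10, k = 3, phi = 0.02), seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$C, b$C)
  expect_identical(a$mu, b$mu)
})

test_that("simulated structure respects the configuration", {
  set.seed(1)
  for (rep in 1:20) {
    cfg <- sim_config(m = 12, n = 3, k = 2, phi = 0.01)
    sim <- simulate_tumor_sample(cfg)
    expect_equal(dim(sim$C), c(12L, 3L))
    expect_true(all(sim$C[, 1] == 2))
    expect_true(all(sim$C[, -1] %in% 0:2))
    # no empty tumor genome, tumor columns distinct
    expect_true(all(colSums(sim$C[, -1]) > 0))
    expect_false(identical(sim$C[, 2], sim$C[, 3]))
    expect_equal(sum(sim$mu), 1)
    expect_gte(sim$mu[1], cfg$purity_range[1])
    expect_lte(sim$mu[1], cfg$purity_range[2])
    expect_true(all(sim$mu[-1] >= cfg$min_clone_fraction - 1e-9))
    # clones ordered by decreasing fraction
    expect_gte(sim$mu[2], sim$mu[3])
    expect_true(all(sim$counts$normal_count >= 1))
  }
})

test_that("phi = 0 gives exactly rounded expected counts", {
  cfg <- sim_config(m = 8, n = 2, k = 3, phi = 0)
  sim <- simulate_tumor_sample(cfg, seed = 2)
  e <- cfg$total_reads * mixture_parameter(sim$C, sim$mu, cfg$weights)
  expect_equal(sim$counts$tumor_count, round(e))
})

test_that("the default m = 39 simulation uses the arm intervals and weights", {
  sim <- simulate_tumor_sample(sim_config(phi = 0.01), seed = 1)
  expect_identical(sim$counts$id, autosome_arms()$id)
  expect_equal(sim$counts$end - sim$counts$start, unname(arm_weights()))
})
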