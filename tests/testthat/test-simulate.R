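test_that("same seed yields a bit-identical table", {
  a <- simulate_descriptor_table(m = 40, n_descriptors = 8, seed = 5)
  b <- simulate_descriptor_table(m = 40, n_descriptors = 8, seed = 5)
  expect_identical(descriptor_matrix(a), descriptor_matrix(b))
  expect_identical(activity_values(a), activity_values(b))
  c <- simulate_descriptor_table(m = 40, n_descriptors = 8, seed = 6)
  expect_false(identical(activity_values(a), activity_values(c)))
})

test_that("noiseless linear link is exactly linear in the active columns", {
  tbl <- simulate_descriptor_table(m = 50, n_descriptors = 6, block_size = 1,
                                   rho = 0, active = c(2, 5), noise_sd = 0,
                                   mixed_scales = FALSE, seed = 11)
  truth <- simulation_truth(tbl)
  fit <- lm(activity_values(tbl) ~
              descriptor_matrix(tbl)[, truth$active] - 1)
  expect_lt(sum(residuals(fit)^2), 1e-16)
  expect_equal(unname(coef(fit)), unname(truth$coef), tolerance = 1e-10)
})

test_that("within-block correlation matches the requested rho", {
  tbl <- simulate_descriptor_table(m = 2000, n_descriptors = 9,
                                   block_size = 3, rho = 0.9,
                                   noise_sd = 0, mixed_scales = FALSE,
                                   seed = 3)
  C <- cor(descriptor_matrix(tbl))
  within <- c(C[1, 2], C[1, 3], C[2, 3], C[4, 5], C[7, 8])
  across <- c(C[1, 4], C[2, 7], C[5, 9])
  expect_true(all(abs(within - 0.9) < 0.05))
  expect_true(all(abs(across) < 0.1))
})

test_that("planted dense outlier deviates by the requested local multiple", {
  tbl <- simulate_descriptor_table(m = 120, n_descriptors = 4,
                                   block_size = 1, rho = 0,
                                   active = 1:2, noise_sd = 0.3,
                                   n_outliers = 1, outlier_sigma = 6,
                                   mixed_scales = FALSE, seed = 8)
  truth <- simulation_truth(tbl)
  expect_length(truth$outlier_ids, 1)
  # recompute the deviation in the generated neighborhood
  M <- scale(descriptor_matrix(tbl))
  D <- as.matrix(dist(M))
  r <- quantile(D[upper.tri(D)], 0.1)
  i <- match(truth$outlier_ids, compound_ids(tbl))
  nbr <- setdiff(which(D[i, ] <= r), i)
  expect_gt(length(nbr), 10)
  y <- activity_values(tbl)
  dev_mult <- abs(y[i] - mean(y[nbr])) / sd(y[nbr])
  expect_gt(dev_mult, 6 * 0.9 * 0.8)  # within range despite the outlier
                                      # inflating its own neighborhood sd
})

test_that("sparse-flag outliers end up with few neighbors", {
  tbl <- simulate_descriptor_table(m = 60, n_descriptors = 4,
                                   block_size = 1, rho = 0,
                                   n_outliers = 1, outlier_sigma = 6,
                                   outlier_dense = FALSE,
                                   mixed_scales = FALSE, seed = 9)
  truth <- simulation_truth(tbl)
  M <- scale(descriptor_matrix(tbl))
  D <- as.matrix(dist(M))
  r <- quantile(D[upper.tri(D)], 0.1)
  i <- match(truth$outlier_ids, compound_ids(tbl))
  expect_lte(sum(D[i, -i] <= r), 5)
})

test_that("mixed scales rescale every third column", {
  tbl <- simulate_descriptor_table(m = 100, n_descriptors = 6,
                                   mixed_scales = TRUE, seed = 2)
  sds <- apply(descriptor_matrix(tbl), 2, sd)
  expect_true(all(sds[c(3, 6)] > 100))
  expect_true(all(sds[c(1, 2, 4, 5)] < 100))
})
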