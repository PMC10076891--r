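uniform_table <- function(m = 100, d = 5, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(runif(m * d), m, d)
    out <- tibble::tibble(compound_id = sprintf("p%03d", seq_len(m)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(M)))
    out$activity <- withr::with_seed(seed + 1, rnorm(m))
    descriptor_table(out, activity = "activity")
  })
}

test_that("achieved fraction is near target and the sphere invariant holds", {
  for (s in 1:3) {
    tbl <- uniform_table(m = 100, d = 5, seed = s)
    sp <- quiet(sphere_exclusion_split(tbl, test_fraction = 0.2))
    frac <- length(sp$test_ids) / 100
    expect_lte(abs(frac - 0.2), 0.05)
    # partition
    expect_setequal(c(sp$train_ids, sp$test_ids), compound_ids(tbl))
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    # every test compound within radius of >= 1 training compound
    M <- descriptor_matrix(tbl)
    for (id in sp$test_ids) {
      d_min <- min(sqrt(colSums(
        (t(M[sp$train_ids, , drop = FALSE]) - M[id, ])^2)))
      expect_lte(d_min, sp$radius + 1e-12)
    }
  }
})

test_that("splitting is deterministic and seeded by the top-activity compound", {
  tbl <- uniform_table(seed = 9)
  a <- quiet(sphere_exclusion_split(tbl, 0.25))
  b <- quiet(sphere_exclusion_split(tbl, 0.25))
  expect_identical(a, b)
  expect_identical(a$seed_compound,
                   compound_ids(tbl)[which.max(activity_values(tbl))])
  expect_true(a$seed_compound %in% a$train_ids)
})

test_that("two identical points split 1/1 for any positive radius", {
  tbl <- descriptor_table(
    tibble::tibble(compound_id = c("a", "b", "c", "d", "e"),
                   d1 = c(1, 1, 5, 9, 13), d2 = c(2, 2, 6, 10, 14),
                   activity = c(5, 4, 3, 2, 1)),
    activity = "activity")
  sp <- quiet(sphere_exclusion_split(tbl, test_fraction = 0.2))
  # "a" and "b" coincide; exactly one of them must be test
  expect_equal(sum(c("a", "b") %in% sp$test_ids), 1)
})

test_that("tiny radius sends every compound to training", {
  tbl <- uniform_table(m = 20, d = 3, seed = 2)
  # target far below 1/m forces the bisection toward radius ~ 0
  sp <- quiet(sphere_exclusion_split(tbl, test_fraction = 0.001))
  expect_length(sp$test_ids, 0)
  expect_length(sp$train_ids, 20)
})

test_that("re-splitting after column changes is valid in the new space", {
  tbl <- uniform_table(m = 60, d = 6, seed = 3)
  sp_full <- quiet(sphere_exclusion_split(tbl, 0.2))
  sub <- qsardnn:::restrict_table(tbl, descriptors = c("V1", "V2"))
  sp_sub <- quiet(sphere_exclusion_split(sub, 0.2))
  expect_false(identical(sp_full$test_ids, sp_sub$test_ids) &&
                 identical(sp_full$radius, sp_sub$radius))
  M <- descriptor_matrix(sub)
  for (id in sp_sub$test_ids) {
    d_min <- min(sqrt(colSums(
      (t(M[sp_sub$train_ids, , drop = FALSE]) - M[id, ])^2)))
    expect_lte(d_min, sp_sub$radius + 1e-12)
  }
})

test_that("minimum size is enforced and tidy() labels the partition", {
  small <- descriptor_table(
    tibble::tibble(compound_id = c("a", "b", "c"),
                   d1 = 1:3, activity = 1:3), activity = "activity")
  expect_error(sphere_exclusion_split(small),
               class = "qsardnn_validation_error")
  tbl <- uniform_table(m = 30, d = 2, seed = 4)
  sp <- quiet(sphere_exclusion_split(tbl, 0.3))
  td <- tidy(sp)
  expect_equal(nrow(td), 30)
  expect_setequal(unique(td$set), c("train", "test"))
})
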