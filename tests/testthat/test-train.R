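linear_data <- function(m = 60, d = 4, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(m * d), m, d)
    w <- runif(d, 0.5, 1.5)
    y <- drop(X %*% w) + rnorm(m, sd = noise)
    list(X = X, y = y)
  })
}

test_that("max_epochs = 1 runs exactly one epoch; patience boundary holds", {
  d <- linear_data(seed = 2)
  net <- dnn_init(c(4, 6, 1), seed = 2)
  fit <- dnn_train(net, d$X, d$y, d$X, d$y, max_epochs = 1,
                   eval_interval = 1, patience = 0, dropout = 0, seed = 2)
  expect_equal(fit$state$epochs_run, 1)
  # patience 0 never stops before the first evaluation
  expect_gte(fit$state$best_epoch, 1)
})

test_that("returned snapshot reproduces the minimum recorded eval cost", {
  d <- linear_data(m = 80, seed = 3, noise = 0.5)
  eval_d <- linear_data(m = 30, seed = 4, noise = 0.5)
  net <- dnn_init(c(4, 8, 1), seed = 3)
  fit <- dnn_train(net, d$X, d$y, eval_d$X, eval_d$y, max_epochs = 150,
                   dropout = 0.2, seed = 3)
  st <- fit$state
  expect_equal(st$best_eval_cost, min(st$cost_eval))
  re_eval <- dnn_cost(fit$net, eval_d$X, eval_d$y, lambda = 1e-4)$total
  expect_identical(re_eval, st$best_eval_cost)
})

test_that("dropout 0 trajectory is bit-identical to the no-dropout path", {
  d <- linear_data(seed = 5)
  eval_d <- linear_data(m = 20, seed = 6)
  net <- dnn_init(c(4, 6, 1), seed = 5)
  f1 <- dnn_train(net, d$X, d$y, eval_d$X, eval_d$y, max_epochs = 40,
                  dropout = 0, seed = 5)
  f2 <- dnn_train(net, d$X, d$y, eval_d$X, eval_d$y, max_epochs = 40,
                  dropout = 0, seed = 5)
  expect_identical(f1$state$cost_train, f2$state$cost_train)
  expect_identical(f1$net, f2$net)
  # nonzero dropout with the same seed genuinely changes the trajectory
  f3 <- dnn_train(net, d$X, d$y, eval_d$X, eval_d$y, max_epochs = 40,
                  dropout = 0.3, seed = 5)
  expect_false(identical(f1$state$cost_train, f3$state$cost_train))
})

test_that("full-batch descent on a linear net is monotone on a convex toy", {
  # linear activations: replace tanh by keeping the pre-activation tiny --
  # instead use a [d, 1] net (no hidden layer), which is exactly linear
  d <- linear_data(m = 50, d = 3, seed = 7)
  net <- dnn_init(c(3, 1), use_bias = FALSE, seed = 7)
  fit <- dnn_train(net, d$X, d$y, NULL, NULL, learning_rate = 0.5,
                   batch_size = 50, max_epochs = 100, dropout = 0,
                   lambda = 0, seed = 7, anneal = 1)
  expect_true(all(diff(fit$state$cost_train) <= 1e-12))
})

test_that("stronger weight decay does not inflate the weight norm", {
  norms <- vapply(c(0, 0.05), function(lam) {
    total <- 0
    for (s in 1:10) {
      d <- linear_data(m = 40, seed = 20 + s, noise = 0.3)
      net <- dnn_init(c(4, 6, 1), seed = 20 + s)
      fit <- dnn_train(net, d$X, d$y, NULL, NULL, max_epochs = 60,
                       dropout = 0, lambda = lam, seed = 20 + s)
      total <- total + sum(vapply(fit$net$weights,
                                  function(w) sum(w^2), 1))
    }
    total / 10
  }, numeric(1))
  expect_lte(norms[2], norms[1])
})

test_that("training on noiseless linear data reaches q2 ~ 1 (small net)", {
  d <- linear_data(m = 120, d = 4, seed = 8)
  net <- dnn_init(c(4, 10, 1), seed = 8)
  fit <- dnn_train(net, d$X, d$y, d$X[1:30, ], d$y[1:30],
                   max_epochs = 400, dropout = 0, seed = 8)
  h <- dnn_forward(fit$net, d$X)
  expect_gte(q_squared(d$y, h), 0.98)
})

test_that("constant training activity is rejected", {
  d <- linear_data(seed = 9)
  net <- dnn_init(c(4, 6, 1), seed = 9)
  expect_error(dnn_train(net, d$X, rep(1, nrow(d$X))),
               class = "qsardnn_validation_error")
})

test_that("train_qsar assembles a scored model and predicts consistently", {
  tbl <- simulate_descriptor_table(m = 80, n_descriptors = 5, rho = 0,
                                   block_size = 1, active = 1:3,
                                   noise_sd = 0.1, mixed_scales = FALSE,
                                   seed = 12)
  fit <- quiet(train_qsar(tbl, config = small_train_config(seed = 12)))
  g <- glance(fit)
  expect_equal(g$n_train + g$n_test, 80)
  expect_lte(g$q2_train, 1)
  # predicting the training rows reproduces the stored training q2
  preds <- predict(fit, tbl)
  expect_equal(nrow(preds), 80)
  tr_rows <- match(fit$train_ids, preds$compound_id)
  expect_equal(q_squared(fit$train_activity, preds$.pred[tr_rows]),
               g$q2_train)
  # row order invariance and duplicated-row determinism
  shuffled <- tbl[c(5:80, 1:4), ]
  attr(shuffled, "normalization") <- attr(tbl, "normalization")
  p2 <- predict(fit, shuffled)
  expect_equal(p2$.pred[match(preds$compound_id, p2$compound_id)],
               preds$.pred)
  expect_error(predict(fit, tbl[, 1:3]),
               class = "qsardnn_validation_error")
})

test_that("applicability distances identify an exact training twin", {
  tbl <- simulate_descriptor_table(m = 60, n_descriptors = 4, rho = 0,
                                   block_size = 1, mixed_scales = FALSE,
                                   seed = 13)
  fit <- quiet(train_qsar(tbl, config = small_train_config(seed = 13)))
  train_row <- tibble::as_tibble(tbl)[match(fit$train_ids[1],
                                            compound_ids(tbl)), ]
  p <- predict(fit, train_row, applicability = TRUE)
  expect_identical(p$nearest_train_id, fit$train_ids[1])
  expect_lt(p$nearest_train_distance, 1e-10)
})
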