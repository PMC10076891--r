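# Training: seeded mini-batch SGD on the -q2 + decay cost, inverted
# dropout, periodic held-out evaluation, early stopping with snapshot
# restore.  One master seed derives separate streams for weight init,
# epoch shuffles and dropout masks, so e.g. switching dropout off never
# perturbs the shuffle sequence.

#' Train a network by stochastic gradient descent
#'
#' Each epoch visits a seeded shuffle of mini-batches of size
#' `batch_size`; weights move against the gradient of
#' `J = -q2 + (lambda/2) sum(W^2)`, where the q2 denominator is fixed for
#' the whole run as `sum((y_train - mean(y_train))^2)` so the stochastic
#' gradient is a constant rescaling of the mean-squared-error gradient
#' (the `"batch"` mode recomputes the denominator per mini-batch instead).
#' Every `eval_interval` epochs the full cost is computed on the
#' evaluation set; training stops when that cost has not improved for
#' `patience` consecutive evaluations, or at `max_epochs`, and the weight
#' snapshot from the best evaluation is returned.
#'
#' @param net A `network_params` (see [dnn_init()]).
#' @param X,y Training inputs and activities.
#' @param X_eval,y_eval Held-out set for early stopping; `NULL` disables
#'   early stopping and returns the final weights.
#' @param learning_rate SGD step size on the q2 cost scale.  Because the
#'   q2 gradient carries a 1/sum((y - mean(y))^2) factor, steps of order 1
#'   here correspond to conventional per-sample mean-squared-error steps
#'   of order 1/m; the default is 1.
#' @param batch_size Mini-batch size `d` (capped at `nrow(X)`).
#' @param max_epochs Epoch budget.
#' @param eval_interval Epochs between held-out evaluations.
#' @param patience Consecutive non-improving evaluations tolerated.
#' @param dropout Hidden-layer dropout rate in \[0, 1).
#' @param lambda Weight-decay coefficient.
#' @param seed Master seed for shuffles and dropout masks.
#' @param denominator_mode `"epoch"` (default, full-training-set q2
#'   denominator) or `"batch"`.
#' @param anneal Reduce-on-plateau factor: every 5 consecutive
#'   non-improving evaluations the learning rate is multiplied by this
#'   factor, shrinking the SGD/dropout jitter near convergence.  Set to 1
#'   to disable.  Default 0.5.
#' @return A list of class `dnn_fit`: `net` (best snapshot), `state` (a
#'   `train_state` with the cost trajectories, best epoch and seed).
#' @export
dnn_train <- function(net, X, y, X_eval = NULL, y_eval = NULL,
                      learning_rate = 1, batch_size = 16L,
                      max_epochs = 2000L, eval_interval = 10L,
                      patience = 20L, dropout = 0, lambda = 1e-4,
                      seed = 1L, denominator_mode = c("epoch", "batch"),
                      anneal = 0.5) {
  denominator_mode <- match.arg(denominator_mode)
  X <- as.matrix(X); m <- nrow(X)
  stopifnot(length(y) == m)
  if (batch_size > m) batch_size <- m
  D_full <- sum((y - mean(y))^2)
  if (D_full <= 0) {
    abort("Training activity is constant; q2 is undefined.",
          class = "qsardnn_validation_error")
  }
  shuffle_seed <- derive_seed(seed, "shuffle")
  dropout_seed <- derive_seed(seed, "dropout")
  qlog("train: m = ", m, ", layers ", paste(net$layer_sizes, collapse = "-"),
       ", seed ", seed, " (shuffle ", shuffle_seed,
       ", dropout ", dropout_seed, ")")
  has_eval <- !is.null(X_eval)
  if (has_eval) X_eval <- as.matrix(X_eval)

  cost_train <- numeric(0)
  eval_epochs <- integer(0); cost_eval <- numeric(0)
  best_cost <- Inf; best_epoch <- 0L; best_net <- net
  bad_evals <- 0L
  stopped <- max_epochs

  for (epoch in seq_len(max_epochs)) {
    perm <- withr::with_seed((shuffle_seed + epoch) %% (2^31 - 1),
                             sample.int(m))
    starts <- seq(1L, m, by = batch_size)
    for (b in seq_along(starts)) {
      idx <- perm[starts[b]:min(starts[b] + batch_size - 1L, m)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      masks <- if (dropout > 0) {
        withr::with_seed((dropout_seed + epoch * 7919 + b) %% (2^31 - 1),
                         draw_masks(net$layer_sizes, length(idx), dropout))
      }
      D <- if (denominator_mode == "epoch") D_full else {
        db <- sum((yb - mean(yb))^2)
        if (db > 0) db else D_full
      }
      g <- dnn_gradient(net, Xb, yb, lambda = lambda, denominator = D,
                        masks = masks)
      for (l in seq_along(net$weights)) {
        net$weights[[l]] <- net$weights[[l]] - learning_rate * g$weights[[l]]
        if (!is.null(net$biases)) {
          net$biases[[l]] <- net$biases[[l]] - learning_rate * g$biases[[l]]
        }
      }
    }
    J_train <- dnn_cost(net, X, y, lambda = lambda)$total
    cost_train[epoch] <- J_train
    if (!is.finite(J_train)) {
      abort(sprintf("Training diverged at epoch %d (cost %g). State: %d epochs recorded, best eval cost %g at epoch %d. Try a smaller learning rate.",
                    epoch, J_train, epoch, best_cost, best_epoch),
            class = "qsardnn_training_error")
    }
    if (has_eval && epoch %% eval_interval == 0L) {
      J_eval <- dnn_cost(net, X_eval, y_eval, lambda = lambda)$total
      eval_epochs <- c(eval_epochs, epoch)
      cost_eval <- c(cost_eval, J_eval)
      if (J_eval < best_cost) {
        best_cost <- J_eval; best_epoch <- epoch; best_net <- net
        bad_evals <- 0L
      } else {
        bad_evals <- bad_evals + 1L
        if (bad_evals > patience) { stopped <- epoch; break }
        if (anneal < 1 && bad_evals %% 5L == 0L) {
          learning_rate <- learning_rate * anneal
        }
      }
    }
  }
  if (!has_eval) { best_net <- net; best_epoch <- length(cost_train) }
  state <- structure(list(
    epochs_run = length(cost_train),
    cost_train = cost_train,
    eval_epochs = eval_epochs,
    cost_eval = cost_eval,
    best_eval_cost = if (has_eval) best_cost else NA_real_,
    best_epoch = best_epoch,
    stopped_epoch = min(stopped, length(cost_train)),
    seed = as.integer(seed)
  ), class = "train_state")
  structure(list(net = best_net, state = state), class = "dnn_fit")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state> %d epochs (best eval cost %.6g at epoch %d)\n",
              x$epochs_run, x$best_eval_cost, x$best_epoch))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.train_state <- function(x, ...) {
  d <- tibble(epoch = seq_len(x$epochs_run), cost_train = x$cost_train,
              cost_eval = NA_real_)
  d$cost_eval[x$eval_epochs] <- x$cost_eval
  d
}

#' Fit a QSAR deep-network model on a descriptor table
#'
#' The high-level entry point: takes a (washed) descriptor table, divides
#' it by [sphere_exclusion_split()] unless a split is supplied, builds the
#' network `n_descriptors - hidden_layers - 1` and trains it with
#' [dnn_train()], scoring training q2 and external-test q2/r2.  If the
#' table has not been normalized yet it is normalized first with the
#' configured mode, and the fitted normalization is stored in the model so
#' [predict.qsar_model()] can replay it on raw prediction inputs.
#'
#' @param x A `descriptor_tbl`.
#' @param split Optional [sphere_exclusion_split()] result; computed from
#'   `config$test_fraction` when `NULL`.
#' @param config A [run_config()].
#' @return An object of class `qsar_model`: the trained `net`, `state`,
#'   `normalization` parameters, `descriptors`, `activity`, `split`,
#'   `train_matrix` (for applicability distances), `config` and `report`
#'   (q2/r2 scores, sizes, stopping epoch).
#' @examples
#' \donttest{
#' tbl <- simulate_descriptor_table(m = 60, n_descriptors = 5, rho = 0,
#'                                  mixed_scales = FALSE, seed = 3)
#' fit <- train_qsar(tbl, config = run_config(hidden_layers = c(8, 8),
#'                                            max_epochs = 100))
#' glance(fit)
#' }
#' @export
train_qsar <- function(x, split = NULL, config = run_config()) {
  stopifnot(inherits(x, "descriptor_tbl"))
  if (is.null(attr(x, "normalization"))) {
    x <- normalize_descriptors(x, mode = config$normalization)
  }
  if (is.null(split)) {
    split <- sphere_exclusion_split(x, test_fraction = config$test_fraction)
  }
  idx <- split_indices(x, split)
  M <- descriptor_matrix(x); y <- activity_values(x)
  Xtr <- M[idx$train, , drop = FALSE]; ytr <- y[idx$train]
  Xte <- M[idx$test, , drop = FALSE]; yte <- y[idx$test]
  net <- dnn_init(c(ncol(M), config$hidden_layers, 1L),
                  use_bias = config$use_bias,
                  seed = derive_seed(config$seed, "init"))
  fit <- dnn_train(net, Xtr, ytr, Xte, yte,
                   learning_rate = config$learning_rate,
                   batch_size = config$batch_size,
                   max_epochs = config$max_epochs,
                   eval_interval = config$eval_interval,
                   patience = config$patience,
                   dropout = config$dropout, lambda = config$lambda,
                   seed = config$seed)
  htr <- forward_pass(fit$net, Xtr)$pred
  hte <- forward_pass(fit$net, Xte)$pred
  report <- model_report(q2_train = q_squared(ytr, htr),
                         q2_test = if (length(yte) >= 2) q_squared(yte, hte) else NA_real_,
                         r2_test = if (length(yte) >= 3) r_squared(yte, hte) else NA_real_,
                         n_train = length(ytr), n_test = length(yte),
                         descriptors = colnames(M),
                         stopping_epoch = fit$state$best_epoch)
  structure(list(net = fit$net, state = fit$state,
                 normalization = attr(x, "normalization"),
                 descriptors = colnames(M), activity = activity_name(x),
                 split = split, train_matrix = Xtr, train_activity = ytr,
                 train_ids = split$train_ids,
                 config = config, report = report),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  r <- x$report
  cat(sprintf("<qsar_model> %d descriptors -> %s, layers %s\n",
              length(x$descriptors), x$activity,
              paste(x$net$layer_sizes, collapse = "-")))
  cat(sprintf("  q2(train) = %.3f, q2(test) = %.3f, r2(test) = %.3f (n = %d/%d, stopped at epoch %d)\n",
              r$q2_train, r$q2_test, r$r2_test, r$n_train, r$n_test,
              r$stopping_epoch))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.qsar_model <- function(x, ...) {
  r <- x$report
  tibble(q2_train = r$q2_train, q2_test = r$q2_test, r2_test = r$r2_test,
         n_train = r$n_train, n_test = r$n_test,
         stopping_epoch = r$stopping_epoch,
         n_descriptors = length(x$descriptors),
         accepted = accept_model(r, x$config$q2_threshold,
                                 x$config$r2_threshold))
}

#' @exportS3Method generics::tidy
tidy.qsar_model <- function(x, ...) tidy(x$state)

#' @exportS3Method ggplot2::autoplot
autoplot.qsar_model <- function(object, ...) {
  d <- tidy(object$state) |>
    tidyr::pivot_longer(c("cost_train", "cost_eval"),
                        names_to = "set", values_to = "cost") |>
    dplyr::filter(is.finite(.data$cost))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$cost,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$state$best_epoch,
                        linetype = "dashed") +
    ggplot2::labs(x = "Epoch", y = "Cost J", colour = NULL,
                  title = "Training trajectory (dashed: restored snapshot)") +
    ggplot2::theme_minimal()
}

#' Predict activities with a fitted QSAR model
#'
#' Applies the model's stored normalization to raw descriptor inputs and
#' evaluates the network in inference mode (no dropout).  Inputs that were
#' already normalized by this package (they carry the normalization
#' attribute) are used as-is.  With `applicability = TRUE` each prediction
#' is accompanied by the Euclidean distance to the nearest training
#' compound: a large distance means no similar training structure exists
#' and the prediction should not be trusted.
#'
#' @param object A `qsar_model`.
#' @param newdata A `descriptor_tbl` or data frame containing every
#'   descriptor column the model was trained on.
#' @param applicability Add `nearest_train_id` and `nearest_train_distance`
#'   columns.  Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with `compound_id` (when available) and `.pred`.
#' @export
predict.qsar_model <- function(object, newdata, applicability = FALSE, ...) {
  missing <- setdiff(object$descriptors, names(newdata))
  if (length(missing) > 0L) {
    abort(sprintf("Missing descriptor column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "qsardnn_validation_error")
  }
  M <- as.matrix(as.data.frame(newdata)[, object$descriptors, drop = FALSE])
  if (is.null(attr(newdata, "normalization"))) {
    M <- apply_normalization(M, object$normalization)
  }
  out <- tibble(.pred = forward_pass(object$net, M)$pred)
  if ("compound_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble(compound_id = as.character(newdata$compound_id)),
                            out)
  }
  if (applicability) {
    Tr <- object$train_matrix
    nn <- apply(M, 1L, function(row) {
      d <- sqrt(colSums((t(Tr) - row)^2))
      j <- which.min(d)
      c(j, d[j])
    })
    out$nearest_train_id <- object$train_ids[nn[1L, ]]
    out$nearest_train_distance <- nn[2L, ]
  }
  out
}
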