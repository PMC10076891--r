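# The training objective: J(W, lambda) = -q2 + (lambda/2) * sum(W^2).
# Substituting -q2 for the average sum-of-squares error leaves the two
# objectives proportional up to constants -- minimising J maximises q2
# exactly -- because q2 = 1 - SSE/SSY and SSY does not depend on W.

#' Cost of a network on a data set
#'
#' Computes `J = -q2 + (lambda/2) * sum(weights^2)` where
#' `q2 = 1 - sum((h - y)^2) / sum((y - mean(y))^2)` and the decay term
#' runs over connection weights only, never biases.  At `lambda = 0`,
#' `J = -q2` exactly, so ranking weight configurations by J is the exact
#' reverse of ranking them by q2.
#'
#' @param net A `network_params`.
#' @param X Input matrix.
#' @param y Observed activities (length `nrow(X)`, at least 2,
#'   non-constant).
#' @param lambda L2 weight-decay coefficient.
#' @param denominator Optional fixed denominator replacing
#'   `sum((y - mean(y))^2)`; used internally during mini-batch training so
#'   every batch shares the full-training-set denominator.
#' @return An object of class `cost_breakdown`: `q2_term` (= -q2),
#'   `decay_term`, `total`, and the underlying `q2`, `sse`, `ssy`.
#' @export
dnn_cost <- function(net, X, y, lambda = 0, denominator = NULL) {
  if (length(y) < 2L) {
    abort("Cost needs at least two observations.",
          class = "qsardnn_validation_error")
  }
  ssy <- denominator %||% sum((y - mean(y))^2)
  if (ssy <= 0) {
    abort("Activity is constant on this set; q2 is undefined.",
          class = "qsardnn_validation_error")
  }
  h <- forward_pass(net, as.matrix(X))$pred
  sse <- sum((h - y)^2)
  q2_term <- -1 + sse / ssy
  decay <- (lambda / 2) * sum(vapply(net$weights,
                                     function(w) sum(w^2), numeric(1)))
  structure(list(q2_term = q2_term, decay_term = decay,
                 total = q2_term + decay, q2 = -q2_term,
                 sse = sse, ssy = ssy),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> J = %.6g (q2 term %.6g + decay %.6g); q2 = %.6g\n",
              x$total, x$q2_term, x$decay_term, x$q2))
  invisible(x)
}

#' Analytic gradient of the cost
#'
#' Backpropagation through the tanh layers.  The gradient of the `-q2`
#' term equals the gradient of `sum((h - y)^2)` scaled by `1/D`, with `D`
#' the (epoch-fixed) denominator, plus `lambda * W` from the decay term.
#' When dropout masks are supplied they must be the masks used in the
#' corresponding forward pass; the gradient is then the exact gradient of
#' the masked network's cost.
#'
#' @param net A `network_params`.
#' @param X Input matrix (mini-batch rows).
#' @param y Observed activities for the rows of `X`.
#' @param lambda L2 weight-decay coefficient.
#' @param denominator The q2 denominator `D`; defaults to
#'   `sum((y - mean(y))^2)` of `y`.
#' @param masks Optional dropout multiplier masks (internal).
#' @return A list with `weights` and (if the net has biases) `biases`
#'   holding gradients shaped like the parameters.
#' @export
dnn_gradient <- function(net, X, y, lambda = 0, denominator = NULL,
                         masks = NULL) {
  X <- as.matrix(X)
  D <- denominator %||% sum((y - mean(y))^2)
  if (D <= 0) {
    abort("Gradient denominator must be positive (non-constant activity).",
          class = "qsardnn_validation_error")
  }
  fw <- forward_pass(net, X, masks)
  L <- length(net$layer_sizes)
  gw <- vector("list", L - 1L)
  gb <- if (!is.null(net$biases)) vector("list", L - 1L) else NULL
  # output is linear: dJ/d(output) = 2 * (h - y) / D
  delta <- matrix(2 * (fw$pred - y) / D, ncol = 1L)
  for (l in rev(seq_len(L - 1L))) {
    gw[[l]] <- unname(crossprod(fw$A[[l]], delta)) + lambda * net$weights[[l]]
    if (!is.null(gb)) gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, net$weights[[l]])
      if (!is.null(masks)) delta <- delta * masks[[l - 1L]]
      delta <- delta * (1 - fw$H[[l]]^2)
    }
  }
  if (any(vapply(gw, function(g) any(!is.finite(g)), logical(1)))) {
    abort("Gradient contains non-finite entries; the optimisation has diverged. Try a smaller learning rate.",
          class = "qsardnn_training_error")
  }
  list(weights = gw, biases = gb)
}
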