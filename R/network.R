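# The feed-forward network: tanh hidden layers, linear output node.
# Weights W[[l]] (S_l x S_{l+1}) connect layer l to layer l+1; biases are
# optional per-node vectors and are never penalised by weight decay.

#' Initialise a feed-forward tanh network
#'
#' Weights are drawn from a zero-mean uniform distribution scaled by
#' `1/sqrt(fan_in)`, the classical scaling that keeps tanh pre-activations
#' in their linear range at any width; biases start at zero.  The same
#' seed yields bit-identical weights.
#'
#' @param layer_sizes Integer vector `S_1..S_L`: input descriptor count,
#'   hidden widths, and 1 output node.
#' @param use_bias Include per-node bias vectors.  Default `TRUE`.
#' @param seed Seed for the weight draw.
#' @return An object of class `network_params` with fields `layer_sizes`,
#'   `weights` (list of matrices), `biases` (list of vectors or `NULL`),
#'   `activation = "tanh"`.
#' @export
dnn_init <- function(layer_sizes, use_bias = TRUE, seed = 1L) {
  if (length(layer_sizes) < 2L || any(layer_sizes < 1) ||
      any(layer_sizes != round(layer_sizes))) {
    abort("`layer_sizes` must be at least two positive integers.",
          class = "qsardnn_validation_error")
  }
  if (layer_sizes[length(layer_sizes)] != 1L) {
    abort("The output layer must have exactly one node (regression head).",
          class = "qsardnn_validation_error")
  }
  layer_sizes <- as.integer(layer_sizes)
  L <- length(layer_sizes)
  withr::with_seed(as.integer(seed), {
    weights <- vector("list", L - 1L)
    biases <- if (use_bias) vector("list", L - 1L) else NULL
    for (l in seq_len(L - 1L)) {
      fan_in <- layer_sizes[l]
      # uniform on +/- sqrt(3)/sqrt(fan_in) has sd exactly 1/sqrt(fan_in)
      a <- sqrt(3) / sqrt(fan_in)
      weights[[l]] <- matrix(runif(fan_in * layer_sizes[l + 1L], -a, a),
                             fan_in, layer_sizes[l + 1L])
      if (use_bias) biases[[l]] <- numeric(layer_sizes[l + 1L])
    }
    structure(list(layer_sizes = layer_sizes, weights = weights,
                   biases = biases, activation = "tanh"),
              class = "network_params")
  })
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> layers %s, %d weights%s\n",
              paste(x$layer_sizes, collapse = "-"),
              dnn_count_parameters(x, include_bias = FALSE),
              if (is.null(x$biases)) "" else
                sprintf(" + %d biases", sum(x$layer_sizes[-1L]))))
  invisible(x)
}

#' Count the free parameters of a network
#'
#' With `include_bias = FALSE` this is the pure connection count
#' `sum(S_l * S_(l+1))`: a 5-20-20-20-1 architecture has
#' 5x20 + 20x20 + 20x20 + 20x1 = 920 weight variables.
#'
#' @param net A `network_params`.
#' @param include_bias Count bias terms too.  Default `FALSE`.
#' @return Integer parameter count.
#' @export
dnn_count_parameters <- function(net, include_bias = FALSE) {
  s <- net$layer_sizes
  n <- sum(s[-length(s)] * s[-1L])
  if (include_bias && !is.null(net$biases)) n <- n + sum(s[-1L])
  as.integer(n)
}

# Dropout masks: one multiplier matrix per hidden layer with entries 0
# (dropped) or 1/(1-rate) (inverted-dropout scaling).  No mask is drawn at
# rate 0, so the rate-0 path consumes no random numbers and is
# bit-identical to inference.
draw_masks <- function(layer_sizes, n_rows, rate) {
  if (rate == 0) return(NULL)
  L <- length(layer_sizes)
  lapply(seq_len(L - 2L), function(h) {
    keep <- matrix(runif(n_rows * layer_sizes[h + 1L]) >= rate,
                   n_rows, layer_sizes[h + 1L])
    keep / (1 - rate)
  })
}

# Full forward pass with cached pre-mask activations for backpropagation.
# masks: NULL (inference) or list indexed by hidden layer.
forward_pass <- function(net, X, masks = NULL) {
  L <- length(net$layer_sizes)
  A <- vector("list", L)      # post-mask activations (A[[1]] = X)
  H <- vector("list", L)      # pre-mask tanh outputs, hidden layers only
  A[[1L]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- A[[l]] %*% net$weights[[l]]
    if (!is.null(net$biases)) Z <- sweep(Z, 2, net$biases[[l]], "+")
    if (l < L - 1L) {
      H[[l + 1L]] <- tanh(Z)
      A[[l + 1L]] <- if (is.null(masks)) H[[l + 1L]] else
        H[[l + 1L]] * masks[[l]]
    } else {
      A[[l + 1L]] <- Z      # linear output
    }
  }
  list(pred = drop(A[[L]]), A = A, H = H)
}

#' Forward evaluation of a network
#'
#' Hidden layers apply tanh; the output node is linear, since log-scale
#' activities (pIC50, LAC50) are unbounded.  In training mode with a
#' nonzero dropout rate, inverted dropout is applied to the hidden
#' activations (surviving nodes scaled by `1/(1-rate)`); inference applies
#' no mask and no scaling.  Training mode at rate 0 is bit-identical to
#' inference.
#'
#' @param net A `network_params`.
#' @param X Numeric matrix, one row per compound, `S_1` columns.
#' @param dropout_rate Hidden-layer dropout rate in \[0, 1).
#' @param mode `"infer"` (default) or `"train"`.
#' @param seed Seed for the dropout mask draw (train mode, rate > 0).
#' @return Numeric vector of predictions, one per row of `X`.
#' @export
dnn_forward <- function(net, X, dropout_rate = 0, mode = c("infer", "train"),
                        seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (ncol(X) != net$layer_sizes[1L]) {
    abort(sprintf("Input has %d columns but the network expects %d.",
                  ncol(X), net$layer_sizes[1L]),
          class = "qsardnn_validation_error")
  }
  masks <- NULL
  if (mode == "train" && dropout_rate > 0) {
    masks <- withr::with_seed(as.integer(seed),
                              draw_masks(net$layer_sizes, nrow(X), dropout_rate))
  }
  forward_pass(net, X, masks)$pred
}
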