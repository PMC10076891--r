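# Synthetic descriptor tables with known generative structure.  These
# emulate the shape of raw MOE/CDK descriptor exports (named numeric
# columns, mixed scales, redundant blocks) while keeping the full ground
# truth -- true coefficients, active columns, planted outliers -- attached
# to the result, so every downstream stage can be tested against what was
# actually generated.

#' Simulate a descriptor table with known structure
#'
#' Descriptors are drawn as block-equicorrelated Gaussians via a
#' shared-factor construction: within a block of size `block_size`, each
#' column is `sqrt(rho) * z_block + sqrt(1 - rho) * eps`, giving exact
#' population correlation `rho` between block members and independence
#' across blocks.  The activity is a linear or tanh link of the active
#' columns plus Gaussian noise; optional planted outliers shift a
#' compound's activity by a stated multiple of its neighborhood standard
#' deviation, placed in dense or sparse regions of descriptor space.
#'
#' @param m Number of compounds.  Default 200.
#' @param n_descriptors Number of descriptor columns K.  Default 30.
#' @param block_size Descriptors per correlated block (1 = independent
#'   columns).  Default 3.
#' @param rho Within-block population correlation, in \[0, 1).  Default 0.9.
#' @param active Indices of the descriptors that truly drive the activity.
#'   Default `1:3`.
#' @param coef Coefficients for the active descriptors; drawn from
#'   U(0.5, 1.5) with random signs when `NULL`.
#' @param link `"linear"` or `"tanh"`: activity is `X_active %*% coef`
#'   (optionally passed through tanh) plus noise.
#' @param noise_sd Standard deviation of the additive Gaussian activity
#'   noise.  Default 0.2.
#' @param n_outliers Number of planted activity outliers.  Default 0.
#' @param outlier_sigma Planted deviation in units of the neighborhood
#'   activity standard deviation.  Default 6.
#' @param outlier_dense If `TRUE` (default) outliers are planted on the
#'   compounds with the most neighbors in descriptor space; if `FALSE`
#'   their descriptors are first displaced far from the data cloud so they
#'   have few or no neighbors.
#' @param mixed_scales Rescale every third column by 1000 to exercise
#'   normalization, as raw descriptor exports mix units.  Default `TRUE`.
#' @param seed Seed; the same seed yields a bit-identical table.
#' @return A [descriptor_table()] with activity column `"activity"` and a
#'   `"truth"` attribute (see [simulation_truth()]) recording coefficients,
#'   active descriptor names, outlier IDs and the noise level.
#' @examples
#' tbl <- simulate_descriptor_table(m = 50, n_descriptors = 6, seed = 7)
#' simulation_truth(tbl)$active
#' @export
simulate_descriptor_table <- function(m = 200, n_descriptors = 30,
                                      block_size = 3, rho = 0.9,
                                      active = 1:3, coef = NULL,
                                      link = c("linear", "tanh"),
                                      noise_sd = 0.2,
                                      n_outliers = 0L, outlier_sigma = 6,
                                      outlier_dense = TRUE,
                                      mixed_scales = TRUE,
                                      seed = 1L) {
  link <- match.arg(link)
  check_scalar_number(m, "m", 2, Inf, integerish = TRUE)
  check_scalar_number(n_descriptors, "n_descriptors", 1, Inf, integerish = TRUE)
  check_scalar_number(block_size, "block_size", 1, Inf, integerish = TRUE)
  check_scalar_number(rho, "rho", 0, 1, open_upper = TRUE)
  check_scalar_number(noise_sd, "noise_sd", 0, Inf)
  check_scalar_number(n_outliers, "n_outliers", 0, Inf, integerish = TRUE)
  if (length(active) < 1L || any(active < 1) || any(active > n_descriptors)) {
    abort("`active` must index descriptor columns.",
          class = "qsardnn_validation_error")
  }
  withr::with_seed(derive_seed(seed, "simulate"), {
    block_id <- rep(seq_len(ceiling(n_descriptors / block_size)),
                    each = block_size)[seq_len(n_descriptors)]
    Z <- matrix(rnorm(m * max(block_id)), m, max(block_id))
    E <- matrix(rnorm(m * n_descriptors), m, n_descriptors)
    X <- sqrt(rho) * Z[, block_id, drop = FALSE] + sqrt(1 - rho) * E
    colnames(X) <- sprintf("d%03d", seq_len(n_descriptors))
    if (is.null(coef)) {
      coef <- runif(length(active), 0.5, 1.5) *
        sample(c(-1, 1), length(active), replace = TRUE)
    }
    stopifnot(length(coef) == length(active))
    eta <- drop(X[, active, drop = FALSE] %*% coef)
    signal <- if (link == "tanh") tanh(eta) else eta
    y <- signal + rnorm(m, sd = noise_sd)
    ids <- sprintf("cpd%04d", seq_len(m))

    outlier_ids <- character()
    if (n_outliers > 0L) {
      d <- as.matrix(dist(scale(X)))
      r <- quantile(d[upper.tri(d)], 0.1)
      n_nbr <- rowSums(d <= r) - 1L
      if (outlier_dense) {
        pick <- order(n_nbr, decreasing = TRUE)[seq_len(n_outliers)]
      } else {
        pick <- order(n_nbr)[seq_len(n_outliers)]
        # displace so the planted compounds sit alone in descriptor space
        X[pick, ] <- X[pick, , drop = FALSE] +
          10 * matrix(sign(rnorm(length(pick) * n_descriptors)),
                      length(pick), n_descriptors)
        d <- as.matrix(dist(scale(X)))
        r <- quantile(d[upper.tri(d)], 0.1)
      }
      for (i in pick) {
        nbr <- setdiff(which(d[i, ] <= r), i)
        s_local <- if (length(nbr) >= 2L) sd(y[nbr]) else noise_sd
        if (!is.finite(s_local) || s_local == 0) s_local <- max(noise_sd, 1e-8)
        centre <- if (length(nbr) > 0L) mean(y[nbr]) else signal[i]
        y[i] <- centre + outlier_sigma * s_local
      }
      outlier_ids <- ids[pick]
    }

    if (mixed_scales) {
      scaled <- seq(3, n_descriptors, by = 3)
      X[, scaled] <- X[, scaled, drop = FALSE] * 1000
    }

    out <- tibble(compound_id = ids)
    out <- dplyr::bind_cols(out, as_tibble(X), tibble(activity = y))
    tbl <- descriptor_table(out, activity = "activity")
    attr(tbl, "truth") <- list(
      active = colnames(X)[active], coef = setNames(coef, colnames(X)[active]),
      link = link, noise_sd = noise_sd, block_id = block_id,
      rho = rho, outlier_ids = outlier_ids, seed = seed
    )
    tbl
  })
}

#' Ground truth of a simulated descriptor table
#'
#' @param x A table produced by [simulate_descriptor_table()].
#' @return A list with elements `active`, `coef`, `link`, `noise_sd`,
#'   `block_id`, `rho`, `outlier_ids` and `seed`.
#' @export
simulation_truth <- function(x) {
  truth <- attr(x, "truth")
  if (is.null(truth)) {
    abort("No simulation ground truth attached to this table.",
          class = "qsardnn_validation_error")
  }
  truth
}
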