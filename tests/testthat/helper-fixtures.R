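# Shared fixtures, all generated in code.

# Small hand-made table: 4 compounds x 3 descriptors.
tiny_table <- function() {
  descriptor_table(
    tibble::tibble(
      compound_id = c("a", "b", "c", "d"),
      logP = c(1.2, 0.4, 2.2, -0.3),
      tpsa = c(40, 80, 20, 95),
      mw = c(300, 210, 410, 180),
      pIC50 = c(5.1, 6.3, 4.8, 7.0)
    ),
    activity = "pIC50"
  )
}

# A dense Gaussian cluster in descriptor space with one activity planted
# `dev` local sds away from its neighborhood mean; compound "out" is the
# planted one.
clustered_outlier_table <- function(m = 30, dev = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(m * 3, sd = 0.3), m, 3)
    X[1, ] <- 0                       # plant at the cluster center
    y <- rnorm(m)
    y[1] <- mean(y[-1]) + dev * sd(y[-1])
    descriptor_table(
      tibble::tibble(compound_id = c("out", sprintf("c%02d", 2:m)),
                     d1 = X[, 1], d2 = X[, 2], d3 = X[, 3],
                     activity = y),
      activity = "activity")
  })
}

# Three columns with EXACT sample correlations cor(b1,b2) = 0.96,
# cor(b1,b3) = 0.90, cor(b2,b3) = 0.97: b2 and b3 both exceed a 0.95
# threshold against some retained column, but only b2 is deleted by the
# greedy order (b3's correlation with the retained b1 is below it).
# Built by mapping the Cholesky factor of the target Gram matrix onto an
# orthonormal centered basis, so the correlations hold exactly, not just
# in expectation.  (0.50 in place of 0.90 would violate the triangle
# inequality for correlations given 0.96 and 0.97.)
correlated_trace_table <- function(n = 60, seed = 42) {
  G <- matrix(c(1, .96, .90, .96, 1, .97, .90, .97, 1), 3, 3)
  L <- chol(G)
  withr::with_seed(seed, {
    raw <- matrix(rnorm(n * 3), n, 3)
    raw <- sweep(raw, 2, colMeans(raw), "-")
    E <- qr.Q(qr(raw))            # orthonormal, columns centered
    B <- E %*% L                  # sample correlation of B is exactly G
    descriptor_table(
      tibble::tibble(compound_id = sprintf("c%03d", seq_len(n)),
                     b1 = B[, 1], b2 = B[, 2], b3 = B[, 3],
                     activity = rnorm(n)),
      activity = "activity")
  })
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

small_train_config <- function(seed = 1, max_epochs = 200, ...) {
  run_config(hidden_layers = c(8, 8), max_epochs = max_epochs,
             patience = 10, seed = seed, ...)
}
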