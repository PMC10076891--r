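# Optional PCA reduction of the descriptor matrix: center columns, form
# the covariance matrix, eigendecompose, order by eigenvalue, project onto
# the leading p eigenvectors.

#' Reduce the descriptor matrix by principal components
#'
#' Centers each descriptor column, computes the descriptor covariance
#' matrix, eigendecomposes it, orders eigenpairs by decreasing eigenvalue,
#' and projects the centered matrix onto the leading `p` eigenvectors.
#' In practice descriptor sets are often too collinear for a clean choice
#' of `p`, which is why [prune_correlated()] is the default reduction; PCA
#' is kept as the classical alternative.
#'
#' @param x A `descriptor_tbl`.
#' @param p Number of components to retain, `1 <= p <= min(m, n)`.
#' @return An object of class `pca_result` with fields `column_means`,
#'   `eigenvalues` (all n, descending), `rotation` (n x p orthonormal
#'   feature matrix), `scores` (m x p projected matrix), `p`, and `table`,
#'   a `descriptor_tbl` whose descriptors are the component scores
#'   `PC1..PCp`.
#' @export
pca_reduce <- function(x, p) {
  stopifnot(inherits(x, "descriptor_tbl"))
  M <- descriptor_matrix(x)
  m <- nrow(M); n <- ncol(M)
  check_scalar_number(p, "p", 1, min(m, n), integerish = TRUE)
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu, "-")
  covM <- stats::cov(M)
  eig <- eigen(covM, symmetric = TRUE)
  # eigen() already sorts descending; clamp tiny negative round-off
  values <- pmax(eig$values, 0)
  V <- eig$vectors[, seq_len(p), drop = FALSE]
  colnames(V) <- sprintf("PC%d", seq_len(p))
  rownames(V) <- colnames(M)
  scores <- Mc %*% V
  reduced <- tibble(compound_id = compound_ids(x))
  reduced <- dplyr::bind_cols(reduced, as_tibble(scores))
  reduced[[activity_name(x)]] <- activity_values(x)
  structure(list(column_means = mu, eigenvalues = values, rotation = V,
                 scores = scores, p = as.integer(p),
                 table = descriptor_table(reduced, activity = activity_name(x))),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  total <- sum(x$eigenvalues)
  kept <- sum(x$eigenvalues[seq_len(x$p)])
  cat(sprintf("<pca_result> %d components, %.1f%% of descriptor variance\n",
              x$p, 100 * kept / total))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         variance_fraction = x$eigenvalues / sum(x$eigenvalues),
         retained = seq_along(x$eigenvalues) <= x$p)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pca_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$eigenvalue,
                                  fill = .data$retained)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = "Descriptor covariance spectrum") +
    ggplot2::theme_minimal()
}
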