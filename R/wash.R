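# Data washing: normalization, Pauta-criterion outlier removal with the
# similar-compound significance rule, and greedy correlation-based
# descriptor pruning.  Each step returns the cleaned table with an audit
# trail accumulated in the "wash" attribute; wash_report() extracts it.

append_wash <- function(x, rows) {
  report <- attr(x, "wash") %||%
    tibble(step = character(), kind = character(), name = character(),
           partner = character(), correlation = double(),
           n_neighbors = integer(), local_mean = double(),
           local_sd = double(), deviation = double())
  if (nrow(rows) > 0L) report <- dplyr::bind_rows(report, rows)
  attr(x, "wash") <- report
  x
}

#' Washing audit trail
#'
#' Every washing step ([normalize_descriptors()], [detect_outliers()],
#' [prune_correlated()]) records what it removed and why.  One row per
#' removal: dropped constant descriptors, flagged outlier compounds (with
#' their neighborhood statistics), and pruned redundant descriptors (with
#' the retained partner and the correlation that triggered removal).
#'
#' @param x A washed `descriptor_tbl`.
#' @return A tibble with columns `step`, `kind`, `name`, `partner`,
#'   `correlation`, `n_neighbors`, `local_mean`, `local_sd`, `deviation`.
#' @export
wash_report <- function(x) {
  attr(x, "wash") %||%
    tibble(step = character(), kind = character(), name = character(),
           partner = character(), correlation = double(),
           n_neighbors = integer(), local_mean = double(),
           local_sd = double(), deviation = double())
}

#' Normalize descriptor columns
#'
#' Raw descriptor exports mix units and scales; distance computations and
#' gradient training both need comparable columns.  `"zscore"` centers and
#' scales each descriptor to mean 0, sd 1; `"minmax"` maps it to \[0, 1\].
#' Constant columns carry no information and break both modes, so they are
#' removed and reported.  The fitted location/scale parameters are stored
#' on the result ([normalization_params()]) so the identical transform can
#' be replayed on prediction inputs.
#'
#' @param x A `descriptor_tbl`.
#' @param mode `"zscore"` (default) or `"minmax"`.
#' @return The normalized `descriptor_tbl` with attributes
#'   `"normalization"` (parameters) and an updated wash report.
#' @export
normalize_descriptors <- function(x, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "descriptor_tbl"))
  M <- descriptor_matrix(x)
  params <- fit_normalization(M, mode)
  constant <- setdiff(colnames(M), params$descriptor)
  if (length(constant) == ncol(M)) {
    abort("All descriptor columns are constant; nothing to normalize.",
          class = "qsardnn_validation_error")
  }
  out <- restrict_table(x, descriptors = params$descriptor)
  Mn <- apply_normalization(descriptor_matrix(out), params)
  for (col in colnames(Mn)) out[[col]] <- Mn[, col]
  attr(out, "normalization") <- params
  attr(out, "wash") <- attr(x, "wash")
  if (length(constant) > 0L) {
    qlog("normalize: dropped ", length(constant), " constant descriptor(s): ",
         paste(constant, collapse = ", "))
    out <- append_wash(out, tibble(step = "normalize", kind = "descriptor",
                                   name = constant))
  }
  out
}

fit_normalization <- function(M, mode) {
  loc <- if (mode == "zscore") colMeans(M) else apply(M, 2, min)
  scl <- if (mode == "zscore") apply(M, 2, sd) else apply(M, 2, max) - loc
  keep <- scl > 0
  tibble(descriptor = colnames(M)[keep], mode = mode,
         location = unname(loc[keep]), scale = unname(scl[keep]))
}

apply_normalization <- function(M, params) {
  M <- M[, params$descriptor, drop = FALSE]
  sweep(sweep(M, 2, params$location, "-"), 2, params$scale, "/")
}

invert_normalization <- function(M, params) {
  sweep(sweep(M, 2, params$scale, "*"), 2, params$location, "+")
}

#' Normalization parameters of a washed table
#'
#' @param x A table returned by [normalize_descriptors()].
#' @return A tibble with columns `descriptor`, `mode`, `location`, `scale`.
#' @export
normalization_params <- function(x) {
  p <- attr(x, "normalization")
  if (is.null(p)) {
    abort("Table has no stored normalization; run normalize_descriptors() first.",
          class = "qsardnn_validation_error")
  }
  p
}

#' Detect and remove activity outliers by the Pauta (3-sigma) criterion
#'
#' QSAR rests on the premise that similar structures have similar
#' activity, so a compound whose activity deviates far from that of its
#' structural neighbors is suspect.  For each compound, the neighborhood is
#' the set of other compounds within Euclidean distance `r` in descriptor
#' space, where `r` is the `radius_quantile` quantile of all pairwise
#' distances.  The compound is flagged when (a) it has strictly more than
#' `min_neighbors` neighbors -- deviation from a sparse neighborhood is not
#' statistically significant -- and (b) its activity deviates from the
#' neighborhood mean by more than `sigma` neighborhood standard deviations.
#' Detection runs on the original table throughout; removals do not
#' cascade.
#'
#' @param x A normalized `descriptor_tbl`.
#' @param sigma Deviation multiplier (default 3, the classical rule).
#' @param min_neighbors Minimum neighbor count, exceeded strictly
#'   (default 10).
#' @param radius_quantile Quantile of pairwise distances defining the
#'   neighborhood radius (default 0.1).
#' @param scope `"local"` (default): neighborhood mean/sd.  `"global"`:
#'   dataset-wide mean/sd with no neighborhood rule, the textbook variant.
#' @return The table with flagged compounds removed and the wash report
#'   extended by one row per removal (neighbor count, local mean/sd,
#'   deviation).
#' @export
detect_outliers <- function(x, sigma = 3, min_neighbors = 10L,
                            radius_quantile = 0.1,
                            scope = c("local", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "descriptor_tbl"))
  check_scalar_number(sigma, "sigma", 0, Inf, open_lower = TRUE)
  check_scalar_number(min_neighbors, "min_neighbors", 0, Inf, integerish = TRUE)
  check_scalar_number(radius_quantile, "radius_quantile", 0, 1, open_lower = TRUE)
  m <- n_compounds(x)
  if (m < min_neighbors + 2L) {
    abort(sprintf("Need at least %d compounds for min_neighbors = %d.",
                  min_neighbors + 2L, min_neighbors),
          class = "qsardnn_validation_error")
  }
  y <- activity_values(x)
  ids <- compound_ids(x)

  if (scope == "global") {
    mu <- mean(y); s <- sd(y)
    dev <- y - mu
    flagged <- if (s == 0) rep(FALSE, m) else abs(dev) > sigma * s
    rows <- tibble(step = "pauta", kind = "compound", name = ids[flagged],
                   n_neighbors = m - 1L, local_mean = mu, local_sd = s,
                   deviation = dev[flagged])
  } else {
    D <- as.matrix(dist(descriptor_matrix(x)))
    r <- quantile(D[upper.tri(D)], radius_quantile, names = FALSE)
    flagged <- logical(m)
    rows_list <- list()
    for (i in seq_len(m)) {
      nbr <- which(D[i, ] <= r)
      nbr <- nbr[nbr != i]
      if (length(nbr) <= min_neighbors) next
      mu <- mean(y[nbr]); s <- sd(y[nbr])
      dev <- y[i] - mu
      hit <- if (s == 0) abs(dev) > 0 else abs(dev) > sigma * s
      if (hit) {
        flagged[i] <- TRUE
        rows_list[[length(rows_list) + 1L]] <-
          tibble(step = "pauta", kind = "compound", name = ids[i],
                 n_neighbors = length(nbr), local_mean = mu, local_sd = s,
                 deviation = dev)
      }
    }
    rows <- dplyr::bind_rows(rows_list)
  }

  if (any(flagged)) {
    qlog("pauta: removed ", sum(flagged), " outlier compound(s): ",
         paste(ids[flagged], collapse = ", "))
  }
  out <- restrict_table(x, rows = which(!flagged))
  append_wash(out, rows)
}

#' Prune redundant descriptors by pairwise correlation
#'
#' Two highly correlated descriptors carry the same information; either
#' alone suffices for training.  The greedy double loop scans columns in
#' order: for each retained column `i`, every later not-yet-deleted column
#' `j` with `|cor(b_i, b_j)| > threshold` is deleted, so earlier columns
#' always win.  On the returned table every remaining pair satisfies
#' `|cor| <= threshold`, and pruning an already pruned table removes
#' nothing.
#'
#' @param x A `descriptor_tbl` with at least two non-constant descriptors.
#' @param threshold Correlation tolerance in (0, 1\].  Default 0.95.
#' @return The pruned table; the wash report gains one row per deleted
#'   descriptor naming the retained partner and their Pearson correlation.
#' @export
prune_correlated <- function(x, threshold = 0.95) {
  stopifnot(inherits(x, "descriptor_tbl"))
  check_scalar_number(threshold, "threshold", 0, 1, open_lower = TRUE)
  M <- descriptor_matrix(x)
  n <- ncol(M)
  if (n < 2L) return(x)
  sds <- apply(M, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant descriptor column(s) %s: normalize first.",
                  paste(colnames(M)[sds == 0], collapse = ", ")),
          class = "qsardnn_validation_error")
  }
  C <- cor(M)
  deleted <- logical(n)
  partner <- integer(n)
  for (i in seq_len(n - 1L)) {
    if (deleted[i]) next
    js <- which(!deleted & abs(C[i, ]) > threshold)
    js <- js[js > i]
    deleted[js] <- TRUE
    partner[js] <- i
  }
  keep <- colnames(M)[!deleted]
  partner_idx <- partner[deleted]
  rows <- tibble(step = "prune", kind = "descriptor",
                 name = colnames(M)[deleted],
                 partner = colnames(M)[partner_idx],
                 correlation = C[cbind(partner_idx, which(deleted))])
  if (any(deleted)) {
    qlog("prune: removed ", sum(deleted), " redundant descriptor(s) at |r| > ",
         threshold)
  }
  out <- restrict_table(x, descriptors = keep)
  append_wash(out, rows)
}

#' Run the full washing pipeline
#'
#' Convenience wrapper: [normalize_descriptors()], then [detect_outliers()],
#' then [prune_correlated()], with parameters taken from a [run_config()].
#'
#' @param x A `descriptor_tbl`.
#' @param config A [run_config()].
#' @return The washed table with the accumulated wash report.
#' @export
wash_table <- function(x, config = run_config()) {
  x |>
    normalize_descriptors(mode = config$normalization) |>
    detect_outliers(sigma = config$sigma,
                    min_neighbors = config$min_neighbors,
                    radius_quantile = config$radius_quantile) |>
    prune_correlated(threshold = config$corr_threshold)
}
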