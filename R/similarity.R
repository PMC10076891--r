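# Applicability diagnostics: a prediction is only trustworthy when the
# training set contains a structurally similar compound.  Similarity is
# measured either as Euclidean distance in (normalized) descriptor space
# or as the Tanimoto coefficient on binary fingerprints.

#' Nearest compound by Euclidean distance in descriptor space
#'
#' @param x A `descriptor_tbl`.
#' @param query_id Compound ID to look up.
#' @return A one-row tibble: `query_id`, `nearest_id`, `distance`.
#' @export
nearest_compound <- function(x, query_id) {
  stopifnot(inherits(x, "descriptor_tbl"))
  ids <- compound_ids(x)
  i <- match(query_id, ids)
  if (is.na(i)) {
    abort(sprintf("Compound `%s` not in table.", query_id),
          class = "qsardnn_validation_error")
  }
  M <- descriptor_matrix(x)
  d <- sqrt(colSums((t(M) - M[i, ])^2))
  d[i] <- Inf
  j <- which.min(d)
  tibble(query_id = query_id, nearest_id = ids[j],
         distance = unname(d[j]))
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' `TC = |A intersect B| / |A union B|` over the on-bits.  Two all-zero
#' fingerprints share no information, so their TC is defined as 0 with a
#' warning.
#'
#' @param a,b Binary (0/1) vectors of equal length.
#' @return The Tanimoto coefficient in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    abort("Fingerprints must be strictly 0/1.",
          class = "qsardnn_validation_error")
  }
  union_bits <- sum(a == 1 | b == 1)
  if (union_bits == 0L) {
    warn("Both fingerprints are empty; Tanimoto coefficient defined as 0.")
    return(0)
  }
  sum(a == 1 & b == 1) / union_bits
}

#' Most similar compound by Tanimoto coefficient
#'
#' @param fingerprints A tibble with a `compound_id` column and strictly
#'   0/1 fingerprint columns (see [read_fingerprints()]).
#' @param query_id Compound ID to look up.
#' @param id Name of the ID column.
#' @return A one-row tibble: `query_id`, `nearest_id`, `tc`.
#' @export
tanimoto_nearest <- function(fingerprints, query_id, id = "compound_id") {
  ids <- as.character(fingerprints[[id]])
  i <- match(query_id, ids)
  if (is.na(i)) {
    abort(sprintf("Compound `%s` not in fingerprint table.", query_id),
          class = "qsardnn_validation_error")
  }
  F <- as.matrix(fingerprints[, setdiff(names(fingerprints), id), drop = FALSE])
  if (!all(F %in% c(0, 1))) {
    abort("Fingerprint columns must be strictly 0/1.",
          class = "qsardnn_validation_error")
  }
  q <- F[i, ]
  inter <- as.vector(F %*% q)
  union_bits <- rowSums(F == 1) + sum(q) - inter
  tc <- ifelse(union_bits == 0, 0, inter / union_bits)
  tc[i] <- -Inf
  j <- which.max(tc)
  tibble(query_id = query_id, nearest_id = ids[j], tc = tc[j])
}
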