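# Rational training/test division by sphere exclusion.  The variant here
# is the farthest-point (max-min) center selection: centers become the
# training set and every compound inside a center's sphere becomes test,
# which guarantees by construction that every test compound has a training
# representative within the sphere radius.

#' Sphere-exclusion training/test split
#'
#' Deterministic given the table.  The first center is the compound with
#' the highest activity (ties broken by lexicographically smallest ID) so
#' the training set anchors the top of the activity range.  Then,
#' repeatedly, the unassigned compound farthest from all existing centers
#' becomes the next center and joins the training set, and every
#' unassigned compound within `radius` of it joins the test set, until all
#' compounds are assigned.  The radius is tuned by bisection (at most 40
#' iterations over \[0, max pairwise distance\]) so the achieved test
#' fraction is closest to `test_fraction`; when the target is not
#' achievable for any radius the closest split is returned with a warning.
#'
#' Because descriptor columns change during variable selection, the split
#' must be recomputed for each descriptor subset: distances in the reduced
#' space differ from distances in the full space.
#'
#' @param x A `descriptor_tbl` with normalized descriptors and at least 5
#'   compounds.
#' @param test_fraction Target fraction of compounds in the test set,
#'   in (0, 1).  Default 0.2.
#' @return An object of class `split_result`: `train_ids`, `test_ids`,
#'   `radius`, `seed_compound`, `test_fraction` (achieved), `target`.
#'   Invariant: every test compound lies within `radius` of at least one
#'   training compound.
#' @export
sphere_exclusion_split <- function(x, test_fraction = 0.2) {
  stopifnot(inherits(x, "descriptor_tbl"))
  check_scalar_number(test_fraction, "test_fraction", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  m <- n_compounds(x)
  if (m < 5L) {
    abort("Sphere-exclusion splitting needs at least 5 compounds.",
          class = "qsardnn_validation_error")
  }
  ids <- compound_ids(x)
  y <- activity_values(x)
  D <- as.matrix(dist(descriptor_matrix(x)))

  top <- which(y == max(y))
  first <- top[order(ids[top])][1L]

  split_at <- function(radius) {
    assigned <- rep(NA_character_, m)
    min_dist_to_center <- rep(Inf, m)
    centre <- first
    repeat {
      assigned[centre] <- "train"
      min_dist_to_center <- pmin(min_dist_to_center, D[centre, ])
      in_sphere <- is.na(assigned) & D[centre, ] <= radius
      assigned[in_sphere] <- "test"
      open <- which(is.na(assigned))
      if (length(open) == 0L) break
      centre <- open[which.max(min_dist_to_center[open])]
    }
    assigned
  }

  lo <- 0; hi <- max(D)
  best <- NULL; best_gap <- Inf; best_radius <- NA_real_
  consider <- function(radius) {
    a <- split_at(radius)
    gap <- abs(mean(a == "test") - test_fraction)
    if (gap < best_gap) {
      best <<- a; best_gap <<- gap; best_radius <<- radius
    }
    mean(a == "test")
  }
  consider(lo); consider(hi)
  for (iter in seq_len(40L)) {
    mid <- (lo + hi) / 2
    frac <- consider(mid)
    if (frac < test_fraction) lo <- mid else hi <- mid
  }

  achieved <- mean(best == "test")
  if (abs(achieved - test_fraction) > 1 / m + 1e-12) {
    warn(sprintf("Target test fraction %.3f not achievable; closest split has %.3f.",
                 test_fraction, achieved))
  }
  structure(list(train_ids = ids[best == "train"],
                 test_ids = ids[best == "test"],
                 radius = best_radius,
                 seed_compound = ids[first],
                 test_fraction = achieved,
                 target = test_fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d test (fraction %.3f, target %.3f), radius %.4g, seed compound %s\n",
              length(x$train_ids), length(x$test_ids), x$test_fraction,
              x$target, x$radius, x$seed_compound))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.split_result <- function(x, ...) {
  tibble(compound_id = c(x$train_ids, x$test_ids),
         set = c(rep("train", length(x$train_ids)),
                 rep("test", length(x$test_ids))))
}

# Row indices of the two sets in the table the split was computed from.
split_indices <- function(x, split) {
  ids <- compound_ids(x)
  list(train = match(split$train_ids, ids), test = match(split$test_ids, ids))
}
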