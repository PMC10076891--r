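# Variable selection: search descriptor subsets of fixed size k,
# re-splitting (the sphere-exclusion geometry changes with the columns)
# and retraining per subset, to maximise model quality on both the
# internal training set and the external test set.

#' Search descriptor subsets of size k
#'
#' For every candidate subset the table is restricted to those columns,
#' the sphere-exclusion split is recomputed in the reduced descriptor
#' space, a fresh network is trained with early stopping, and the model is
#' scored.  The default score `min(q2_train, r2_test)` demands quality on
#' both sets at once; `"sum"` trades them off instead.  Ties are broken by
#' `r2_test`, then by the order of evaluation (lexicographic subset order
#' for the exhaustive strategy).  The whole run is deterministic given the
#' config's master seed.
#'
#' Exhaustive search evaluates all `choose(K, k)` subsets and requires
#' that count to fit in `max_evals`; the random strategy draws
#' `max_evals` distinct subsets uniformly.
#'
#' @param x A washed, normalized `descriptor_tbl`.
#' @param k Subset size, `1 <= k <= K`.
#' @param strategy `"exhaustive"` or `"random"`.
#' @param max_evals Evaluation budget.
#' @param config A [run_config()] governing splitting and training.
#' @param score `"min"` (default) or `"sum"` aggregation of q2_train and
#'   r2_test.
#' @param cores Subsets evaluated in parallel with this many workers;
#'   results are reduced in evaluation order so they are identical to a
#'   serial run.  Default 1.
#' @return An object of class `selection_run`: `results` (one row per
#'   evaluated subset), `best` (descriptor names), `best_model` (the
#'   refitted `qsar_model`), `K`, `k`, `strategy`, `n_evaluated`,
#'   `any_accepted`.
#' @export
select_descriptors <- function(x, k, strategy = c("exhaustive", "random"),
                               max_evals = 1000L, config = run_config(),
                               score = c("min", "sum"), cores = 1L) {
  strategy <- match.arg(strategy)
  score <- match.arg(score)
  stopifnot(inherits(x, "descriptor_tbl"))
  K <- n_descriptors(x)
  check_scalar_number(k, "k", 1, K, integerish = TRUE)
  check_scalar_number(max_evals, "max_evals", 1, Inf, integerish = TRUE)
  all_names <- descriptor_names(x)

  n_total <- choose(K, k)
  if (strategy == "exhaustive") {
    if (n_total > max_evals) {
      abort(sprintf("Exhaustive search needs %g evaluations but max_evals = %d; raise the budget or use strategy = \"random\".",
                    n_total, max_evals),
            class = "qsardnn_validation_error")
    }
    subsets <- combn(K, k, simplify = FALSE)
  } else {
    n_draw <- min(max_evals, n_total)
    subsets <- withr::with_seed(derive_seed(config$seed, "subset"), {
      if (n_total <= 1e5) {
        all_subsets <- combn(K, k, simplify = FALSE)
        all_subsets[sample.int(length(all_subsets), n_draw)]
      } else {
        seen <- new.env(parent = emptyenv())
        out <- list()
        while (length(out) < n_draw) {
          s <- sort(sample.int(K, k))
          key <- paste(s, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            out[[length(out) + 1L]] <- s
          }
        }
        out
      }
    })
  }

  qlog("select: evaluating ", length(subsets), " subset(s) of size ", k,
       " out of K = ", K, " (", strategy, ")")

  eval_subset <- function(cols) {
    tbl_k <- restrict_table(x, descriptors = all_names[cols])
    split <- sphere_exclusion_split(tbl_k,
                                    test_fraction = config$test_fraction)
    fit <- train_qsar(tbl_k, split = split, config = config)
    r <- fit$report
    list(fit = fit,
         row = tibble(descriptors = paste(all_names[cols], collapse = "+"),
                      q2_train = r$q2_train, q2_test = r$q2_test,
                      r2_test = r$r2_test,
                      score = if (score == "min") min(r$q2_train, r$r2_test)
                              else r$q2_train + r$r2_test,
                      accepted = accept_model(r, config$q2_threshold,
                                              config$r2_threshold),
                      stopping_epoch = r$stopping_epoch))
  }

  evaluated <- if (cores > 1L) {
    parallel::mclapply(subsets, eval_subset, mc.cores = cores)
  } else {
    lapply(subsets, eval_subset)
  }

  results <- dplyr::bind_rows(lapply(evaluated, `[[`, "row"))
  results$subset_id <- seq_len(nrow(results))
  results <- dplyr::relocate(results, "subset_id")

  best_i <- 1L
  for (i in seq_len(nrow(results))) {
    better <- results$score[i] > results$score[best_i] ||
      (results$score[i] == results$score[best_i] &&
         results$r2_test[i] > results$r2_test[best_i])
    if (i > 1L && better) best_i <- i
  }
  any_accepted <- any(results$accepted)
  if (!any_accepted) {
    warn("No evaluated subset met the acceptance thresholds; returning the best scoring one anyway.")
  }
  structure(list(results = results,
                 best = all_names[subsets[[best_i]]],
                 best_model = evaluated[[best_i]]$fit,
                 K = K, k = as.integer(k), strategy = strategy,
                 max_evals = as.integer(max_evals),
                 n_evaluated = nrow(results),
                 any_accepted = any_accepted,
                 seed = config$seed),
            class = "selection_run")
}

#' @export
print.selection_run <- function(x, ...) {
  cat(sprintf("<selection_run> %s, %d/%g subsets of size %d from K = %d\n",
              x$strategy, x$n_evaluated, choose(x$K, x$k), x$k, x$K))
  cat(sprintf("  best: %s (score %.3f)%s\n",
              paste(x$best, collapse = "+"),
              max(x$results$score),
              if (x$any_accepted) "" else "  [no subset accepted]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.selection_run <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.selection_run <- function(x, ...) {
  tibble(K = x$K, k = x$k, strategy = x$strategy,
         n_evaluated = x$n_evaluated,
         best_descriptors = paste(x$best, collapse = "+"),
         best_score = max(x$results$score),
         any_accepted = x$any_accepted)
}

#' @exportS3Method ggplot2::autoplot
autoplot.selection_run <- function(object, ...) {
  d <- object$results
  d$is_best <- d$subset_id == d$subset_id[which.max(d$score)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q2_train, y = .data$r2_test,
                                  colour = .data$is_best)) +
    ggplot2::geom_point(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey40",
                                            "TRUE" = "red")) +
    ggplot2::labs(x = expression(q^2 ~ "(train)"),
                  y = expression(r^2 ~ "(test)"),
                  title = "Descriptor-subset search") +
    ggplot2::theme_minimal()
}
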