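# Run configuration: defaults, validation, and the XML parameter file.

#' Build a run configuration
#'
#' Collects every tunable of the pipeline in one validated list.  All
#' arguments have documented defaults; an XML parameter file
#' ([parse_run_config()]) overrides any subset of them.
#'
#' @param corr_threshold Pearson-correlation tolerance for descriptor
#'   pruning, in (0, 1].  Default 0.95.
#' @param sigma Pauta multiplier: a compound is an outlier when its
#'   activity deviates more than `sigma` local standard deviations from its
#'   neighborhood mean.  Default 3 (the 3-sigma rule).
#' @param min_neighbors A flagged deviation only counts when the compound
#'   has strictly more than this many neighbors in descriptor space.
#'   Default 10.
#' @param radius_quantile Quantile of all pairwise Euclidean distances used
#'   as the neighborhood radius.  Default 0.1.
#' @param normalization `"zscore"` or `"minmax"`.
#' @param test_fraction Target test-set fraction for sphere-exclusion
#'   splitting, in (0, 1).  Default 0.2.
#' @param hidden_layers Integer vector of hidden-layer widths.  Default
#'   `c(20, 20, 20)`.
#' @param dropout Hidden-layer dropout rate in \[0, 1).  Default 0:
#'   dropout is worthwhile for wide/deep architectures whose parameter
#'   count dwarfs the compound count, but it puts a noise floor under the
#'   fit of the default-sized network, which weight decay and early
#'   stopping already regularize.
#' @param lambda L2 weight-decay coefficient.  Default 1e-4.
#' @param learning_rate SGD step size on the q2 cost scale (the gradient
#'   of the -q2 term is the mean-squared-error gradient divided by
#'   `sum((y - mean(y))^2)`, so order-1 steps are appropriate).  Default 1.
#' @param batch_size Mini-batch size d.  Default 16.
#' @param max_epochs Epoch budget.  Default 2000.
#' @param eval_interval Epochs between held-out cost evaluations.
#'   Default 10.
#' @param patience Consecutive non-improving evaluations before early
#'   stopping.  Default 20.
#' @param use_bias Include per-node bias terms.  Default `TRUE` (biases are
#'   never penalised by weight decay).
#' @param k Descriptor-subset size for variable selection.  Default 2.
#' @param strategy `"exhaustive"` or `"random"` subset search.
#' @param max_evals Budget of subsets to evaluate.  Default 1000.
#' @param q2_threshold,r2_threshold Model-acceptance thresholds.  Defaults
#'   0.60 and 0.55.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.  Default 1.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(corr_threshold = 0.95,
                       sigma = 3,
                       min_neighbors = 10L,
                       radius_quantile = 0.1,
                       normalization = c("zscore", "minmax"),
                       test_fraction = 0.2,
                       hidden_layers = c(20L, 20L, 20L),
                       dropout = 0,
                       lambda = 1e-4,
                       learning_rate = 1,
                       batch_size = 16L,
                       max_epochs = 2000L,
                       eval_interval = 10L,
                       patience = 20L,
                       use_bias = TRUE,
                       k = 2L,
                       strategy = c("exhaustive", "random"),
                       max_evals = 1000L,
                       q2_threshold = 0.60,
                       r2_threshold = 0.55,
                       seed = 1L) {
  normalization <- match.arg(normalization)
  strategy <- match.arg(strategy)
  check_scalar_number(corr_threshold, "corr_threshold", 0, 1, open_lower = TRUE)
  check_scalar_number(sigma, "sigma", 0, Inf, open_lower = TRUE)
  check_scalar_number(min_neighbors, "min_neighbors", 0, Inf, integerish = TRUE)
  check_scalar_number(radius_quantile, "radius_quantile", 0, 1, open_lower = TRUE)
  check_scalar_number(test_fraction, "test_fraction", 0, 1,
                      open_lower = TRUE, open_upper = TRUE)
  if (length(hidden_layers) < 1L || any(hidden_layers < 1) ||
      any(hidden_layers != round(hidden_layers))) {
    abort("`hidden_layers` must be positive integers.",
          class = "qsardnn_validation_error")
  }
  check_scalar_number(dropout, "dropout", 0, 1, open_upper = TRUE)
  check_scalar_number(lambda, "lambda", 0, Inf)
  check_scalar_number(learning_rate, "learning_rate", 0, Inf, open_lower = TRUE)
  for (nm in c("batch_size", "max_epochs", "eval_interval", "k", "max_evals")) {
    check_scalar_number(get(nm), nm, 1, Inf, integerish = TRUE)
  }
  check_scalar_number(patience, "patience", 0, Inf, integerish = TRUE)
  check_scalar_number(q2_threshold, "q2_threshold", -Inf, 1)
  check_scalar_number(r2_threshold, "r2_threshold", 0, 1)
  check_scalar_number(seed, "seed", -2^31, 2^31, integerish = TRUE)
  if (!is.logical(use_bias) || length(use_bias) != 1L || is.na(use_bias)) {
    abort("`use_bias` must be TRUE or FALSE.", class = "qsardnn_validation_error")
  }
  structure(list(
    corr_threshold = corr_threshold, sigma = sigma,
    min_neighbors = as.integer(min_neighbors),
    radius_quantile = radius_quantile, normalization = normalization,
    test_fraction = test_fraction,
    hidden_layers = as.integer(hidden_layers), dropout = dropout,
    lambda = lambda, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    eval_interval = as.integer(eval_interval), patience = as.integer(patience),
    use_bias = use_bias,
    k = as.integer(k), strategy = strategy, max_evals = as.integer(max_evals),
    q2_threshold = q2_threshold, r2_threshold = r2_threshold,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# element -> (section, run_config argument, parser)
xml_schema <- function() {
  num <- function(v) as.numeric(v)
  int <- function(v) as.integer(round(as.numeric(v)))
  chr <- function(v) v
  lgl <- function(v) as.logical(toupper(v))
  ints <- function(v) as.integer(trimws(strsplit(v, ",")[[1]]))
  list(
    wash = list(corr_threshold = num, sigma = num, min_neighbors = int,
                radius_quantile = num, normalization = chr),
    split = list(test_fraction = num),
    network = list(hidden_layers = ints, dropout = num, lambda = num,
                   learning_rate = num, batch_size = int, max_epochs = int,
                   eval_interval = int, patience = int, use_bias = lgl),
    varselect = list(k = int, strategy = chr, max_evals = int,
                     q2_threshold = num, r2_threshold = num),
    seed = int
  )
}

#' Parse an XML parameter file
#'
#' Reads a `<qsardnn>` document and returns a [run_config()] in which every
#' element present in the file overrides the documented default.  Unknown
#' elements are errors, not warnings: a silently ignored typo in a
#' parameter name would corrupt an experiment.
#'
#' An empty `<qsardnn/>` document yields the all-defaults configuration.
#' The recognised elements are `<wash>` (`corr_threshold`, `sigma`,
#' `min_neighbors`, `radius_quantile`, `normalization`), `<split>`
#' (`test_fraction`), `<network>` (`hidden_layers` as a comma list,
#' `dropout`, `lambda`, `learning_rate`, `batch_size`, `max_epochs`,
#' `eval_interval`, `patience`, `use_bias`), `<varselect>` (`k`,
#' `strategy`, `max_evals`, `q2_threshold`, `r2_threshold`) and `<seed>`.
#'
#' @param path Path to the XML file.
#' @return A `run_config`.
#' @export
parse_run_config <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(sprintf("Malformed XML in %s: %s", path, conditionMessage(e)),
          class = "qsardnn_parse_error")
  })
  root <- xml2::xml_name(doc)
  if (root != "qsardnn") {
    abort(sprintf("Expected root element <qsardnn>, found <%s>.", root),
          class = "qsardnn_parse_error")
  }
  schema <- xml_schema()
  overrides <- list()
  for (section in xml2::xml_children(doc)) {
    sec_name <- xml2::xml_name(section)
    if (identical(sec_name, "seed")) {
      overrides$seed <- schema$seed(xml2::xml_text(section))
      next
    }
    if (!sec_name %in% setdiff(names(schema), "seed")) {
      abort(sprintf("Unknown configuration element <%s>.", sec_name),
            class = "qsardnn_config_error")
    }
    for (el in xml2::xml_children(section)) {
      el_name <- xml2::xml_name(el)
      parser <- schema[[sec_name]][[el_name]]
      if (is.null(parser)) {
        abort(sprintf("Unknown configuration element <%s> in <%s>.",
                      el_name, sec_name),
              class = "qsardnn_config_error")
      }
      value <- parser(xml2::xml_text(el))
      if (anyNA(value)) {
        abort(sprintf("Cannot parse value of <%s> (\"%s\").",
                      el_name, xml2::xml_text(el)),
              class = "qsardnn_parse_error")
      }
      overrides[[el_name]] <- value
    }
  }
  tryCatch(do.call(run_config, overrides), error = function(e) {
    if (inherits(e, "qsardnn_validation_error")) {
      abort(sprintf("Invalid configuration value in %s: %s",
                    path, conditionMessage(e)),
            class = "qsardnn_validation_error")
    }
    abort(conditionMessage(e), class = "qsardnn_config_error")
  })
}

#' Write a run configuration as XML
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  schema <- xml_schema()
  doc <- xml2::xml_new_root("qsardnn")
  for (sec in setdiff(names(schema), "seed")) {
    node <- xml2::xml_add_child(doc, sec)
    for (el in names(schema[[sec]])) {
      v <- config[[el]]
      txt <- if (is.logical(v)) tolower(as.character(v)) else
        paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
              collapse = ",")
      xml2::xml_add_child(node, el, txt)
    }
  }
  xml2::xml_add_child(doc, "seed", as.character(config$seed))
  xml2::write_xml(doc, path)
  invisible(path)
}
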