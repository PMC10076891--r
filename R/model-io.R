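# Model persistence: portable JSON text with weights stored as decimal
# strings at full (%.17g) precision, so load(save(m)) reproduces
# predictions bit-identically and the file stays diffable and
# language-neutral.

MODEL_FORMAT_VERSION <- "qsardnn-model-1"

num_to_str <- function(x) sprintf("%.17g", x)
str_to_num <- function(s) as.numeric(s)

#' Save a fitted QSAR model as portable JSON
#'
#' Records layer sizes, weights, biases, activation name, normalization
#' parameters, selected descriptor names, the activity name and a config
#' snapshot.  Floating-point values are written as 17-significant-digit
#' decimal strings, enough to round-trip an IEEE double exactly.
#'
#' @param model A `qsar_model` from [train_qsar()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  net <- model$net
  payload <- list(
    format = MODEL_FORMAT_VERSION,
    layer_sizes = net$layer_sizes,
    activation = net$activation,
    use_bias = !is.null(net$biases),
    weights = lapply(net$weights, function(w) {
      list(nrow = nrow(w), ncol = ncol(w), data = num_to_str(as.vector(w)))
    }),
    biases = if (!is.null(net$biases)) lapply(net$biases, num_to_str),
    normalization = list(
      descriptor = model$normalization$descriptor,
      mode = model$normalization$mode,
      location = num_to_str(model$normalization$location),
      scale = num_to_str(model$normalization$scale)
    ),
    descriptors = model$descriptors,
    activity = model$activity,
    train_ids = model$train_ids,
    train_matrix = num_to_str(as.vector(model$train_matrix)),
    train_activity = num_to_str(model$train_activity),
    report = model$report,
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a QSAR model saved by [save_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `qsar_model` whose predictions are bit-identical to the saved
#'   model's.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path),
          class = "qsardnn_data_error")
  }
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      abort(sprintf("Cannot read model file %s (truncated or not JSON): %s",
                    path, conditionMessage(e)),
            class = "qsardnn_parse_error")
    })
  if (!identical(payload$format, MODEL_FORMAT_VERSION)) {
    abort(sprintf("Model format \"%s\" does not match the supported \"%s\".",
                  payload$format %||% "<missing>", MODEL_FORMAT_VERSION),
          class = "qsardnn_version_error")
  }
  required <- c("layer_sizes", "weights", "normalization", "descriptors",
                "activity")
  missing <- setdiff(required, names(payload))
  if (length(missing) > 0L) {
    abort(sprintf("Model file is missing field(s): %s (truncated?).",
                  paste(missing, collapse = ", ")),
          class = "qsardnn_parse_error")
  }
  layer_sizes <- as.integer(unlist(payload$layer_sizes))
  weights <- lapply(payload$weights, function(w) {
    matrix(str_to_num(unlist(w$data)),
           as.integer(w$nrow), as.integer(w$ncol))
  })
  biases <- if (isTRUE(payload$use_bias)) {
    lapply(payload$biases, function(b) str_to_num(unlist(b)))
  }
  net <- structure(list(layer_sizes = layer_sizes, weights = weights,
                        biases = biases,
                        activation = payload$activation),
                   class = "network_params")
  descriptors <- unlist(payload$descriptors)
  train_ids <- unlist(payload$train_ids)
  norm <- tibble(descriptor = unlist(payload$normalization$descriptor),
                 mode = unlist(payload$normalization$mode),
                 location = str_to_num(unlist(payload$normalization$location)),
                 scale = str_to_num(unlist(payload$normalization$scale)))
  train_matrix <- matrix(str_to_num(unlist(payload$train_matrix)),
                         nrow = length(train_ids),
                         ncol = length(descriptors))
  colnames(train_matrix) <- descriptors
  config <- if (!is.null(payload$config)) {
    do.call(run_config, lapply(payload$config, unlist))
  }
  report <- lapply(payload$report, unlist)
  structure(list(net = net, state = NULL, normalization = norm,
                 descriptors = descriptors,
                 activity = payload$activity, split = NULL,
                 train_matrix = train_matrix,
                 train_activity = str_to_num(unlist(payload$train_activity)),
                 train_ids = train_ids,
                 config = config, report = report),
            class = "qsar_model")
}
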