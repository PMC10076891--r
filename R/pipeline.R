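# Pipeline orchestration: simulate -> wash -> split -> train/select ->
# predict, every stage materialising its artifacts to disk so a completed
# run is fully reproducible from the config snapshot and master seed.

#' Run the modelling pipeline
#'
#' Executes the requested stages in their declared order, writing every
#' intermediate artifact under `out_dir`:
#'
#' * `simulate` -- synthetic descriptor CSV plus a ground-truth JSON
#'   sidecar (skipped when `input` points at a real table);
#' * `wash` -- normalization, Pauta outlier removal and correlation
#'   pruning; writes the washed CSV and the wash-report CSV;
#' * `split` -- sphere-exclusion division; writes train/test ID lists and
#'   a JSON summary;
#' * `train` -- fits the network on the split; writes the model JSON, the
#'   per-epoch cost trajectory CSV and a model-report JSON;
#' * `select` -- descriptor-subset search instead of a single fit; writes
#'   the per-subset CSV and the best model;
#' * `predict` -- predictions (with applicability distances) for the test
#'   set, written as CSV.
#'
#' A stage failure halts the run; artifacts of completed stages are
#' retained.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names, in order.
#' @param input Path to a descriptor CSV (required unless `simulate` is
#'   the first stage).
#' @param out_dir Output directory, created if needed.
#' @param activity Name of the activity column.  Default `"activity"`.
#' @return A tibble (class `pipeline_run`): one row per executed stage
#'   with its elapsed seconds and output paths.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "wash", "split", "train",
                                    "predict"),
                         input = NULL, out_dir = "qsardnn_run",
                         activity = "activity") {
  known <- c("simulate", "wash", "split", "train", "select", "predict")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")),
          class = "qsardnn_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!"simulate" %in% stages) {
    if (is.null(input) || !file.exists(input)) {
      abort(sprintf("Input file not found: %s", input %||% "<NULL>"),
            class = "qsardnn_data_error")
    }
  }
  write_run_config(config, file.path(out_dir, "config.xml"))

  tbl <- NULL; split <- NULL; model <- NULL
  rows <- list()
  p <- function(...) file.path(out_dir, ...)

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- character()
    qlog("pipeline: stage ", stage, " (seed ", config$seed, ")")
    switch(stage,
      simulate = {
        tbl <- simulate_descriptor_table(seed = config$seed)
        write_descriptor_table(tbl, p("simulated.csv"))
        truth <- simulation_truth(tbl)
        jsonlite::write_json(truth, p("simulated_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        outputs <- c(p("simulated.csv"), p("simulated_truth.json"))
      },
      wash = {
        if (is.null(tbl)) tbl <- read_descriptor_table(input, activity)
        tbl <- wash_table(tbl, config)
        write_descriptor_table(tbl, p("washed.csv"))
        readr::write_csv(wash_report(tbl), p("wash_report.csv"),
                         progress = FALSE)
        outputs <- c(p("washed.csv"), p("wash_report.csv"))
      },
      split = {
        if (is.null(tbl)) tbl <- read_descriptor_table(input, activity)
        split <- sphere_exclusion_split(tbl, config$test_fraction)
        writeLines(split$train_ids, p("train_ids.txt"))
        writeLines(split$test_ids, p("test_ids.txt"))
        jsonlite::write_json(
          list(radius = split$radius, seed_compound = split$seed_compound,
               test_fraction = split$test_fraction, target = split$target,
               n_train = length(split$train_ids),
               n_test = length(split$test_ids)),
          p("split.json"), auto_unbox = TRUE, digits = NA)
        outputs <- p(c("train_ids.txt", "test_ids.txt", "split.json"))
      },
      train = {
        if (is.null(tbl)) tbl <- read_descriptor_table(input, activity)
        model <- train_qsar(tbl, split = split, config = config)
        save_model(model, p("model.json"))
        readr::write_csv(tidy(model$state), p("train_state.csv"),
                         progress = FALSE)
        jsonlite::write_json(model$report, p("model_report.json"),
                             auto_unbox = TRUE, digits = NA)
        outputs <- p(c("model.json", "train_state.csv", "model_report.json"))
      },
      select = {
        if (is.null(tbl)) tbl <- read_descriptor_table(input, activity)
        run <- select_descriptors(tbl, k = config$k,
                                  strategy = config$strategy,
                                  max_evals = config$max_evals,
                                  config = config)
        readr::write_csv(run$results, p("selection.csv"), progress = FALSE)
        model <- run$best_model
        save_model(model, p("model.json"))
        outputs <- p(c("selection.csv", "model.json"))
      },
      predict = {
        if (is.null(model)) {
          abort("Stage `predict` needs a trained model; run `train` or `select` first (or load a model file).",
                class = "qsardnn_config_error")
        }
        target_tbl <- if (!is.null(tbl) && !is.null(model$split)) {
          restrict_table(tbl, rows = match(model$split$test_ids,
                                           compound_ids(tbl)))
        } else tbl
        pred <- predict(model, target_tbl, applicability = TRUE)
        pred$observed <- activity_values(target_tbl)
        readr::write_csv(pred, p("predictions.csv"), progress = FALSE)
        outputs <- p("predictions.csv")
      }
    )
    rows[[stage]] <- tibble(stage = stage,
                            seconds = proc.time()[["elapsed"]] - t0,
                            outputs = paste(outputs, collapse = ";"))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pipeline_run", class(out))
  readr::write_csv(as_tibble(out), p("pipeline_run.csv"), progress = FALSE)
  out
}
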