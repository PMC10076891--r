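# Descriptor tables: compounds x named molecular descriptors plus one
# activity column.  A descriptor_tbl is a tibble whose first column holds
# the compound IDs, with the activity column name carried as an attribute;
# every other numeric column is a descriptor.

new_descriptor_tbl <- function(data, activity, id = "compound_id") {
  structure(as_tibble(data),
            activity = activity, id_col = id,
            class = c("descriptor_tbl", class(as_tibble(data))))
}

#' Build a descriptor table from a data frame
#'
#' A descriptor table is the central data structure of the package: one row
#' per compound, one named numeric column per molecular descriptor, a
#' compound-ID column and a single activity column (e.g. pIC50 or LAC50).
#'
#' @param data A data frame or tibble.
#' @param activity Name of the activity column in `data`.
#' @param id Name of the compound-ID column.  Default `"compound_id"`.
#' @param exclude Character vector of metadata columns to drop (they are
#'   neither descriptors nor the activity).
#' @return A `descriptor_tbl`, a tibble subclass.
#' @examples
#' df <- data.frame(compound_id = c("a", "b", "c"),
#'                  logP = c(1.2, 0.4, 2.2), tpsa = c(40, 80, 20),
#'                  pIC50 = c(5.1, 6.3, 4.8))
#' descriptor_table(df, activity = "pIC50")
#' @export
descriptor_table <- function(data, activity, id = "compound_id",
                             exclude = character()) {
  data <- as_tibble(data)
  if (!id %in% names(data)) {
    abort(sprintf("Compound-ID column `%s` not found.", id),
          class = "qsardnn_validation_error")
  }
  if (!is.character(activity) || length(activity) != 1L ||
      !activity %in% names(data)) {
    abort(sprintf("Activity column `%s` not found.", activity %||% "<NULL>"),
          class = "qsardnn_config_error")
  }
  data <- data[, setdiff(names(data), setdiff(exclude, c(id, activity)))]
  ids <- as.character(data[[id]])
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate compound IDs: %s.",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "qsardnn_validation_error")
  }
  if (anyDuplicated(names(data))) {
    abort("Duplicate descriptor names are not allowed.",
          class = "qsardnn_validation_error")
  }
  data[[id]] <- ids
  value_cols <- setdiff(names(data), id)
  for (col in value_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("Column `%s` is not numeric.", col),
            class = "qsardnn_parse_error")
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      abort(sprintf("Non-finite value in column `%s`, row %d (compound `%s`).",
                    col, bad, ids[bad]),
            class = "qsardnn_parse_error")
    }
  }
  new_descriptor_tbl(data, activity = activity, id = id)
}

#' @export
print.descriptor_tbl <- function(x, ...) {
  cat(sprintf("# Descriptor table: %d compounds x %d descriptors (activity: %s)\n",
              n_compounds(x), n_descriptors(x), activity_name(x)))
  NextMethod()
}

#' Accessors for descriptor tables
#'
#' @param x A `descriptor_tbl`.
#' @return `compound_ids()` the character ID vector; `activity_name()` the
#'   activity column name; `activity_values()` the numeric activity vector;
#'   `descriptor_names()` the descriptor column names;
#'   `descriptor_matrix()` the numeric matrix of descriptors with
#'   compound IDs as row names; `n_compounds()`/`n_descriptors()` counts.
#' @name descriptor-accessors
NULL

#' @rdname descriptor-accessors
#' @export
compound_ids <- function(x) as.character(x[[attr(x, "id_col")]])

#' @rdname descriptor-accessors
#' @export
activity_name <- function(x) attr(x, "activity")

#' @rdname descriptor-accessors
#' @export
activity_values <- function(x) x[[attr(x, "activity")]]

#' @rdname descriptor-accessors
#' @export
descriptor_names <- function(x) {
  setdiff(names(x), c(attr(x, "id_col"), attr(x, "activity")))
}

#' @rdname descriptor-accessors
#' @export
descriptor_matrix <- function(x) {
  m <- as.matrix(x[, descriptor_names(x), drop = FALSE])
  rownames(m) <- compound_ids(x)
  m
}

#' @rdname descriptor-accessors
#' @export
n_compounds <- function(x) nrow(x)

#' @rdname descriptor-accessors
#' @export
n_descriptors <- function(x) length(descriptor_names(x))

# Rebuild a descriptor_tbl after row/column subsetting, carrying the
# wash/normalization metadata along (normalization params restricted to
# the kept descriptors).
restrict_table <- function(x, rows = NULL, descriptors = NULL) {
  id <- attr(x, "id_col"); act <- attr(x, "activity")
  keep <- c(id, descriptors %||% descriptor_names(x), act)
  out <- as_tibble(x)[rows %||% seq_len(nrow(x)), keep]
  out <- new_descriptor_tbl(out, activity = act, id = id)
  norm <- attr(x, "normalization")
  if (!is.null(norm)) {
    attr(out, "normalization") <- norm[norm$descriptor %in% keep, , drop = FALSE]
  }
  attr(out, "wash") <- attr(x, "wash")
  out
}

#' Read a descriptor table from CSV
#'
#' Expects a UTF-8, comma-separated file with a mandatory header whose first
#' column is `compound_id`.  Every cell of a descriptor or activity column
#' must parse as a decimal number (decimal point, never comma); any cell
#' that does not is reported with its row and column.
#'
#' @param path Path to the CSV file.
#' @param activity Name of the activity column.
#' @param id Name of the compound-ID column (default `"compound_id"`).
#' @param exclude Metadata columns to drop by name.
#' @param impute_mean If `TRUE`, missing descriptor cells are replaced by
#'   the column mean instead of raising an error.  Missing activity values
#'   are always an error.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, activity, id = "compound_id",
                                  exclude = character(),
                                  impute_mean = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "qsardnn_data_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, locale = readr::locale(decimal_mark = "."))
  if (!activity %in% names(raw)) {
    abort(sprintf("Activity column `%s` missing from %s.", activity, path),
          class = "qsardnn_config_error")
  }
  if (!id %in% names(raw)) {
    abort(sprintf("Compound-ID column `%s` missing from %s.", id, path),
          class = "qsardnn_parse_error")
  }
  raw <- raw[, setdiff(names(raw), setdiff(exclude, c(id, activity)))]
  for (col in setdiff(names(raw), id)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      if (impute_mean && col != activity) {
        v[bad] <- mean(v, na.rm = TRUE)
      } else {
        abort(sprintf("Cannot parse cell as a number: column `%s`, row %d (value \"%s\").",
                      col, bad[1L], raw[[col]][bad[1L]]),
              class = "qsardnn_parse_error")
      }
    }
    raw[[col]] <- v
  }
  descriptor_table(raw, activity = activity, id = id)
}

#' Write a descriptor table to CSV
#'
#' The inverse of [read_descriptor_table()]: doubles are written with
#' round-trippable precision so read-after-write reproduces the table
#' exactly.
#'
#' @param x A `descriptor_tbl`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_descriptor_table <- function(x, path) {
  stopifnot(inherits(x, "descriptor_tbl"))
  readr::write_csv(as_tibble(x), path, progress = FALSE)
  invisible(x)
}

#' Read a binary fingerprint table from CSV
#'
#' Same shape as a descriptor CSV but every non-ID column must be strictly
#' 0/1.  Used for Tanimoto similarity diagnostics.
#'
#' @param path Path to the CSV file.
#' @param id Name of the compound-ID column.
#' @return A tibble with the ID column and integer 0/1 columns.
#' @export
read_fingerprints <- function(path, id = "compound_id") {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!id %in% names(raw)) {
    abort(sprintf("Compound-ID column `%s` missing from %s.", id, path),
          class = "qsardnn_parse_error")
  }
  for (col in setdiff(names(raw), id)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      abort(sprintf("Fingerprint column `%s` contains values other than 0/1.", col),
            class = "qsardnn_parse_error")
    }
    raw[[col]] <- as.integer(v)
  }
  raw
}
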