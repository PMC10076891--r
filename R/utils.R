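# Internal helpers: logging and the seeding contract shared by every
# stochastic operation in the package.

the <- new.env(parent = emptyenv())
the$logfile <- NULL

#' Route package log messages to a file
#'
#' Log lines always go to standard error; `set_logfile()` additionally
#' appends them to `path`.  Use `NULL` to disable the file sink.
#'
#' @param path File path or `NULL`.
#' @return The previous logfile path, invisibly.
#' @export
set_logfile <- function(path = NULL) {
  old <- the$logfile
  the$logfile <- path
  invisible(old)
}

qlog <- function(..., .envir = parent.frame()) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  message(line)
  if (!is.null(the$logfile)) {
    cat(line, "\n", file = the$logfile, append = TRUE, sep = "")
  }
  invisible(line)
}

# One master seed deterministically derives the seeds of every stochastic
# sub-operation (weight init, epoch shuffles, dropout masks, subset
# sampling).  The derivation is a fixed affine map modulo 2^31 - 1 so the
# derived seeds stay valid 32-bit integers and distinct streams never
# collide for master seeds below ~2e9.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  streams <- c(init = 1, shuffle = 2, dropout = 3, subset = 4,
               simulate = 5, split = 6, pipeline = 7)
  k <- streams[[match.arg(stream, names(streams))]]
  as.integer((abs(master) * 7 + k * 104729) %% (2^31 - 1))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "qsardnn_validation_error")
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its allowed range %s%g, %g%s.",
                  name, x, if (open_lower) "(" else "[", lower, upper,
                  if (open_upper) ")" else "]"),
          class = "qsardnn_validation_error")
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be an integer.", name),
          class = "qsardnn_validation_error")
  }
  invisible(x)
}
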