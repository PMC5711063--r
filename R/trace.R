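#' Uniformly sampled motion / voltage trace
#'
#' The basic time-series container of the pipeline: a displacement trace (mm,
#' superior-inferior axis) or a surrogate voltage trace (V), sampled uniformly
#' at interval `dt` starting at `t0`.
#'
#' @param values numeric vector of samples (mm or V), finite, length >= 2.
#' @param dt sampling interval in seconds, > 0.
#' @param t0 time of the first sample in seconds.
#' @param kind `"displacement"` or `"voltage"`.
#' @return An object of class `resp_trace`: a list with fields `t0`, `dt`,
#'   `values` and `kind`.  Duration is `(length(values) - 1) * dt`.
#' @examples
#' tr <- resp_trace(sin(seq(0, 2 * pi, length.out = 101)), dt = 0.01)
#' trace_duration(tr)
#' @export
resp_trace <- function(values, dt, t0 = 0,
                       kind = c("displacement", "voltage")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("a trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("trace values must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  structure(list(t0 = as.numeric(t0), dt = dt, values = values, kind = kind),
            class = "resp_trace")
}

#' @rdname resp_trace
#' @param x a `resp_trace`.
#' @export
is_resp_trace <- function(x) inherits(x, "resp_trace")

stopifnot_trace <- function(x, kind = NULL, arg = deparse(substitute(x))) {
  if (!is_resp_trace(x)) {
    stop(sprintf("`%s` must be a resp_trace", arg), call. = FALSE)
  }
  if (!is.null(kind) && x$kind != kind) {
    stop(sprintf("`%s` must be a %s trace, got a %s trace",
                 arg, kind, x$kind), call. = FALSE)
  }
  invisible(x)
}

#' @rdname resp_trace
#' @export
trace_times <- function(x) {
  stopifnot_trace(x)
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @rdname resp_trace
#' @export
trace_duration <- function(x) {
  stopifnot_trace(x)
  (length(x$values) - 1) * x$dt
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %s, %d samples @ %g s (%.3g s), range [%.4g, %.4g] %s\n",
              x$kind, length(x$values), x$dt, trace_duration(x),
              min(x$values), max(x$values),
              if (x$kind == "displacement") "mm" else "V"))
  invisible(x)
}

#' @export
as.data.frame.resp_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$values)
}

#' Read and write traces as two-column CSV
#'
#' The on-disk format is a CSV with header `time_s,value`, strictly
#' increasing, uniformly sampled time column.  A write/read round trip
#' reproduces the sample values to better than 1e-9.
#'
#' @param path file path.
#' @param kind trace kind to assign on read (the file stores no unit).
#' @return `read_trace` returns a [resp_trace]; `write_trace` invisibly
#'   returns `path`.
#' @export
read_trace <- function(path, kind = c("displacement", "voltage")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("time_s", "value"))) {
    stop("trace file must have header \"time_s,value\": ", path, call. = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("trace file has fewer than 2 samples: ", path, call. = FALSE)
  }
  steps <- diff(df$time_s)
  dt <- steps[1]
  if (dt <= 0) {
    stop("time column not strictly increasing at row 2 of ", path,
         call. = FALSE)
  }
  bad <- which(abs(steps - dt) > 1e-6 * dt)
  if (length(bad) > 0L) {
    stop(sprintf("non-uniform sampling in %s: row %d has step %g, expected %g",
                 path, bad[1] + 2L, steps[bad[1]], dt), call. = FALSE)
  }
  resp_trace(df$value, dt = dt, t0 = df$time_s[1], kind = kind)
}

#' @rdname read_trace
#' @param trace a [resp_trace].
#' @export
write_trace <- function(trace, path) {
  stopifnot_trace(trace)
  df <- as.data.frame(trace)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("time_s,value", con, sep = "\n")
  writeLines(paste(format(df$time_s, digits = 15, trim = TRUE, scientific = FALSE),
                   format(df$value, digits = 17, trim = TRUE),
                   sep = ","),
             con, sep = "\n")
  invisible(path)
}
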