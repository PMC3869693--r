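#' Construct a stopped-flow trace
#'
#' A relaxation time course from a rapid-mixing experiment: scattered
#' light intensity (osmotic shrink/swell), probe fluorescence during
#' H2O/D2O exchange, or pH-probe fluorescence (ammonia, proton uptake).
#'
#' @param times Sampling times in s, strictly increasing.
#' @param signal Signal values (arbitrary units), same length as `times`.
#' @param temperature Temperature in K.  The default 288.15 K (15 C)
#'   is the usual working temperature for red-cell stopped-flow assays.
#' @param condition Label: `"osmotic"`, `"D2O-exchange"`, `"NH3"` or
#'   `"H+"`.
#' @param gradient Optional description of the applied gradient
#'   (osmolality or concentration step).
#' @param direction Optional direction label (`"shrink"`, `"swell"`,
#'   `"exchange"`).
#' @return An object of class `stopped_flow_trace`.
#' @export
stopped_flow_trace <- function(times, signal, temperature = 288.15,
                               condition = "osmotic", gradient = NULL,
                               direction = NULL) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) != length(signal))
    stop("times and signal must have the same length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = times, signal = signal,
                 temperature = as.numeric(temperature),
                 condition = condition, gradient = gradient,
                 direction = direction),
            class = "stopped_flow_trace")
}

#' @export
print.stopped_flow_trace <- function(x, ...) {
  cat(sprintf("Stopped-flow trace (%s): %d samples over %.4g s at %.2f K\n",
              x$condition, length(x$times),
              if (length(x$times)) diff(range(x$times)) else 0,
              x$temperature))
  invisible(x)
}

#' @export
plot.stopped_flow_trace <- function(x, ...) {
  plot(x$times, x$signal, type = "l", xlab = "time (s)",
       ylab = "signal (a.u.)", ...)
  invisible(x)
}

#' Write a stopped-flow trace
#'
#' Plain-text format: `#key=value` metadata header lines followed by a
#' two-column (time, signal) table.
#'
#' @param trace A `stopped_flow_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature=%g", trace$temperature), con)
  writeLines(sprintf("# condition=%s", trace$condition), con)
  if (!is.null(trace$gradient))
    writeLines(sprintf("# gradient=%s", trace$gradient), con)
  if (!is.null(trace$direction))
    writeLines(sprintf("# direction=%s", trace$direction), con)
  writeLines("time\tsignal", con)
  writeLines(sprintf("%.8g\t%.8g", trace$times, trace$signal), con)
  invisible(path)
}

#' Read a stopped-flow trace
#'
#' Reads the `#key=value` header + two-column format written by
#' [write_trace()].  Missing metadata fall back to defaults (288.15 K,
#' condition `"osmotic"`) with a warning, so that traces exported by
#' other instruments remain usable.
#'
#' @param path Input file path.
#' @return A `stopped_flow_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("#\\s*([^=\\s]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  has_header <- length(body) > 0 &&
    is.na(suppressWarnings(as.numeric(strsplit(trimws(body[1]),
                                               "[[:space:],;]+")[[1]][1])))
  if (has_header) body <- body[-1]
  if (!length(body)) stop("trace file has no data rows")
  parts <- do.call(rbind, strsplit(trimws(body), "[[:space:],;]+"))
  if (ncol(parts) < 2) stop("trace file needs two numeric columns")
  times <- as.numeric(parts[, 1])
  signal <- as.numeric(parts[, 2])
  if (anyNA(times) || anyNA(signal)) stop("non-numeric values in trace body")
  if (any(diff(times) <= 0)) stop("trace time column must be strictly increasing")
  if (is.null(meta$temperature))
    warning("no temperature in trace header; assuming 288.15 K (15 C)")
  stopped_flow_trace(
    times, signal,
    temperature = if (is.null(meta$temperature)) 288.15
                  else as.numeric(meta$temperature),
    condition = if (is.null(meta$condition)) "osmotic" else meta$condition,
    gradient = meta$gradient, direction = meta$direction)
}
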