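#' Construct an event stream
#'
#' An event stream is the in-memory form of one DVS recording: a
#' data.frame with integer columns `t` (microseconds, non-negative),
#' `x` (column, 0-based), `y` (row, 0-based) and `p` (polarity, +1 for
#' brightening, -1 for dimming), sorted by `t` with the original order
#' preserved among equal timestamps, plus the sensor dimensions as
#' attributes. Coordinates use the common event-camera convention:
#' origin at the top-left, `x` in `[0, width)`, `y` in `[0, height)`.
#'
#' @param t,x,y,p integer vectors of equal length; `p` must be +1/-1.
#' @param sensor_dims integer `c(width, height)` in pixels.
#' @param sort sort by `t` (stable)? Set `FALSE` only if already sorted.
#' @return a data.frame of class `event_stream`.
#' @export
#' @examples
#' ev <- event_stream(t = c(5, 0), x = c(1, 2), y = c(0, 3),
#'                    p = c(1, -1), sensor_dims = c(4, 4))
#' ev$t  # sorted: 0, 5
event_stream <- function(t = integer(), x = integer(), y = integer(),
                         p = integer(), sensor_dims, sort = TRUE) {
  stopifnot(length(sensor_dims) == 2, all(sensor_dims >= 1))
  n <- length(t)
  if (length(x) == 1L) x <- rep_len(x, n)
  if (length(y) == 1L) y <- rep_len(y, n)
  if (length(p) == 1L) p <- rep_len(p, n)
  if (length(x) != n || length(y) != n || length(p) != n) {
    stop("t, x, y, p must have equal length (scalars recycle)")
  }
  ev <- data.frame(t = as.integer(round(t)), x = as.integer(x),
                   y = as.integer(y), p = as.integer(p))
  if (sort && n > 1 && is.unsorted(ev$t)) {
    ev <- ev[order(ev$t, method = "radix"), , drop = FALSE] # stable
    rownames(ev) <- NULL
  }
  attr(ev, "sensor_width") <- as.integer(sensor_dims[1])
  attr(ev, "sensor_height") <- as.integer(sensor_dims[2])
  class(ev) <- c("event_stream", "data.frame")
  validate_event_stream(ev)
}

validate_event_stream <- function(ev) {
  w <- attr(ev, "sensor_width")
  h <- attr(ev, "sensor_height")
  if (nrow(ev)) {
    if (any(ev$t < 0)) stop("timestamps must be non-negative")
    bad <- which(ev$x < 0 | ev$x >= w | ev$y < 0 | ev$y >= h)
    if (length(bad)) {
      stop(sprintf("event %d out of sensor bounds: (x=%d, y=%d) on %dx%d",
                   bad[1], ev$x[bad[1]], ev$y[bad[1]], w, h))
    }
    if (!all(ev$p %in% c(-1L, 1L))) stop("polarity must be +1 or -1")
    if (is.unsorted(ev$t)) stop("events must be non-decreasing in t")
  }
  ev
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d events on a %dx%d sensor\n", nrow(x),
              attr(x, "sensor_width"), attr(x, "sensor_height")))
  if (nrow(x)) {
    cat(sprintf("  t: [%d, %d] us;  +%d / -%d events\n", min(x$t), max(x$t),
                sum(x$p > 0), sum(x$p < 0)))
  }
  invisible(x)
}

#' Sensor dimensions of an event stream
#' @param ev an `event_stream`.
#' @return integer `c(width, height)`.
#' @export
sensor_dims <- function(ev) {
  c(width = attr(ev, "sensor_width"), height = attr(ev, "sensor_height"))
}

#' Read / write event streams as CSV
#'
#' The on-disk text dialect is a header line `t,x,y,p` followed by one
#' integer row per event; polarity is stored as `{0,1}` with 0 encoding
#' -1 (the usual sensor-vendor convention), and mapped back to signed
#' `{-1,+1}` in memory. Row order among equal timestamps is preserved, so
#' a write/read cycle reproduces the stream exactly.
#'
#' @param path file path.
#' @param sensor_dims integer `c(width, height)`; events outside these
#'   bounds are an error.
#' @return `read_events_csv()`: an [event_stream()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' ev <- event_stream(t = c(0, 5, 5), x = c(1, 2, 0), y = c(1, 0, 0),
#'                    p = c(1, -1, 1), sensor_dims = c(4, 4))
#' write_events_csv(ev, f)
#' identical(read_events_csv(f, c(4, 4)), ev)
read_events_csv <- function(path, sensor_dims) {
  if (!file.exists(path)) stop("event CSV not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = ",",
                      colClasses = list(integer = 1:4), fill = FALSE,
                      showProgress = FALSE),
    error = function(e) stop("cannot parse event CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(names(dt), c("t", "x", "y", "p"))) {
    stop("event CSV '", path, "' must have header 't,x,y,p'")
  }
  bad <- which(!stats::complete.cases(dt))
  if (length(bad)) {
    stop(sprintf("malformed row at data line %d of '%s'", bad[1], path))
  }
  if (nrow(dt) && !all(dt$p %in% c(0L, 1L))) {
    stop(sprintf("malformed row at data line %d of '%s': p must be 0 or 1",
                 which(!(dt$p %in% c(0L, 1L)))[1], path))
  }
  event_stream(t = dt$t, x = dt$x, y = dt$y, p = 2L * dt$p - 1L,
               sensor_dims = sensor_dims)
}

#' @param ev an [event_stream()].
#' @rdname read_events_csv
#' @return `write_events_csv()`: `path`, invisibly.
#' @export
write_events_csv <- function(ev, path) {
  stopifnot(inherits(ev, "event_stream"))
  dt <- data.table::data.table(t = ev$t, x = ev$x, y = ev$y,
                               p = as.integer(ev$p > 0))
  ok <- tryCatch({
    data.table::fwrite(dt, path, sep = ",", col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write event CSV to '", path, "'")
  invisible(path)
}

#' Read / write event streams as Parquet
#'
#' Columnar-binary counterpart of the CSV dialect: the four integer event
#' columns under keys `t`, `x`, `y`, `p` (polarity stored as `{0,1}`),
#' with the sensor dimensions carried in the file's schema metadata.
#' Requires the `arrow` package.
#'
#' @inheritParams read_events_csv
#' @param path file path (conventionally `.parquet`).
#' @return `read_events_parquet()`: an [event_stream()];
#'   `write_events_parquet()`: `path`, invisibly.
#' @export
read_events_parquet <- function(path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for Parquet event files")
  }
  if (!file.exists(path)) stop("event file not found: ", path)
  tb <- arrow::read_parquet(path, as_data_frame = FALSE)
  md <- tb$metadata
  if (is.null(md$sensor_width) || is.null(md$sensor_height)) {
    stop("'", path, "' lacks sensor dimension metadata")
  }
  df <- as.data.frame(tb)
  event_stream(t = df$t, x = df$x, y = df$y, p = 2L * df$p - 1L,
               sensor_dims = c(as.integer(md$sensor_width),
                               as.integer(md$sensor_height)))
}

#' @rdname read_events_parquet
#' @export
write_events_parquet <- function(ev, path) {
  if (!requireNamespace("arrow", quietly = TRUE)) {
    stop("the 'arrow' package is required for Parquet event files")
  }
  stopifnot(inherits(ev, "event_stream"))
  tb <- arrow::arrow_table(t = ev$t, x = ev$x, y = ev$y,
                           p = as.integer(ev$p > 0))
  tb$metadata$sensor_width <- as.character(attr(ev, "sensor_width"))
  tb$metadata$sensor_height <- as.character(attr(ev, "sensor_height"))
  arrow::write_parquet(tb, path)
  invisible(path)
}
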