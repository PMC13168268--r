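#' Segment an event stream into particle transits
#'
#' A transit — one particle crossing the illuminated region — shows up as
#' a burst of event activity between quiet stretches. The stream's time
#' span is divided into bins of `bin_us` microseconds; a transit window is
#' a maximal run of consecutive bins whose event count is at least
#' `min_rate`, and active runs separated by fewer than `min_gap` quiet
#' bins are merged into one window (a particle briefly dipping below
#' threshold mid-transit should not split the sample).
#'
#' @param ev an [event_stream()].
#' @param bin_us bin width in microseconds (> 0).
#' @param min_rate minimum events per bin for a bin to count as active
#'   (>= 1).
#' @param min_gap minimum number of consecutive quiet bins that separates
#'   two transits; shorter gaps are bridged.
#' @return a data.frame with columns `t_start`, `t_end` (microseconds,
#'   half-open `[t_start, t_end)`), sorted and disjoint; zero rows if the
#'   stream never reaches `min_rate`.
#' @export
#' @examples
#' ev <- event_stream(t = rep(1000:1019, each = 25), x = 0, y = 0, p = 1,
#'                    sensor_dims = c(2, 2))
#' segment_transits(ev, bin_us = 100, min_rate = 5)
segment_transits <- function(ev, bin_us, min_rate = 1, min_gap = 1) {
  stopifnot(inherits(ev, "event_stream"), bin_us > 0, min_rate >= 1,
            min_gap >= 1)
  empty <- data.frame(t_start = integer(), t_end = integer())
  if (!nrow(ev)) return(empty)
  t0 <- min(ev$t)
  bins <- (ev$t - t0) %/% as.integer(bin_us) # 0-based bin index
  counts <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  active <- counts >= min_rate
  if (!any(active)) return(empty)
  # bridge quiet gaps shorter than min_gap between active runs
  r <- rle(active)
  if (length(r$lengths) > 2) {
    interior <- seq(2L, length(r$lengths) - 1L)
    bridge <- interior[!r$values[interior] & r$lengths[interior] < min_gap]
    r$values[bridge] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    t_start = t0 + (starts[keep] - 1L) * as.integer(bin_us),
    t_end = t0 + ends[keep] * as.integer(bin_us)
  )
}

#' Accumulate an event window into per-polarity count grids
#'
#' Counts, per pixel, the positive and negative events with timestamps in
#' the half-open window `[t_start, t_end)`. The two `height x width`
#' integer matrices (row `y + 1`, column `x + 1`) together conserve the
#' event count of the window.
#'
#' @param ev an [event_stream()].
#' @param window numeric `c(t_start, t_end)` in microseconds, or a
#'   one-row data.frame as returned by [segment_transits()]. Defaults to
#'   the full stream span.
#' @return an object of class `event_frame`: a list with integer matrices
#'   `pos` and `neg` and the `window` used.
#' @export
#' @examples
#' ev <- event_stream(t = c(0, 1, 2), x = c(1, 1, 1), y = c(2, 2, 2),
#'                    p = c(1, 1, -1), sensor_dims = c(4, 4))
#' fr <- accumulate_frame(ev)
#' fr$pos[3, 2]  # 2 positive events at (x=1, y=2)
accumulate_frame <- function(ev, window = NULL) {
  stopifnot(inherits(ev, "event_stream"))
  w <- attr(ev, "sensor_width")
  h <- attr(ev, "sensor_height")
  if (is.null(window)) {
    window <- if (nrow(ev)) c(min(ev$t), max(ev$t) + 1) else c(0, 1)
  }
  if (is.data.frame(window)) window <- c(window$t_start[1], window$t_end[1])
  if (!(length(window) == 2 && window[1] < window[2])) {
    stop("window must satisfy t_start < t_end")
  }
  sel <- ev$t >= window[1] & ev$t < window[2]
  idx <- ev$y[sel] * w + ev$x[sel] + 1L # row-major pixel id, then reshaped
  pol <- ev$p[sel]
  np <- w * h
  pos <- matrix(tabulate(idx[pol > 0], nbins = np), nrow = h, ncol = w,
                byrow = TRUE)
  neg <- matrix(tabulate(idx[pol < 0], nbins = np), nrow = h, ncol = w,
                byrow = TRUE)
  structure(list(pos = pos, neg = neg, window = as.numeric(window)),
            class = "event_frame")
}

#' @export
print.event_frame <- function(x, ...) {
  cat(sprintf("<event_frame> %dx%d, window [%g, %g) us, +%d / -%d events\n",
              ncol(x$pos), nrow(x$pos), x$window[1], x$window[2],
              sum(x$pos), sum(x$neg)))
  invisible(x)
}
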