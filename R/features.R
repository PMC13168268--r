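#' Binarize an event frame into presence/absence polarity maps
#'
#' Each element of the downstream hypervector encodes the presence or
#' absence of events in a region, so counts are reduced to presence: a
#' map bit is 1 wherever at least `min_count` events of that polarity
#' fell. The default `min_count = 1` is pure presence/absence; larger
#' thresholds are an extension for noisy recordings.
#'
#' @param frame an `event_frame` from [accumulate_frame()].
#' @param min_count events needed for a bit to switch on (default 1).
#' @return an object of class `polarity_maps`: a list with binary integer
#'   matrices `pos` and `neg` of equal dimensions.
#' @export
binarize_frame <- function(frame, min_count = 1) {
  stopifnot(inherits(frame, "event_frame"), min_count >= 1)
  structure(
    list(pos = (frame$pos >= min_count) + 0L,
         neg = (frame$neg >= min_count) + 0L),
    class = "polarity_maps"
  )
}

#' OR-pooling down-sampling of a binary grid
#'
#' Reduces an `H x W` binary grid to `ceiling(H/bh) x ceiling(W/bw)` by
#' OR over non-overlapping `bh x bw` blocks: an output cell is 1 iff any
#' bit in its block is 1. This is the presence-preserving pooling implied
#' by region-presence encoding (a coarser region has an event iff any of
#' its sub-regions does); `stride` mode instead keeps the top-left pixel
#' of each block, for comparison. Block `c(1, 1)` is the identity.
#'
#' @param m binary matrix (0/1).
#' @param block integer `c(bh, bw)`, both >= 1.
#' @param method `"or"` (default) or `"stride"`.
#' @return binary integer matrix of the pooled size.
#' @export
#' @examples
#' m <- diag(4L)
#' downsample_or(m, c(2, 2))
downsample_or <- function(m, block, method = c("or", "stride")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), length(block) == 2)
  bh <- as.integer(block[1]); bw <- as.integer(block[2])
  if (bh < 1 || bw < 1) stop("block sizes must be >= 1")
  if (bh == 1 && bw == 1) return(m + 0L)
  if (method == "stride") {
    return(m[seq(1, nrow(m), by = bh), seq(1, ncol(m), by = bw),
             drop = FALSE] + 0L)
  }
  gr <- ceiling(seq_len(nrow(m)) / bh)
  gc <- ceiling(seq_len(ncol(m)) / bw)
  s <- rowsum(m, gr, reorder = TRUE)
  s <- t(rowsum(t(s), gc, reorder = TRUE))
  out <- (s > 0) + 0L
  dimnames(out) <- NULL
  out
}

#' Build a binary feature vector from polarity maps
#'
#' With `polarity_mode = "split"` the positive and negative maps are
#' flattened row-major and concatenated (positive first), doubling the
#' feature length and keeping polarity-specific structure. With
#' `"merged"` polarity is discarded: the maps are combined by elementwise
#' OR into a single map of the original length.
#'
#' @param maps a `polarity_maps` object (see [binarize_frame()]), whose
#'   maps may have been down-sampled with [downsample_or()].
#' @param polarity_mode `"split"` (default) or `"merged"`.
#' @return integer 0/1 vector with attribute `polarity_mode`; length
#'   `2 * H * W` for split, `H * W` for merged.
#' @export
#' @examples
#' maps <- structure(list(pos = matrix(c(1L, 0L), 1), neg = matrix(c(0L, 1L), 1)),
#'                   class = "polarity_maps")
#' make_feature(maps, "split")   # 1 0 0 1
#' make_feature(maps, "merged")  # 1 1
make_feature <- function(maps, polarity_mode = c("split", "merged")) {
  polarity_mode <- match.arg(polarity_mode)
  stopifnot(identical(dim(maps$pos), dim(maps$neg)))
  bits <- if (polarity_mode == "split") {
    c(as.integer(t(maps$pos)), as.integer(t(maps$neg)))
  } else {
    as.integer(t(maps$pos | maps$neg))
  }
  attr(bits, "polarity_mode") <- polarity_mode
  bits
}

#' Build the feature matrix for a dataset of event files
#'
#' Runs the full preprocessing chain — read events, accumulate the
#' transit frame, binarize, down-sample each polarity map, build the
#' feature vector — over every file of a dataset manifest (see
#' [load_manifest()]). Each file is expected to hold one particle
#' transit. By default the frame is accumulated over a short window at
#' the centre of the file's time span (`window_fraction` of it): there
#' the particle sits near the beam waist, intensity changes are
#' dominated by fringe motion rather than by the overall rise and fall
#' of brightness, and positive and negative events fall on opposite
#' fringe flanks, so the two polarity maps carry complementary
#' structure. Accumulating the whole transit instead
#' (`window_fraction = 1`) lets every active pixel both brighten and
#' dim, collapsing the two maps into near-copies.
#'
#' @param manifest data.frame with columns `class`, `session`, `sample`,
#'   `file` (paths resolved against `dir` if relative).
#' @param sensor_dims integer `c(width, height)` of the recordings.
#' @param dir dataset root used to resolve relative file paths.
#' @param block OR-pooling block `c(bh, bw)` applied to each polarity map
#'   before concatenation (default `c(1, 1)`: full resolution).
#' @param polarity_mode `"split"` or `"merged"` (see [make_feature()]).
#' @param min_count binarization threshold (see [binarize_frame()]).
#' @param window_fraction fraction of each file's time span accumulated,
#'   as a window at the centre of the span (default 0.3); 1 accumulates
#'   the full recording.
#' @return a list with `features` (n x L integer 0/1 matrix, one row per
#'   manifest row), `labels`, `sessions`, `samples` and the `map_dim`
#'   (`c(H', W')`) of one polarity map.
#' @export
build_features <- function(manifest, sensor_dims, dir = ".",
                           block = c(1, 1),
                           polarity_mode = c("split", "merged"),
                           min_count = 1, window_fraction = 0.3) {
  polarity_mode <- match.arg(polarity_mode)
  stopifnot(nrow(manifest) > 0, window_fraction > 0, window_fraction <= 1)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", manifest$file), manifest$file,
                  file.path(dir, manifest$file))
  hp <- ceiling(sensor_dims[2] / block[1])
  wp <- ceiling(sensor_dims[1] / block[2])
  len <- if (polarity_mode == "split") 2L * hp * wp else hp * wp
  feats <- matrix(0L, nrow = nrow(manifest), ncol = len)
  for (i in seq_len(nrow(manifest))) {
    ev <- read_event_file(paths[i], sensor_dims)
    win <- central_window(ev, window_fraction)
    maps <- binarize_frame(accumulate_frame(ev, win), min_count = min_count)
    maps$pos <- downsample_or(maps$pos, block)
    maps$neg <- downsample_or(maps$neg, block)
    feats[i, ] <- make_feature(maps, polarity_mode)
  }
  list(features = feats, labels = as.character(manifest$class),
       sessions = as.integer(manifest$session),
       samples = as.integer(manifest$sample), map_dim = c(hp, wp))
}

#' Accumulation windows within an event stream
#'
#' `central_window()` returns the window of length `fraction` times the
#' stream's time span centred on the middle of the span — the default
#' feature-accumulation window, sitting on the motion-dominated heart
#' of a transit. `peak_activity_window()` instead returns the
#' same-length window containing the most events (ties resolved toward
#' the earliest), useful for activity-triggered delimiting.
#'
#' @param ev an [event_stream()].
#' @param fraction window length as a fraction of the time span.
#' @return numeric `c(t_start, t_end)`, half-open.
#' @export
central_window <- function(ev, fraction = 0.3) {
  stopifnot(inherits(ev, "event_stream"), fraction > 0)
  if (!nrow(ev)) return(c(0, 1))
  t0 <- min(ev$t); t1 <- max(ev$t) + 1
  if (fraction >= 1) return(c(t0, t1))
  mid <- (t0 + t1) / 2
  len <- (t1 - t0) * fraction
  c(mid - len / 2, mid + len / 2)
}

#' @rdname central_window
#' @export
peak_activity_window <- function(ev, fraction = 0.3) {
  stopifnot(inherits(ev, "event_stream"), fraction > 0)
  if (!nrow(ev)) return(c(0, 1))
  t0 <- min(ev$t); t1 <- max(ev$t) + 1
  if (fraction >= 1) return(c(t0, t1))
  len <- (t1 - t0) * fraction
  # events are sorted: count in [t_i, t_i + len) is j(i) - i + 1
  hi <- findInterval(ev$t + len, ev$t + 0.5) # last event < t_i + len
  n_in <- hi - seq_along(ev$t) + 1L
  i <- which.max(n_in)
  c(ev$t[i], ev$t[i] + len)
}

# Dispatch on file extension: .csv or .parquet.
read_event_file <- function(path, sensor_dims) {
  if (grepl("\\.parquet$", path)) read_events_parquet(path)
  else read_events_csv(path, sensor_dims)
}
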