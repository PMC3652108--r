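# Tabulated channel allocations for the 4-, 8- and 12-channel processors.
# Center frequencies use logarithmic spacing for 4 channels and semilogarithmic
# mel spacing for 8 and 12 channels; bandwidths are the conventional-strategy
# analysis bandwidths. Values are embedded verbatim as ground truth.
.channel_tables <- list(
  `4` = list(
    spacing = "logarithmic",
    cf = c(460, 953, 1971, 4078),
    bw = c(321, 664, 1373, 2426)
  ),
  `8` = list(
    spacing = "mel",
    cf = c(394, 692, 1064, 1528, 2109, 2834, 3740, 4871),
    bw = c(265, 331, 431, 516, 645, 805, 1006, 1257)
  ),
  `12` = list(
    spacing = "mel",
    cf = c(274, 453, 662, 905, 1190, 1521, 1908, 2359, 2885, 3499, 4215, 5050),
    bw = c(165, 193, 225, 262, 306, 357, 416, 486, 567, 661, 771, 900)
  )
)

#' Split a channel bandwidth into tail and tip bandwidths
#'
#' Each dual-path channel uses a broad "tail" bandpass on its linear pathway
#' and a sharp "tip" bandpass on its nonlinear pathway. The tail bandwidth is
#' three times the tip bandwidth; the tail bandwidth equals the conventional
#' channel analysis bandwidth, so the tip filter is one third of it.
#'
#' @param bw_channel Conventional channel bandwidth in Hz (positive).
#' @return Named numeric vector `c(bw_tail = , bw_tip = )` in Hz.
#' @examples
#' split_bandwidths(321)  # c(bw_tail = 321, bw_tip = 107)
#' @export
split_bandwidths <- function(bw_channel) {
  if (!is.numeric(bw_channel) || length(bw_channel) != 1L ||
      !is.finite(bw_channel) || bw_channel <= 0) {
    stop("`bw_channel` must be a single positive bandwidth in Hz")
  }
  c(bw_tail = bw_channel, bw_tip = bw_channel / 3)
}

#' Construct a single channel specification
#'
#' @param cf Center frequency in Hz.
#' @param bw_channel Conventional analysis bandwidth in Hz. Tail and tip
#'   bandwidths are derived with [split_bandwidths()] unless given explicitly.
#' @param bw_tail,bw_tip Optional explicit pathway bandwidths in Hz.
#' @return A list of class `channel_spec` with fields `cf`, `bw_channel`,
#'   `bw_tail`, `bw_tip`.
#' @export
channel_spec <- function(cf, bw_channel, bw_tail = NULL, bw_tip = NULL) {
  if (cf <= 0) stop("center frequency must be positive")
  if (bw_channel <= 0) stop("channel bandwidth must be positive")
  if (is.null(bw_tail) || is.null(bw_tip)) {
    s <- split_bandwidths(bw_channel)
    if (is.null(bw_tail)) bw_tail <- unname(s["bw_tail"])
    if (is.null(bw_tip)) bw_tip <- unname(s["bw_tip"])
  }
  if (bw_tail <= 0 || bw_tip <= 0) stop("all bandwidths must be positive")
  structure(list(cf = cf, bw_channel = bw_channel,
                 bw_tail = bw_tail, bw_tip = bw_tip),
            class = "channel_spec")
}

#' Tabulated channel maps for 4, 8 and 12 channels
#'
#' Returns the embedded channel allocation table for the supported channel
#' counts, with the tail/tip pathway bandwidths derived from the conventional
#' analysis bandwidth via [split_bandwidths()]. No interpolation is performed
#' for other counts; arbitrary maps can be built with [channel_map()].
#'
#' @param n Channel count: 4, 8 or 12.
#' @return A `channel_map` object (see [channel_map()]).
#' @examples
#' m <- make_channel_map(8)
#' m$channels[[8]]$cf  # 4871
#' @export
make_channel_map <- function(n) {
  key <- as.character(n)
  if (length(n) != 1L || !key %in% names(.channel_tables)) {
    stop("no tabulated map for n = ", n, " channels (supported: 4, 8, 12)")
  }
  tab <- .channel_tables[[key]]
  specs <- Map(channel_spec, tab$cf, tab$bw)
  channel_map(specs, spacing_kind = tab$spacing)
}

#' Construct a channel map from channel specifications
#'
#' @param channels List of [channel_spec()] objects with strictly increasing
#'   center frequencies.
#' @param spacing_kind Spacing label, `"logarithmic"` or `"mel"`.
#' @return An object of class `channel_map`.
#' @export
channel_map <- function(channels, spacing_kind = c("logarithmic", "mel")) {
  spacing_kind <- match.arg(spacing_kind)
  if (!length(channels)) stop("channel map must contain at least one channel")
  stopifnot(all(vapply(channels, inherits, logical(1), "channel_spec")))
  cfs <- vapply(channels, `[[`, numeric(1), "cf")
  if (any(diff(cfs) <= 0)) {
    stop("center frequencies must be strictly increasing")
  }
  structure(list(channels = channels, spacing_kind = spacing_kind),
            class = "channel_map")
}

#' @rdname channel_map
#' @param x A `channel_map`.
#' @param ... Ignored.
#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("<channel_map: %d channels, %s spacing>\n",
              length(x$channels), x$spacing_kind))
  print(as.data.frame(x))
  invisible(x)
}

#' @rdname channel_map
#' @param row.names,optional Passed through for S3 consistency; unused.
#' @export
as.data.frame.channel_map <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(
    channel = seq_along(x$channels),
    cf_hz = vapply(x$channels, `[[`, numeric(1), "cf"),
    bw_channel_hz = vapply(x$channels, `[[`, numeric(1), "bw_channel"),
    bw_tail_hz = vapply(x$channels, `[[`, numeric(1), "bw_tail"),
    bw_tip_hz = vapply(x$channels, `[[`, numeric(1), "bw_tip")
  )
}

#' Export or import a channel map as CSV
#'
#' Columns: `channel, cf_hz, bw_channel_hz, bw_tail_hz, bw_tip_hz`.
#'
#' @param map A `channel_map`.
#' @param path CSV file path.
#' @return `write_channel_map()` returns `path` invisibly; `read_channel_map()`
#'   returns a `channel_map`.
#' @export
write_channel_map <- function(map, path) {
  stopifnot(inherits(map, "channel_map"))
  df <- as.data.frame(map)
  df$spacing_kind <- map$spacing_kind
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_channel_map
#' @export
read_channel_map <- function(path) {
  df <- utils::read.csv(path)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    channel_spec(df$cf_hz[i], df$bw_channel_hz[i],
                 bw_tail = df$bw_tail_hz[i], bw_tip = df$bw_tip_hz[i])
  })
  spacing <- if ("spacing_kind" %in% names(df)) df$spacing_kind[1] else
    "logarithmic"
  channel_map(specs, spacing_kind = spacing)
}

#' Channel bandwidth as a function of center frequency
#'
#' Two ways of assigning an analysis bandwidth to an arbitrary center
#' frequency, both anchored to the 12-channel allocation table:
#' `interp_channel_bandwidth()` interpolates linearly in log(cf)-log(bw), with
#' linear extrapolation beyond the tabulated ends (used by the cochlear
#' partition analysis); `nearest_channel_bandwidth()` takes the bandwidth of
#' the tabulated channel nearest in log-frequency (used for single demo
#' channels such as cf 1500 Hz, which maps to the 1521 Hz entry, bw 357 Hz).
#'
#' @param cf Center frequency (Hz), vectorized.
#' @return Bandwidth(s) in Hz.
#' @export
interp_channel_bandwidth <- function(cf) {
  tab <- .channel_tables[["12"]]
  lx <- log(tab$cf); ly <- log(tab$bw)
  lq <- log(cf)
  out <- stats::approx(lx, ly, xout = lq, rule = 1)$y
  # extend the end segments linearly in log-log
  lo <- lq < lx[1]; hi <- lq > lx[length(lx)]
  if (any(lo)) {
    s <- (ly[2] - ly[1]) / (lx[2] - lx[1])
    out[lo] <- ly[1] + s * (lq[lo] - lx[1])
  }
  if (any(hi)) {
    k <- length(lx)
    s <- (ly[k] - ly[k - 1]) / (lx[k] - lx[k - 1])
    out[hi] <- ly[k] + s * (lq[hi] - lx[k])
  }
  exp(out)
}

#' @rdname interp_channel_bandwidth
#' @export
nearest_channel_bandwidth <- function(cf) {
  tab <- .channel_tables[["12"]]
  vapply(cf, function(f) {
    tab$bw[which.min(abs(log(f) - log(tab$cf)))]
  }, numeric(1))
}
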