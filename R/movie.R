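#' Movie container: a 5-D camera-count array with imaging metadata
#'
#' A `movie` is a numeric array with dimension order `(T, C, Z, Y, X)` —
#' missing axes have extent 1 — carrying the two pieces of metadata every
#' downstream computation needs: the pixel size in micrometres and the frame
#' interval in seconds. Pixel coordinates throughout the package are 0-based
#' with `x` = column and `y` = row, origin at the centre of the top-left
#' pixel, so `x_um = x_px * pixel_size_um`.
#'
#' @param data numeric array. Accepted shapes: `(Y, X)`, `(T, Y, X)`,
#'   `(T, C, Y, X)` or the full `(T, C, Z, Y, X)`.
#' @param pixel_size_um pixel size, micrometres per pixel (> 0).
#' @param frame_interval_s time between frames, seconds (> 0).
#' @param channel_names optional character vector, one per channel.
#' @return An object of class `movie`.
#' @export
movie <- function(data, pixel_size_um, frame_interval_s, channel_names = NULL) {
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  check_number(frame_interval_s, "frame_interval_s", min = .Machine$double.eps)
  if (!is.numeric(data)) abort("`data` must be a numeric array.")
  d <- dim(data) %||% length(data)
  data <- switch(as.character(length(d)),
    "2" = array(data, c(1L, 1L, 1L, d[1], d[2])),
    "3" = aperm(array(data, c(d, 1L, 1L)), c(1L, 4L, 5L, 2L, 3L)),
    "4" = aperm(array(data, c(d, 1L)), c(1L, 2L, 5L, 3L, 4L)),
    "5" = data,
    abort("`data` must have 2 to 5 dimensions.")
  )
  nc <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) abort("`channel_names` length must equal the channel count.")
  structure(data,
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    channel_names = channel_names,
    class = c("movie", "array")
  )
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<movie> %d frame(s), %d channel(s), %d z, %d x %d px | %.4g um/px, %.4g s/frame\n",
    d[1], d[2], d[3], d[4], d[5],
    attr(x, "pixel_size_um"), attr(x, "frame_interval_s")
  ))
  invisible(x)
}

n_frames <- function(m) dim(m)[1]
n_channels <- function(m) dim(m)[2]

#' Extract one 2-D frame from a movie
#'
#' Collapses the z axis according to `z_policy` and returns a plain matrix
#' `(Y, X)`.
#'
#' @param m a [movie].
#' @param t frame index (1-based).
#' @param channel channel index (1-based).
#' @param z_policy `"max_project"` (maximum-intensity projection over z) or
#'   `"first"`.
#' @return numeric matrix `(Y, X)`.
#' @export
movie_frame <- function(m, t, channel = 1L, z_policy = c("max_project", "first")) {
  z_policy <- match.arg(z_policy)
  if (!inherits(m, "movie")) abort("`m` must be a movie.")
  t <- check_count(t, "t"); channel <- check_count(channel, "channel")
  if (channel > n_channels(m)) {
    abort(sprintf("channel %d requested but movie has %d channel(s).", channel, n_channels(m)))
  }
  if (t > n_frames(m)) abort(sprintf("frame %d requested but movie has %d frame(s).", t, n_frames(m)))
  d <- dim(m)
  sub <- array(m[t, channel, , , ], c(d[3], d[4], d[5]))
  if (z_policy == "max_project") {
    apply(sub, c(2L, 3L), max)
  } else {
    matrix(sub[1L, , ], d[4], d[5])
  }
}

#' Write a movie as a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are ordered `t` major, then channel, then z. Counts are stored as
#' 16-bit unsigned integers (values are rounded and clipped at 65535, the
#' usual camera bit depth), and the sidecar `<path>.json` records
#' `pixel_size_um`, `frame_interval_s`, `channel_names` and the axis extents
#' so the array shape round-trips.
#'
#' @param m a [movie].
#' @param path output TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path) {
  if (!inherits(m, "movie")) abort("`m` must be a movie.")
  d <- dim(m)
  pages <- list()
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    pg <- matrix(m[t, ch, z, , ], d[4], d[5])
    pages[[length(pages) + 1L]] <- pmin(pmax(round(pg), 0), 65535) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    pixel_size_um = attr(m, "pixel_size_um"),
    frame_interval_s = attr(m, "frame_interval_s"),
    channel_names = attr(m, "channel_names"),
    shape = list(t = d[1], c = d[2], z = d[3], y = d[4], x = d[5])
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path; metadata is taken from the sidecar JSON unless
#'   overridden.
#' @param pixel_size_um,frame_interval_s override or supply metadata when no
#'   sidecar exists.
#' @return a [movie].
#' @export
read_movie <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  frame_interval_s <- frame_interval_s %||% meta$frame_interval_s
  if (is.null(pixel_size_um) || is.null(frame_interval_s)) {
    abort("pixel_size_um / frame_interval_s not found in sidecar; pass them explicitly.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) round(p * 65535))
  shp <- meta$shape
  if (is.null(shp)) shp <- list(t = length(pages), c = 1L, z = 1L, y = nrow(pages[[1]]), x = ncol(pages[[1]]))
  arr <- array(0, c(shp$t, shp$c, shp$z, shp$y, shp$x))
  i <- 1L
  for (t in seq_len(shp$t)) for (ch in seq_len(shp$c)) for (z in seq_len(shp$z)) {
    arr[t, ch, z, , ] <- pages[[i]]
    i <- i + 1L
  }
  movie(arr, pixel_size_um, frame_interval_s, channel_names = meta$channel_names)
}
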