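# Shared fixtures, all generated in code.

# a noiseless continuous-valued frame with one Gaussian spot
render_single_spot <- function(x_px, y_px, amp = 100, bg = 10, sigma = 1.3,
                               field = c(32L, 32L), pixel_size_um = 0.13) {
  opt <- optics(pixel_size_um = pixel_size_um, psf_sigma_px = sigma,
                photons_per_spot = amp, background_level = bg,
                read_noise_sd = 0, field_px = field)
  trk <- tibble::tibble(track_id = 1L, frame = 0L,
                        x_um = x_px * pixel_size_um, y_um = y_px * pixel_size_um)
  movie_frame(render_movie(trk, opt, noise = FALSE, digitize = FALSE), 1)
}

# well-separated fiducial grid in pixels
fiducial_grid <- function(spacing = 24, lo = 10, hi = 250) {
  g <- expand.grid(x = seq(lo, hi, by = spacing), y = seq(lo, hi, by = spacing))
  tibble::tibble(x_px = g$x, y_px = g$y)
}

# integer label matrix holding one centred disk
disk_labels <- function(radius = 10, field = 64L, cx = NULL, cy = NULL) {
  cx <- if (is.null(cx)) (field - 1) / 2 else cx
  cy <- if (is.null(cy)) (field - 1) / 2 else cy
  xs <- matrix(rep(0:(field - 1), each = field), field)
  ys <- matrix(rep(0:(field - 1), field), field)
  lab <- matrix(0L, field, field)
  lab[(xs - cx)^2 + (ys - cy)^2 <= radius^2] <- 1L
  lab
}

# brute-force Euclidean distance of every pixel to the nearest mask pixel
brute_force_dist <- function(mask) {
  idx <- which(mask)
  mr <- (idx - 1) %% nrow(mask); mc <- (idx - 1) %/% nrow(mask)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    out[i, j] <- if (mask[i, j]) 0 else
      sqrt(min((mr - (i - 1))^2 + (mc - (j - 1))^2))
  }
  out
}

# emulate photoactivated imaging: each emitter's visible window starts at a
# uniformly random frame and ends by geometric bleaching
slice_visible_window <- function(tracks, p_bleach, latest_start, seed) {
  set.seed(seed)
  dplyr::bind_rows(lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    on <- sample.int(latest_start, 1)
    len <- stats::rgeom(1, p_bleach) + 1L
    tr[tr$frame >= on & tr$frame < on + len, , drop = FALSE]
  }))
}
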