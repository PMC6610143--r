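#' Camera and optics description for rendered movies
#'
#' Defaults emulate a x100 EM-CCD single-molecule setup: 130 nm pixels and a
#' diffraction-limited point-spread function of about one pixel width.
#'
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels (> 0).
#' @param photons_per_spot expected peak amplitude of one emitter, counts.
#' @param background_level constant background, counts.
#' @param read_noise_sd Gaussian read noise standard deviation, counts.
#' @param frame_interval_s seconds per frame (> 0).
#' @param field_px field size `c(height, width)` in pixels (each >= 16).
#' @return An `optics` list.
#' @export
optics <- function(pixel_size_um = 0.13, psf_sigma_px = 1.0,
                   photons_per_spot = 200, background_level = 100,
                   read_noise_sd = 2, frame_interval_s = 0.0438,
                   field_px = c(128L, 128L)) {
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  check_number(psf_sigma_px, "psf_sigma_px", min = .Machine$double.eps)
  check_number(photons_per_spot, "photons_per_spot", min = 0)
  check_number(background_level, "background_level", min = 0)
  check_number(read_noise_sd, "read_noise_sd", min = 0)
  check_number(frame_interval_s, "frame_interval_s", min = .Machine$double.eps)
  if (length(field_px) != 2 || any(field_px < 16)) {
    abort("`field_px` must be c(height, width) with both >= 16.")
  }
  structure(
    list(pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px,
         photons_per_spot = photons_per_spot, background_level = background_level,
         read_noise_sd = read_noise_sd, frame_interval_s = frame_interval_s,
         field_px = as.integer(field_px)),
    class = "optics"
  )
}

#' Photoactivation and photobleaching kinetics
#'
#' Emitters can start dark (photoactivatable label), switch on at periodic
#' activation pulses with some probability, and irreversibly bleach at a
#' first-order rate while visible. The defaults describe a conventional dye:
#' everything on from frame one, no bleaching. For sparse single-molecule
#' tracking use e.g. `photo_kinetics(initially_dark_fraction = 1,
#' activation_pulse_period = 10, activation_prob_per_pulse = 0.1,
#' bleach_rate = 0.5)` — a pulse once every 10 s switching on a small random
#' subset, as in photoactivated tracking experiments.
#'
#' @param activation_pulse_period seconds between activation pulses.
#' @param activation_prob_per_pulse probability a dark emitter activates at a
#'   pulse, in `[0, 1]`.
#' @param bleach_rate first-order bleaching rate of visible emitters, 1/s (>= 0).
#' @param initially_dark_fraction fraction of emitters dark at t = 0, `[0, 1]`.
#' @return A `photo_kinetics` list.
#' @export
photo_kinetics <- function(activation_pulse_period = 10,
                           activation_prob_per_pulse = 1,
                           bleach_rate = 0,
                           initially_dark_fraction = 0) {
  check_number(activation_pulse_period, "activation_pulse_period", min = .Machine$double.eps)
  check_number(activation_prob_per_pulse, "activation_prob_per_pulse", min = 0, max = 1)
  check_number(bleach_rate, "bleach_rate", min = 0)
  check_number(initially_dark_fraction, "initially_dark_fraction", min = 0, max = 1)
  structure(
    list(activation_pulse_period = activation_pulse_period,
         activation_prob_per_pulse = activation_prob_per_pulse,
         bleach_rate = bleach_rate,
         initially_dark_fraction = initially_dark_fraction),
    class = "photo_kinetics"
  )
}

#' Render a track table into a synthetic fluorescence movie
#'
#' Each visible emitter is drawn as a symmetric 2-D Gaussian of width
#' `psf_sigma_px` and peak amplitude `photons_per_spot` on a constant
#' background; the camera model is Poisson shot noise on the expected signal
#' plus Gaussian read noise, rounded to integer counts (set `noise = FALSE`
#' and `digitize = FALSE` for an exact noiseless expectation image).
#' Visibility follows the [photo_kinetics] activation/bleach state of each
#' track. Positions outside the field are clipped to its edge.
#'
#' @param tracks tibble with `track_id`, `frame` (0-based), `x_um`, `y_um`
#'   and optionally `channel` (1-based; default all channel 1). An empty
#'   table gives a pure-background movie.
#' @param optics an [optics].
#' @param photo a [photo_kinetics].
#' @param n_frames number of frames; default spans the track table.
#' @param n_channels default spans the track table.
#' @param seed integer seed (noise and photo-switching).
#' @param noise add Poisson + read noise (default TRUE).
#' @param digitize round to integer camera counts (default TRUE).
#' @return a [movie]; attribute `visible` holds the per-row visibility flags
#'   used while rendering.
#' @export
render_movie <- function(tracks, optics, photo = photo_kinetics(),
                         n_frames = NULL, n_channels = NULL, seed = 1L,
                         noise = TRUE, digitize = TRUE) {
  if (!inherits(optics, "optics")) abort("`optics` must come from optics().")
  if (!inherits(photo, "photo_kinetics")) abort("`photo` must come from photo_kinetics().")
  if (is.null(tracks) || nrow(tracks) == 0) {
    tracks <- tibble(track_id = integer(), frame = integer(),
                     x_um = numeric(), y_um = numeric())
  }
  if (!"channel" %in% names(tracks)) tracks$channel <- 1L
  n_frames <- n_frames %||% (max(c(tracks$frame, 0L)) + 1L)
  n_channels <- n_channels %||% max(c(tracks$channel, 1L))
  set.seed(seed)
  h <- optics$field_px[1]; w <- optics$field_px[2]
  dt <- optics$frame_interval_s

  vis <- emitter_visibility(tracks, photo, dt)
  arr <- array(0, c(n_frames, n_channels, 1L, h, w))
  halfwin <- ceiling(5 * optics$psf_sigma_px)
  for (t in seq_len(n_frames)) {
    for (ch in seq_len(n_channels)) {
      img <- matrix(optics$background_level, h, w)
      rows <- which(tracks$frame == t - 1L & tracks$channel == ch & vis)
      for (r in rows) {
        x <- min(max(tracks$x_um[r] / optics$pixel_size_um, 0), w - 1)
        y <- min(max(tracks$y_um[r] / optics$pixel_size_um, 0), h - 1)
        img <- add_gaussian_spot(img, x, y, optics$photons_per_spot,
                                 optics$psf_sigma_px, halfwin)
      }
      if (noise) {
        img <- rpois(length(img), pmax(img, 0)) + rnorm(length(img), 0, optics$read_noise_sd)
        img <- matrix(img, h, w)
      }
      if (digitize) img <- pmax(round(img), 0)
      arr[t, ch, 1L, , ] <- img
    }
  }
  m <- movie(arr, optics$pixel_size_um, dt)
  attr(m, "visible") <- vis
  m
}

# per-row visibility under activation pulses + first-order bleaching
emitter_visibility <- function(tracks, photo, dt) {
  if (nrow(tracks) == 0) return(logical(0))
  vis <- rep(TRUE, nrow(tracks))
  for (key in unique(paste(tracks$track_id, tracks$channel))) {
    rows <- which(paste(tracks$track_id, tracks$channel) == key)
    rows <- rows[order(tracks$frame[rows])]
    nf <- length(rows)
    t_s <- tracks$frame[rows] * dt
    dark <- runif(1) < photo$initially_dark_fraction
    on_frame <- if (!dark) 1L else NA_integer_
    if (dark) {
      pulses <- which(t_s %% photo$activation_pulse_period < dt)
      for (p in pulses) {
        if (runif(1) < photo$activation_prob_per_pulse) { on_frame <- p; break }
      }
    }
    state <- rep(FALSE, nf)
    if (!is.na(on_frame)) {
      p_bleach <- 1 - exp(-photo$bleach_rate * dt)
      off_frame <- nf + 1L
      if (p_bleach > 0) {
        surv <- which(runif(nf - on_frame + 1L) < p_bleach)
        if (length(surv)) off_frame <- on_frame + surv[1]
      }
      state[seq_len(nf) >= on_frame & seq_len(nf) < off_frame] <- TRUE
    }
    vis[rows] <- state
  }
  vis
}

add_gaussian_spot <- function(img, x, y, amp, sigma, halfwin) {
  h <- nrow(img); w <- ncol(img)
  c0 <- max(1L, floor(x + 1 - halfwin)); c1 <- min(w, ceiling(x + 1 + halfwin))
  r0 <- max(1L, floor(y + 1 - halfwin)); r1 <- min(h, ceiling(y + 1 + halfwin))
  cols <- c0:c1; rows <- r0:r1
  gx <- exp(-((cols - 1 - x)^2) / (2 * sigma^2))
  gy <- exp(-((rows - 1 - y)^2) / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amp * outer(gy, gx)
  img
}
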