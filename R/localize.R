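#' Detect diffraction-limited spots in one frame
#'
#' Classic bandpass detection: the image is filtered with a
#' difference-of-Gaussians (small sigma minus large sigma, a passband sized
#' to diffraction-limited spots), binarized, and each connected component of
#' at least `min_area` pixels is reduced to its intensity-weighted centroid.
#' These centroids are the coarse positions that [fit_gaussian_2d()] refines.
#'
#' @param frame_image 2-D numeric matrix `(Y, X)`, at least 16 x 16, all
#'   finite.
#' @param band_low_sigma,band_high_sigma Gaussian sigmas (px) of the
#'   difference-of-Gaussians; `band_low_sigma < band_high_sigma`.
#' @param threshold `"mean_sd"` (mean + `nsd` * SD of the bandpassed frame)
#'   or `"otsu"`.
#' @param nsd SD multiplier for the `"mean_sd"` strategy.
#' @param min_area minimum component area, px^2.
#' @return tibble `x_px`, `y_px` (0-based, intensity-weighted centroid),
#'   `area_px2`, `peak` (bandpassed peak value). Zero rows when nothing is
#'   detected.
#' @export
detect_spots <- function(frame_image, band_low_sigma = 1, band_high_sigma = 3,
                         threshold = c("mean_sd", "otsu"), nsd = 3,
                         min_area = 3) {
  threshold <- match.arg(threshold)
  if (!is.matrix(frame_image) || nrow(frame_image) < 16 || ncol(frame_image) < 16) {
    abort("`frame_image` must be a matrix of at least 16 x 16 pixels.")
  }
  if (!all(is.finite(frame_image))) abort("`frame_image` contains non-finite pixels.")
  check_number(band_low_sigma, "band_low_sigma", min = .Machine$double.eps)
  check_number(band_high_sigma, "band_high_sigma", min = .Machine$double.eps)
  if (band_low_sigma >= band_high_sigma) abort("`band_low_sigma` must be < `band_high_sigma`.")
  band <- EBImage::gblur(frame_image, sigma = band_low_sigma) -
    EBImage::gblur(frame_image, sigma = band_high_sigma)
  if (sd(band) == 0) return(empty_detections())
  thr <- if (threshold == "mean_sd") {
    mean(band) + nsd * sd(band)
  } else {
    rng <- range(band)
    rng[1] + EBImage::otsu(EBImage::Image((band - rng[1]) / diff(rng)), range = c(0, 1)) * diff(rng)
  }
  bw <- band > thr
  if (!any(bw)) return(empty_detections())
  lab <- EBImage::bwlabel(bw)
  wts <- pmax(band, 0)
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  df <- tibble(lab = labs, y = rows - 1, x = cols - 1, w = wts[idx]) %>%
    group_by(.data$lab) %>%
    summarise(
      area_px2 = dplyr::n(),
      x_px = sum(.data$x * .data$w) / sum(.data$w),
      y_px = sum(.data$y * .data$w) / sum(.data$w),
      peak = max(.data$w),
      .groups = "drop"
    ) %>%
    filter(.data$area_px2 >= min_area) %>%
    select("x_px", "y_px", "area_px2", "peak")
  df
}

empty_detections <- function() {
  tibble(x_px = numeric(), y_px = numeric(), area_px2 = numeric(), peak = numeric())
}

#' Refine a spot position by 2-D elliptical Gaussian least squares
#'
#' Fits the model
#' `I(x, y) = I_BG + I * exp(-(x - x0)^2 / (2 * sigma_x^2) - (y - y0)^2 / (2 * sigma_y^2))`
#' to a square window around a candidate position by Levenberg-Marquardt
#' nonlinear least squares, initialized at the candidate centroid with
#' moment-based widths. A stalled optimizer or a degenerate (flat) window is
#' reported as `converged = FALSE` rather than as an error.
#'
#' @param frame_image 2-D numeric matrix.
#' @param x_px,y_px candidate centre, 0-based pixels.
#' @param window_halfwidth half-width of the square fit window, px; windows
#'   extending past the frame edge are shrunk (minimum 5 x 5).
#' @param circular force `sigma_x == sigma_y`.
#' @return one-row tibble `I_BG`, `I`, `x0`, `y0`, `sigma_x`, `sigma_y`,
#'   `converged`, `residual_norm`, `edge_truncated`.
#' @export
fit_gaussian_2d <- function(frame_image, x_px, y_px, window_halfwidth = 5,
                            circular = FALSE) {
  check_number(x_px, "x_px"); check_number(y_px, "y_px")
  window_halfwidth <- check_count(window_halfwidth, "window_halfwidth", min = 2L)
  h <- nrow(frame_image); w <- ncol(frame_image)
  cx <- round(x_px); cy <- round(y_px)
  c0 <- max(0, cx - window_halfwidth); c1 <- min(w - 1, cx + window_halfwidth)
  r0 <- max(0, cy - window_halfwidth); r1 <- min(h - 1, cy + window_halfwidth)
  edge_truncated <- (c1 - c0 < 2 * window_halfwidth) || (r1 - r0 < 2 * window_halfwidth)
  if (c1 - c0 < 4 || r1 - r0 < 4) abort("fit window smaller than 5 x 5 pixels.")
  win <- frame_image[(r0:r1) + 1, (c0:c1) + 1, drop = FALSE]
  xs <- c0:c1; ys <- r0:r1
  fail <- function() tibble(
    I_BG = mean(win), I = 0, x0 = x_px, y0 = y_px,
    sigma_x = NA_real_, sigma_y = NA_real_, converged = FALSE,
    residual_norm = NA_real_, edge_truncated = edge_truncated
  )
  if (sd(win) == 0) return(fail())

  bg0 <- min(win)
  amp0 <- max(win) - bg0
  wts <- pmax(win - bg0, 0)
  tot <- sum(wts)
  mx <- sum(outer(rep(1, length(ys)), xs) * wts) / tot
  my <- sum(outer(ys, rep(1, length(xs))) * wts) / tot
  sx0 <- sqrt(max(sum(outer(rep(1, length(ys)), (xs - mx)^2) * wts) / tot, 0.25))
  sy0 <- sqrt(max(sum(outer((ys - my)^2, rep(1, length(xs))) * wts) / tot, 0.25))
  gridx <- outer(rep(1, length(ys)), xs)
  gridy <- outer(ys, rep(1, length(xs)))
  resid_fun <- function(p) {
    if (circular) p[6] <- p[5]
    mdl <- p[1] + p[2] * exp(-(gridx - p[3])^2 / (2 * p[5]^2) -
                              (gridy - p[4])^2 / (2 * p[6]^2))
    as.vector(mdl - win)
  }
  p0 <- c(bg0, amp0, mx, my, sx0, sy0)
  fit <- tryCatch(
    minpack.lm::nls.lm(p0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail())
  p <- fit$par
  if (circular) p[6] <- p[5]
  p[5] <- abs(p[5]); p[6] <- abs(p[6])
  inside <- p[3] >= min(xs) - 0.5 && p[3] <= max(xs) + 0.5 &&
    p[4] >= min(ys) - 0.5 && p[4] <= max(ys) + 0.5
  ok <- fit$info %in% 1:4 && inside && p[2] >= 0 && p[5] > 0 && p[6] > 0
  tibble(
    I_BG = p[1], I = p[2], x0 = p[3], y0 = p[4],
    sigma_x = p[5], sigma_y = p[6], converged = ok,
    residual_norm = sqrt(sum(fit$fvec^2)), edge_truncated = edge_truncated
  )
}

#' Localize spots in every frame of a movie
#'
#' Runs [detect_spots()] then [fit_gaussian_2d()] on each frame of one
#' channel (maximum-intensity projecting over z first, when present) and
#' returns one table of sub-pixel localizations. Fits that do not converge
#' keep their detection centroid and are flagged.
#'
#' @param m a [movie].
#' @param channel channel index (1-based).
#' @param z_policy passed to [movie_frame()].
#' @param window_halfwidth fit window half-width, px.
#' @param ... further arguments to [detect_spots()].
#' @return tibble `frame` (0-based), `channel`, `x_px`, `y_px`, `x_um`,
#'   `y_um`, `I`, `I_BG`, `sigma_x`, `sigma_y`, `converged`,
#'   `detection_x_px`, `detection_y_px`.
#' @export
localize_movie <- function(m, channel = 1L, z_policy = "max_project",
                           window_halfwidth = 5, ...) {
  if (!inherits(m, "movie")) abort("`m` must be a movie.")
  channel <- check_count(channel, "channel")
  if (channel > n_channels(m)) {
    abort(sprintf("channel %d requested but movie has %d channel(s).", channel, n_channels(m)))
  }
  px <- attr(m, "pixel_size_um")
  out <- vector("list", n_frames(m))
  for (t in seq_len(n_frames(m))) {
    img <- movie_frame(m, t, channel, z_policy)
    det <- detect_spots(img, ...)
    if (nrow(det) == 0) next
    fits <- map_dfr(seq_len(nrow(det)), function(i) {
      fit_gaussian_2d(img, det$x_px[i], det$y_px[i], window_halfwidth)
    })
    x <- ifelse(fits$converged, fits$x0, det$x_px)
    y <- ifelse(fits$converged, fits$y0, det$y_px)
    out[[t]] <- tibble(
      frame = t - 1L, channel = channel,
      x_px = x, y_px = y, x_um = x * px, y_um = y * px,
      I = fits$I, I_BG = fits$I_BG,
      sigma_x = fits$sigma_x, sigma_y = fits$sigma_y,
      converged = fits$converged,
      detection_x_px = det$x_px, detection_y_px = det$y_px
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(
      frame = integer(), channel = integer(), x_px = numeric(), y_px = numeric(),
      x_um = numeric(), y_um = numeric(), I = numeric(), I_BG = numeric(),
      sigma_x = numeric(), sigma_y = numeric(), converged = logical(),
      detection_x_px = numeric(), detection_y_px = numeric()
    )
  }
  res
}

#' Estimate per-frame rigid drift against a reference frame
#'
#' Translation is estimated from the peak of the circular cross-correlation
#' (computed by FFT) between each frame and the reference, refined to
#' sub-pixel precision by quadratic interpolation around the peak. Applying
#' the negated drift re-centres the movie.
#'
#' @param m a [movie] with at least 2 frames.
#' @param reference_frame 1-based index of the reference frame.
#' @param channel channel to use.
#' @return tibble `frame` (0-based), `dx_px`, `dy_px`, `confident` (FALSE for
#'   featureless frames, whose drift is reported as 0).
#' @export
estimate_drift <- function(m, reference_frame = 1L, channel = 1L) {
  if (!inherits(m, "movie")) abort("`m` must be a movie.")
  if (n_frames(m) < 2) abort("drift estimation needs at least 2 frames.")
  ref <- movie_frame(m, reference_frame, channel)
  fr <- fft(ref - mean(ref))
  out <- vector("list", n_frames(m))
  for (t in seq_len(n_frames(m))) {
    img <- movie_frame(m, t, channel)
    if (sd(img) == 0 || sd(ref) == 0) {
      out[[t]] <- tibble(frame = t - 1L, dx_px = 0, dy_px = 0, confident = FALSE)
      next
    }
    cc <- Re(fft(Conj(fr) * fft(img - mean(img)), inverse = TRUE))
    pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
    nr <- nrow(cc); nc <- ncol(cc)
    dy <- pk[1] - 1; dx <- pk[2] - 1
    # sub-pixel: quadratic interpolation along each axis around the peak
    ym <- cc[(pk[1] - 2) %% nr + 1, pk[2]]; y0 <- cc[pk[1], pk[2]]; yp <- cc[pk[1] %% nr + 1, pk[2]]
    xm <- cc[pk[1], (pk[2] - 2) %% nc + 1]; xp <- cc[pk[1], pk[2] %% nc + 1]
    den_y <- ym - 2 * y0 + yp; den_x <- xm - 2 * y0 + xp
    if (den_y != 0) dy <- dy + 0.5 * (ym - yp) / den_y
    if (den_x != 0) dx <- dx + 0.5 * (xm - xp) / den_x
    if (dy > nr / 2) dy <- dy - nr
    if (dx > nc / 2) dx <- dx - nc
    out[[t]] <- tibble(frame = t - 1L, dx_px = dx, dy_px = dy, confident = TRUE)
  }
  bind_rows(out)
}
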