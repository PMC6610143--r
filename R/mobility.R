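#' Ensemble mean squared displacement of a track set
#'
#' Computes, per track, the time-averaged MSD at each lag (over all ordered
#' frame pairs separated by that lag), then averages the per-track curves
#' across tracks with the across-track standard error as the error bar —
#' the time-averaged-then-ensemble convention whose error bars reflect
#' particle-to-particle variability.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_um`, `y_um`.
#' @param max_lag_frames largest lag, frames; must be reachable by at least
#'   one track.
#' @param frame_interval_s seconds per frame, used to express lags in s.
#' @return an `msd_curve`: tibble `lag_frames`, `lag_s`, `msd_um2`,
#'   `sem_um2`, `n_tracks`, with attribute `frame_interval_s`. The lag-0
#'   point (MSD 0 by convention) is included.
#' @export
ensemble_msd <- function(tracks, max_lag_frames = 10L, frame_interval_s = 1) {
  max_lag_frames <- check_count(max_lag_frames, "max_lag_frames")
  check_number(frame_interval_s, "frame_interval_s", min = .Machine$double.eps)
  if (nrow(tracks) == 0) abort("`tracks` is empty.")
  per_track <- tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    filter(dplyr::n() >= 2) %>%
    group_by(.data$track_id) %>%
    summarise(msd = list(track_msd(.data$x_um, .data$y_um, max_lag_frames)),
              .groups = "drop")
  if (nrow(per_track) == 0) abort("no track of length >= 2.")
  mat <- do.call(rbind, per_track$msd)          # tracks x lags, NA when too short
  if (all(is.na(mat[, max_lag_frames]))) {
    abort("max_lag_frames exceeds every track length.")
  }
  msd <- colMeans(mat, na.rm = TRUE)
  nlag <- colSums(!is.na(mat))
  sem <- apply(mat, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  })
  ok <- nlag > 0
  out <- tibble(
    lag_frames = c(0L, which(ok)),
    lag_s = c(0, which(ok)) * frame_interval_s,
    msd_um2 = c(0, msd[ok]),
    sem_um2 = c(0, sem[ok]),
    n_tracks = c(nrow(mat), nlag[ok])
  )
  structure(out, frame_interval_s = frame_interval_s, per_track = mat,
            class = c("msd_curve", class(out)))
}

# time-averaged MSD of one track at lags 1..max_lag (NA where track too short)
track_msd <- function(x, y, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(lag) {
    if (lag >= n) return(NA_real_)
    mean((x[seq_len(n - lag) + lag] - x[seq_len(n - lag)])^2 +
           (y[seq_len(n - lag) + lag] - y[seq_len(n - lag)])^2)
  }, numeric(1))
}

#' Fit a diffusion coefficient from the first points of an MSD curve
#'
#' Ordinary least squares of MSD against lag time over the first `n_points`
#' non-zero lags, with a free intercept (which absorbs static localization
#' error). For 2-D Brownian motion the slope is `m = 4 D`, so `D = m / 4`.
#'
#' The 95% confidence half-width on `D` reflects across-track variability:
#' when the curve carries its per-track MSD matrix (any [ensemble_msd()]
#' output does), the slope's standard error is computed by a delete-one
#' jackknife over tracks, which respects the strong correlation of MSD
#' values across lags within a track. Without per-track information the
#' residual-based OLS standard error is used instead (and is typically
#' optimistic).
#'
#' @param msd an `msd_curve` from [ensemble_msd()] (or any tibble with
#'   `lag_s`, `msd_um2`).
#' @param n_points number of non-zero lags to fit (default 5, the usual
#'   short-time window where the linear approximation holds).
#' @return a `diffusion_fit` list: `m` (slope, um^2/s), `intercept`, `D`,
#'   `ci95`, `n_points_fit`, `negative_slope` flag.
#' @export
fit_diffusion <- function(msd, n_points = 5L) {
  n_points <- check_count(n_points, "n_points", min = 2L)
  pts <- filter(as_tibble(msd), .data$lag_frames > 0)
  if (nrow(pts) < n_points) {
    abort(sprintf("MSD curve has %d non-zero lags; %d required.", nrow(pts), n_points))
  }
  pts <- head(pts, n_points)
  fit <- lm(msd_um2 ~ lag_s, data = pts)
  m <- unname(coef(fit)[2])
  D <- m / 4
  per_track <- attr(msd, "per_track")
  lags_idx <- pts$lag_frames
  if (!is.null(per_track) &&
      all(lags_idx <= ncol(per_track)) &&
      sum(stats::complete.cases(per_track[, lags_idx, drop = FALSE])) >= 3) {
    sub <- per_track[stats::complete.cases(per_track[, lags_idx, drop = FALSE]),
                     lags_idx, drop = FALSE]
    nt <- nrow(sub)
    x <- pts$lag_s
    xc <- x - mean(x)
    slope_of <- function(y) sum(xc * (y - mean(y))) / sum(xc^2)
    tot <- colSums(sub)
    # delete-one jackknife over tracks; slope is linear in the mean curve
    jack <- vapply(seq_len(nt), function(i) slope_of((tot - sub[i, ]) / (nt - 1)),
                   numeric(1))
    se <- sqrt((nt - 1) / nt * sum((jack - mean(jack))^2))
    dfree <- nt - 1
  } else {
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
    dfree <- n_points - 2
  }
  ci95 <- qt(0.975, df = dfree) * se / 4
  if (m < 0) warn("fitted MSD slope is negative (subdiffusion or noise); D reported as-is.")
  structure(
    list(m = m, intercept = unname(coef(fit)[1]), D = D, ci95 = ci95,
         n_points_fit = n_points, negative_slope = m < 0),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g um^2/s (95%% CI), slope %.4g over %d points\n",
              x$D, x$ci95, x$m, x$n_points_fit))
  invisible(x)
}

#' Spatial mobility map of a filtered track set
#'
#' One point per track at its mean position, valued by its mean
#' frame-to-frame jump — the map that reveals spatial mobility structure
#' (e.g. reduced mobility at the nuclear periphery). See [plot_mobility_map()]
#' for the figure.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_um`, `y_um` (typically
#'   after [filter_bound()]).
#' @return tibble `track_id`, `n_frames`, `mean_jump_um`, `mean_x_um`,
#'   `mean_y_um` (class `mobility_map`). Empty input gives an empty map.
#' @export
mobility_map <- function(tracks) {
  out <- track_jump_stats(tracks)
  structure(out, class = c("mobility_map", class(out)))
}

#' Detect directed-transport events in a single track
#'
#' The instantaneous speed at each step is the displacement rate smoothed by
#' a centred moving average over `smoothing_frames` steps; a directed event
#' is at least `min_run_frames` consecutive smoothed samples above
#' `speed_threshold`. Also returns the cumulative travel distance (path
#' length from the track origin) through time.
#'
#' @param track tibble with `frame`, `x_um`, `y_um` for ONE track.
#' @param frame_interval_s seconds per frame.
#' @param speed_threshold um/s; 1 um/s is the conventional cutoff for
#'   motor-driven transport.
#' @param min_run_frames minimum consecutive above-threshold samples.
#' @param smoothing_frames centred moving-average window, steps (odd).
#' @return list with `events` (tibble `start_frame`, `end_frame`,
#'   `mean_speed_um_s`, `path_length_um`, `net_displacement_um`) and
#'   `profile` (tibble `frame`, `t_s`, `travel_um`, `speed_um_s`).
#' @export
directed_events <- function(track, frame_interval_s = 1, speed_threshold = 1,
                            min_run_frames = 3L, smoothing_frames = 3L) {
  check_number(frame_interval_s, "frame_interval_s", min = .Machine$double.eps)
  check_number(speed_threshold, "speed_threshold", min = 0)
  min_run_frames <- check_count(min_run_frames, "min_run_frames")
  smoothing_frames <- check_count(smoothing_frames, "smoothing_frames")
  track <- arrange(track, .data$frame)
  n <- nrow(track)
  empty_events <- tibble(start_frame = integer(), end_frame = integer(),
                         mean_speed_um_s = numeric(), path_length_um = numeric(),
                         net_displacement_um = numeric())
  steps <- if (n > 1) sqrt(diff(track$x_um)^2 + diff(track$y_um)^2) else numeric(0)
  profile <- tibble(
    frame = track$frame, t_s = track$frame * frame_interval_s,
    travel_um = c(0, cumsum(steps)),
    speed_um_s = c(NA_real_, moving_average(steps, smoothing_frames)) / frame_interval_s
  )
  if (n <= smoothing_frames) {
    return(list(events = empty_events, profile = profile))
  }
  above <- !is.na(profile$speed_um_s) & profile$speed_um_s > speed_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- list()
  for (k in which(r$values & r$lengths >= min_run_frames)) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- track[max(i0 - 1, 1):i1, ]
    path <- sum(sqrt(diff(seg$x_um)^2 + diff(seg$y_um)^2))
    net <- sqrt((seg$x_um[nrow(seg)] - seg$x_um[1])^2 +
                  (seg$y_um[nrow(seg)] - seg$y_um[1])^2)
    ev[[length(ev) + 1L]] <- tibble(
      start_frame = track$frame[i0], end_frame = track$frame[i1],
      # mean speed over the event from the raw path, not the smoothed samples
      mean_speed_um_s = path / ((nrow(seg) - 1) * frame_interval_s),
      path_length_um = path, net_displacement_um = net
    )
  }
  list(events = if (length(ev)) bind_rows(ev) else empty_events,
       profile = profile)
}

moving_average <- function(v, k) {
  if (length(v) == 0) return(numeric(0))
  if (k <= 1 || length(v) < k) return(v)
  half <- (k - 1) %/% 2
  vapply(seq_along(v), function(i) {
    mean(v[max(1, i - half):min(length(v), i + half)])
  }, numeric(1))
}
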