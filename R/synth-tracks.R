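#' Motion models for simulated emitters
#'
#' Describes how a simulated emitter moves between frames:
#' * `brownian` — isotropic 2-D diffusion; per-axis increments are Gaussian
#'   with variance `2 * D * dt`, so the frame-to-frame mean squared
#'   displacement is `4 * D * dt`.
#' * `bound` — the emitter stays at a fixed anchor with Gaussian positional
#'   jitter of standard deviation `jitter_sd` per axis (chromatin-bound
#'   molecules, translation sites tethered to large complexes).
#' * `motored` — alternating diffusive and directed (motor-driven) intervals;
#'   each directed segment has a duration, a speed and a heading, emulating
#'   transported mRNA particles.
#'
#' `mobility_field` lets the local diffusion coefficient vary across the
#' field (e.g. reduced mobility near the nuclear periphery): it is a function
#' `(x_um, y_um) -> scale` multiplying `D` at that position.
#'
#' @param kind `"brownian"`, `"bound"` or `"motored"`.
#' @param D diffusion coefficient, um^2/s (>= 0). For `motored`, the D of the
#'   diffusive intervals.
#' @param jitter_sd positional jitter of bound emitters, um (>= 0).
#' @param segments for `motored`: a data frame with columns
#'   `duration_s`, `speed_um_s`, `heading_rad` describing the directed runs;
#'   runs are separated by diffusive intervals of `pause_s` seconds.
#' @param pause_s duration of the diffusive interval between directed runs, s.
#' @param mobility_field optional function `(x_um, y_um) -> scale` for D.
#' @return A `motion_model` list.
#' @export
motion_model <- function(kind = c("brownian", "bound", "motored"),
                         D = 0.1, jitter_sd = 0.03,
                         segments = NULL, pause_s = 0,
                         mobility_field = NULL) {
  kind <- match.arg(kind)
  check_number(D, "D", min = 0)
  check_number(jitter_sd, "jitter_sd", min = 0)
  check_number(pause_s, "pause_s", min = 0)
  if (kind == "motored") {
    if (is.null(segments) || !all(c("duration_s", "speed_um_s", "heading_rad") %in% names(segments))) {
      abort("motored models need `segments` with duration_s, speed_um_s, heading_rad.")
    }
    if (any(segments$speed_um_s < 0) || any(segments$duration_s <= 0)) {
      abort("motored segment speeds must be >= 0 and durations > 0.")
    }
  }
  if (!is.null(mobility_field) && !is.function(mobility_field)) {
    abort("`mobility_field` must be a function (x_um, y_um) -> scale.")
  }
  structure(
    list(kind = kind, D = D, jitter_sd = jitter_sd,
         segments = segments, pause_s = pause_s, mobility_field = mobility_field),
    class = "motion_model"
  )
}

#' Simulate ground-truth emitter tracks
#'
#' Generates `n_tracks` trajectories of `n_frames` positions each under a
#' [motion_model], inside a rectangular field with reflecting boundaries (so
#' emitter density stays uniform). All positions are in micrometres; the
#' frame interval `dt` converts the diffusion coefficient into per-frame
#' jump variance. The same `seed` always reproduces the identical table.
#'
#' @param model a [motion_model].
#' @param n_tracks number of tracks (>= 1).
#' @param n_frames frames per track (>= 1).
#' @param dt frame interval, seconds (> 0).
#' @param bounds field box `c(xmin, xmax, ymin, ymax)` in um.
#' @param seed integer seed.
#' @return tibble with columns `track_id`, `frame` (0-based), `t_s`,
#'   `x_um`, `y_um`, `state` (`"diffusive"`, `"bound"` or `"directed"`).
#' @export
make_tracks <- function(model, n_tracks, n_frames, dt,
                        bounds = c(0, 33.3, 0, 33.3), seed = 1L) {
  if (!inherits(model, "motion_model")) abort("`model` must be a motion_model.")
  n_tracks <- check_count(n_tracks, "n_tracks")
  n_frames <- check_count(n_frames, "n_frames")
  check_number(dt, "dt", min = .Machine$double.eps)
  if (length(bounds) != 4 || !all(is.finite(bounds)) ||
      bounds[2] <= bounds[1] || bounds[4] <= bounds[3]) {
    abort("`bounds` must be finite c(xmin, xmax, ymin, ymax) with positive extents.")
  }
  set.seed(seed)
  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    x0 <- runif(1, bounds[1], bounds[2])
    y0 <- runif(1, bounds[3], bounds[4])
    pos <- switch(model$kind,
      bound = sim_bound(model, n_frames, x0, y0),
      brownian = sim_brownian(model, n_frames, dt, x0, y0, bounds),
      motored = sim_motored(model, n_frames, dt, x0, y0, bounds)
    )
    out[[i]] <- tibble(
      track_id = i,
      frame = seq_len(n_frames) - 1L,
      t_s = (seq_len(n_frames) - 1) * dt,
      x_um = reflect(pos$x, bounds[1], bounds[2]),
      y_um = reflect(pos$y, bounds[3], bounds[4]),
      state = pos$state
    )
  }
  bind_rows(out)
}

sim_bound <- function(model, n_frames, x0, y0) {
  list(
    x = x0 + rnorm(n_frames, 0, model$jitter_sd),
    y = y0 + rnorm(n_frames, 0, model$jitter_sd),
    state = rep("bound", n_frames)
  )
}

sim_brownian <- function(model, n_frames, dt, x0, y0, bounds) {
  x <- numeric(n_frames); y <- numeric(n_frames)
  x[1] <- x0; y[1] <- y0
  if (is.null(model$mobility_field)) {
    s <- sqrt(2 * model$D * dt)
    if (n_frames > 1) {
      x <- x0 + c(0, cumsum(rnorm(n_frames - 1, 0, s)))
      y <- y0 + c(0, cumsum(rnorm(n_frames - 1, 0, s)))
    }
  } else {
    for (k in seq_len(n_frames - 1)) {
      scale <- model$mobility_field(reflect(x[k], bounds[1], bounds[2]),
                                    reflect(y[k], bounds[3], bounds[4]))
      s <- sqrt(2 * model$D * max(scale, 0) * dt)
      x[k + 1] <- x[k] + rnorm(1, 0, s)
      y[k + 1] <- y[k] + rnorm(1, 0, s)
    }
  }
  list(x = x, y = y, state = rep("diffusive", n_frames))
}

sim_motored <- function(model, n_frames, dt, x0, y0, bounds) {
  # build a per-frame schedule: pause (diffusive) / run (directed) / pause ...
  seg <- model$segments
  vx <- numeric(n_frames); vy <- numeric(n_frames)
  state <- rep("diffusive", n_frames)
  t <- model$pause_s
  for (j in seq_len(nrow(seg))) {
    idx <- which((seq_len(n_frames) - 1) * dt >= t &
                 (seq_len(n_frames) - 1) * dt < t + seg$duration_s[j])
    vx[idx] <- seg$speed_um_s[j] * cos(seg$heading_rad[j])
    vy[idx] <- seg$speed_um_s[j] * sin(seg$heading_rad[j])
    state[idx] <- "directed"
    t <- t + seg$duration_s[j] + model$pause_s
  }
  s <- sqrt(2 * model$D * dt)
  dx <- vx[-n_frames] * dt + rnorm(n_frames - 1, 0, s) * (state[-n_frames] == "diffusive")
  dy <- vy[-n_frames] * dt + rnorm(n_frames - 1, 0, s) * (state[-n_frames] == "diffusive")
  list(x = x0 + c(0, cumsum(dx)), y = y0 + c(0, cumsum(dy)), state = state)
}

# fold positions back into [lo, hi] by reflection
reflect <- function(v, lo, hi) {
  w <- hi - lo
  u <- (v - lo) %% (2 * w)
  lo + ifelse(u > w, 2 * w - u, u)
}
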