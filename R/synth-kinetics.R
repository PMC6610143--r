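#' Simulate a FRAP experiment trace
#'
#' Produces the three intensity series a photobleaching experiment records:
#' the bleach-spot ROI, the whole-compartment reference, and a constant
#' imaging background. Before the bleach both ROI and whole sit at a plateau
#' of 1 (arbitrary units, above `background_value`); at the bleach frame the
#' ROI drops instantaneously by `bleach_depth` and recovers as
#' `I(t) = I0 + mobile_fraction * bleach_depth * (1 - exp(-k t))` with
#' `I0 = 1 - bleach_depth`. Both signal series additionally decay as
#' `exp(-acq_bleach_rate * t)` from the first frame, emulating acquisition
#' photobleaching of the whole cell — the factor the double normalization in
#' [normalize_frap()] is designed to cancel.
#'
#' @param k recovery rate, 1/s (> 0). `t_half = log(2) / k` for the
#'   single-exponential model.
#' @param mobile_fraction fraction of the bleached pool that recovers, `[0, 1]`.
#' @param bleach_depth fractional drop at the bleach, `(0, 1]`.
#' @param acq_bleach_rate acquisition-bleaching rate of the whole cell, 1/s.
#' @param pre_frames,post_frames frames before/after the bleach.
#' @param dt frame interval, s (> 0).
#' @param noise_sd additive Gaussian noise on each series.
#' @param seed integer seed.
#' @param background_value constant offset on all series.
#' @return tibble `time_s`, `roi_intensity`, `whole_intensity`, `background`,
#'   `phase`; attributes `bleach_frame` (row index of the first post-bleach
#'   sample) and the generating parameters.
#' @export
make_frap_trace <- function(k, mobile_fraction = 1, bleach_depth = 0.6,
                            acq_bleach_rate = 0, pre_frames = 10L,
                            post_frames = 120L, dt = 1, noise_sd = 0,
                            seed = 1L, background_value = 0.05) {
  check_number(k, "k", min = .Machine$double.eps)
  check_number(mobile_fraction, "mobile_fraction", min = 0, max = 1)
  check_number(bleach_depth, "bleach_depth", min = .Machine$double.eps, max = 1)
  check_number(acq_bleach_rate, "acq_bleach_rate", min = 0)
  pre_frames <- check_count(pre_frames, "pre_frames")
  post_frames <- check_count(post_frames, "post_frames")
  check_number(dt, "dt", min = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", min = 0)
  set.seed(seed)
  n <- pre_frames + post_frames
  time_s <- (seq_len(n) - 1) * dt
  t_post <- time_s - time_s[pre_frames + 1L]          # 0 at first post-bleach frame
  I0 <- 1 - bleach_depth
  roi <- ifelse(t_post < 0, 1, I0 + mobile_fraction * bleach_depth * (1 - exp(-k * pmax(t_post, 0))))
  whole <- rep(1, n)
  acq <- exp(-acq_bleach_rate * time_s)
  out <- tibble(
    time_s = time_s,
    roi_intensity = roi * acq + background_value + rnorm(n, 0, noise_sd),
    whole_intensity = whole * acq + background_value + rnorm(n, 0, noise_sd),
    background = background_value + rnorm(n, 0, noise_sd),
    phase = ifelse(t_post < 0, "pre", "post")
  )
  structure(out, bleach_frame = pre_frames + 1L,
            params = list(k = k, mobile_fraction = mobile_fraction,
                          bleach_depth = bleach_depth,
                          acq_bleach_rate = acq_bleach_rate,
                          background_value = background_value))
}

#' Simulate a one-to-one binding sensorgram
#'
#' Closed-form surface-binding kinetics for a single analyte concentration
#' `C`: during association
#' `R(t) = R_eq * (1 - exp(-(k_on * C + k_off) * t))` with
#' `R_eq = R_max * C * k_on / (C * k_on + k_off)`
#' (equivalently `R_max * C / (C + K_D)`, `K_D = k_off / k_on`); during
#' dissociation `R(t) = R(t_assoc) * exp(-k_off * (t - t_assoc))`.
#'
#' @param k_on association rate, 1/(M s) (>= 0).
#' @param k_off dissociation rate, 1/s (>= 0).
#' @param R_max saturating response, response units.
#' @param C analyte concentration, molar (>= 0).
#' @param t_assoc,t_dissoc phase durations, s.
#' @param dt sampling interval, s (> 0).
#' @param noise_sd additive Gaussian noise, response units.
#' @param seed integer seed.
#' @return tibble `time_s`, `response`, `phase` (`"association"` /
#'   `"dissociation"`), `concentration_M`; attribute `params`.
#' @export
make_sensorgram <- function(k_on, k_off, R_max, C,
                            t_assoc = 300, t_dissoc = 600, dt = 1,
                            noise_sd = 0, seed = 1L) {
  check_number(k_on, "k_on", min = 0)
  check_number(k_off, "k_off", min = 0)
  check_number(R_max, "R_max", min = 0)
  check_number(C, "C", min = 0)
  check_number(t_assoc, "t_assoc", min = 0)
  check_number(t_dissoc, "t_dissoc", min = 0)
  check_number(dt, "dt", min = .Machine$double.eps)
  check_number(noise_sd, "noise_sd", min = 0)
  set.seed(seed)
  time_s <- seq(0, t_assoc + t_dissoc, by = dt)
  r <- sensorgram_model(time_s, k_on, k_off, R_max, C, t_assoc)
  tibble(
    time_s = time_s,
    response = r + rnorm(length(r), 0, noise_sd),
    phase = ifelse(time_s <= t_assoc, "association", "dissociation"),
    concentration_M = C
  ) -> out
  structure(out, params = list(k_on = k_on, k_off = k_off, R_max = R_max,
                               C = C, t_assoc = t_assoc))
}

# noiseless closed form shared with fit_binding()
sensorgram_model <- function(time_s, k_on, k_off, R_max, C, t_assoc) {
  kobs <- k_on * C + k_off
  R_eq <- if (kobs > 0) R_max * C * k_on / kobs else 0
  r <- ifelse(time_s <= t_assoc,
              R_eq * (1 - exp(-kobs * time_s)),
              NA_real_)
  R_end <- R_eq * (1 - exp(-kobs * t_assoc))
  dis <- time_s > t_assoc
  r[dis] <- R_end * exp(-k_off * (time_s[dis] - t_assoc))
  r
}
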