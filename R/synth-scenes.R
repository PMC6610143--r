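#' Describe a translational-inhibitor run-off experiment
#'
#' After a ribosome-releasing drug is added at `drug_time_s`, nascent-chain
#' spots (channel 1) disappear with independent exponential waiting times at
#' `runoff_rate`, so the expected surviving fraction at time `t` is
#' `exp(-runoff_rate * (t - drug_time_s))`; mRNA spots (channel 2) persist
#' when `mrna_channel_persists` is `TRUE`.
#'
#' @param n_cells number of cells (>= 1).
#' @param spots_per_cell spots in each cell at t = 0 (>= 1).
#' @param drug_time_s drug-addition time, s (within the movie duration).
#' @param runoff_rate per-spot disappearance rate after the drug, 1/s (>= 0).
#' @param mrna_channel_persists keep an mRNA channel whose spots never vanish.
#' @return A `runoff_scene` list.
#' @export
runoff_scene <- function(n_cells = 3L, spots_per_cell = 16L,
                         drug_time_s = 100, runoff_rate = 0.02,
                         mrna_channel_persists = TRUE) {
  n_cells <- check_count(n_cells, "n_cells")
  spots_per_cell <- check_count(spots_per_cell, "spots_per_cell")
  check_number(drug_time_s, "drug_time_s", min = 0)
  check_number(runoff_rate, "runoff_rate", min = 0)
  structure(
    list(n_cells = n_cells, spots_per_cell = spots_per_cell,
         drug_time_s = drug_time_s, runoff_rate = runoff_rate,
         mrna_channel_persists = isTRUE(mrna_channel_persists)),
    class = "runoff_scene"
  )
}

#' Simulate a puromycin-style run-off scene
#'
#' Generates ground-truth spot presence per cell and frame under a
#' [runoff_scene], and optionally renders a two-channel movie of the first
#' cell's field. Spots jitter in place (tethered translation sites).
#'
#' @param scene a [runoff_scene].
#' @param optics an [optics]; its `frame_interval_s` sets the sampling.
#' @param n_frames number of frames; `drug_time_s` must fall inside.
#' @param seed integer seed.
#' @param render render a movie of cell 1 (default FALSE; the count table is
#'   what the run-off analysis consumes).
#' @return list with `spots` (tibble: `cell`, `spot_id`, `channel`, `frame`,
#'   `t_s`, `x_um`, `y_um`, `present`), `counts` (tibble: `cell`, `channel`,
#'   `frame`, `t_s`, `n_spots`) and `movie` (a [movie] or `NULL`).
#' @export
make_runoff_scene <- function(scene, optics, n_frames = 40L, seed = 1L,
                              render = FALSE) {
  if (!inherits(scene, "runoff_scene")) abort("`scene` must come from runoff_scene().")
  if (!inherits(optics, "optics")) abort("`optics` must come from optics().")
  n_frames <- check_count(n_frames, "n_frames")
  dt <- optics$frame_interval_s
  if (scene$drug_time_s >= n_frames * dt) {
    abort("`drug_time_s` must fall within the movie duration.")
  }
  set.seed(seed)
  fw <- optics$field_px[2] * optics$pixel_size_um
  fh <- optics$field_px[1] * optics$pixel_size_um
  t_s <- (seq_len(n_frames) - 1) * dt
  channels <- if (scene$mrna_channel_persists) 1:2 else 1L
  spots <- list()
  for (cell in seq_len(scene$n_cells)) {
    for (s in seq_len(scene$spots_per_cell)) {
      x0 <- runif(1, 0.1 * fw, 0.9 * fw); y0 <- runif(1, 0.1 * fh, 0.9 * fh)
      # exponential waiting time after the drug for the nascent-chain channel
      vanish_t <- if (scene$runoff_rate > 0) {
        scene$drug_time_s + rexp(1, scene$runoff_rate)
      } else Inf
      for (ch in channels) {
        present <- if (ch == 1L) t_s < vanish_t else rep(TRUE, n_frames)
        spots[[length(spots) + 1L]] <- tibble(
          cell = cell, spot_id = s, channel = ch,
          frame = seq_len(n_frames) - 1L, t_s = t_s,
          x_um = x0 + rnorm(n_frames, 0, 0.03),
          y_um = y0 + rnorm(n_frames, 0, 0.03),
          present = present
        )
      }
    }
  }
  spots <- bind_rows(spots)
  counts <- spots %>%
    group_by(.data$cell, .data$channel, .data$frame, .data$t_s) %>%
    summarise(n_spots = sum(.data$present), .groups = "drop")
  mv <- NULL
  if (render) {
    trk <- spots %>%
      filter(.data$cell == 1L, .data$present) %>%
      mutate(track_id = .data$spot_id + 1000L * .data$channel)
    mv <- render_movie(trk, optics, n_frames = n_frames,
                       n_channels = max(channels), seed = seed + 1L)
  }
  list(spots = spots, counts = counts, movie = mv,
       drug_time_s = scene$drug_time_s)
}

#' Simulate an early-embryo nuclear development sequence
#'
#' Renders a three-channel movie of disk-shaped nuclei that double in number
#' every `division_period_frames` frames (area roughly halving at each
#' division, as cleavage-stage blastomeres do):
#' * channel 1 — a nuclear **mask** channel (bright disks on dark background,
#'   emulating a constitutive nuclear label used for segmentation),
#' * channel 2 — a **probe** channel whose nuclear-to-cytoplasmic intensity
#'   ratio follows `expression_ramp`,
#' * channel 3 — a **target** channel following the same ramp.
#'
#' Ground truth records every nucleus centre, radius and the true Nuc/Cyt
#' ratio per frame.
#'
#' @param n_start_nuclei nuclei at frame 0 (>= 1).
#' @param division_period_frames frames between synchronous divisions.
#' @param n_frames total frames.
#' @param nucleus_radius_px starting nuclear radius, pixels (>= 2; smaller
#'   nuclei cannot be segmented).
#' @param optics an [optics]; `field_px` sets the frame size. The default
#'   emulates a low-magnification embryo time-lapse: 0.662 um pixels, one
#'   frame every 5 minutes, a 192 x 192 field.
#' @param expression_ramp nuclear-to-cytoplasmic ratio of the probe/target
#'   channels: length-2 `c(start, end)` (linear ramp) or a length-`n_frames`
#'   vector.
#' @param cyto_level cytoplasmic intensity of the probe/target channels, counts.
#' @param seed integer seed.
#' @return list with `movie` (three channels) and `nuclei` (tibble: `frame`,
#'   `nucleus_id`, `parent_id`, `x_px`, `y_px`, `x_um`, `y_um`, `radius_px`,
#'   `true_ratio`).
#' @export
make_embryo_sequence <- function(n_start_nuclei = 4L, division_period_frames = 10L,
                                 n_frames = 25L, nucleus_radius_px = 14,
                                 optics = NULL,
                                 expression_ramp = c(1, 2.5),
                                 cyto_level = 200, seed = 1L) {
  optics <- optics %||% spottrackr::optics(
    pixel_size_um = 0.662, background_level = 5, read_noise_sd = 1,
    frame_interval_s = 300, field_px = c(192L, 192L)
  )
  n_start_nuclei <- check_count(n_start_nuclei, "n_start_nuclei")
  division_period_frames <- check_count(division_period_frames, "division_period_frames")
  n_frames <- check_count(n_frames, "n_frames")
  check_number(nucleus_radius_px, "nucleus_radius_px", min = 2)
  check_number(cyto_level, "cyto_level", min = 1)
  ramp <- if (length(expression_ramp) == 2L) {
    seq(expression_ramp[1], expression_ramp[2], length.out = n_frames)
  } else if (length(expression_ramp) == n_frames) {
    as.numeric(expression_ramp)
  } else {
    abort("`expression_ramp` must have length 2 or n_frames.")
  }
  if (any(ramp <= 0)) abort("`expression_ramp` values must be > 0.")
  set.seed(seed)
  h <- optics$field_px[1]; w <- optics$field_px[2]

  # initial nuclei on a jittered grid, then synchronous divisions
  g <- ceiling(sqrt(n_start_nuclei))
  cx <- (rep(seq_len(g), g)[seq_len(n_start_nuclei)] - 0.5) * w / g
  cy <- (rep(seq_len(g), each = g)[seq_len(n_start_nuclei)] - 0.5) * h / g
  nuc <- tibble(
    nucleus_id = seq_len(n_start_nuclei), parent_id = NA_integer_,
    x_px = cx + rnorm(n_start_nuclei, 0, 2),
    y_px = cy + rnorm(n_start_nuclei, 0, 2),
    radius_px = nucleus_radius_px
  )
  next_id <- n_start_nuclei + 1L
  margin <- function(r) r + 6
  truth <- vector("list", n_frames)
  arr <- array(0, c(n_frames, 3L, 1L, h, w))
  for (f in seq_len(n_frames)) {
    if (f > 1 && (f - 1) %% division_period_frames == 0) {
      kids <- vector("list", nrow(nuc))
      for (i in seq_len(nrow(nuc))) {
        ang <- runif(1, 0, 2 * pi)
        r_new <- nuc$radius_px[i] / sqrt(2)
        if (r_new < 2) r_new <- 2     # segmentability floor
        sep <- 1.6 * nuc$radius_px[i]
        kids[[i]] <- tibble(
          nucleus_id = c(next_id, next_id + 1L),
          parent_id = nuc$nucleus_id[i],
          x_px = nuc$x_px[i] + c(1, -1) * sep / 2 * cos(ang),
          y_px = nuc$y_px[i] + c(1, -1) * sep / 2 * sin(ang),
          radius_px = r_new
        )
        next_id <- next_id + 2L
      }
      nuc <- bind_rows(kids)
    }
    # slow random drift, clamped inside the field
    nuc$x_px <- nuc$x_px + rnorm(nrow(nuc), 0, 0.3)
    nuc$y_px <- nuc$y_px + rnorm(nrow(nuc), 0, 0.3)
    # relax overlaps so neighbouring nuclei stay individually segmentable
    for (iter in seq_len(40)) {
      moved <- FALSE
      if (nrow(nuc) > 1) {
        for (i in seq_len(nrow(nuc) - 1)) for (j in (i + 1):nrow(nuc)) {
          minsep <- nuc$radius_px[i] + nuc$radius_px[j] + 5
          dx <- nuc$x_px[j] - nuc$x_px[i]; dy <- nuc$y_px[j] - nuc$y_px[i]
          d <- sqrt(dx^2 + dy^2)
          if (d < minsep) {
            if (d < 1e-6) { dx <- 1; dy <- 0; d <- 1 }
            push <- (minsep - d) / 2 + 0.5
            nuc$x_px[i] <- nuc$x_px[i] - push * dx / d
            nuc$y_px[i] <- nuc$y_px[i] - push * dy / d
            nuc$x_px[j] <- nuc$x_px[j] + push * dx / d
            nuc$y_px[j] <- nuc$y_px[j] + push * dy / d
            moved <- TRUE
          }
        }
      }
      nuc$x_px <- pmin(pmax(nuc$x_px, margin(nuc$radius_px)), w - 1 - margin(nuc$radius_px))
      nuc$y_px <- pmin(pmax(nuc$y_px, margin(nuc$radius_px)), h - 1 - margin(nuc$radius_px))
      if (!moved) break
    }
    disk <- matrix(FALSE, h, w)
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    ys <- matrix(rep(0:(h - 1), w), h, w)
    for (i in seq_len(nrow(nuc))) {
      disk <- disk | ((xs - nuc$x_px[i])^2 + (ys - nuc$y_px[i])^2 <= nuc$radius_px[i]^2)
    }
    mask_img <- ifelse(disk, 1000, 20)
    probe_img <- ifelse(disk, ramp[f] * cyto_level, cyto_level)
    for (ch in 1:3) {
      base <- switch(ch, mask_img, probe_img, probe_img)
      img <- rpois(h * w, base + optics$background_level) +
        rnorm(h * w, 0, optics$read_noise_sd)
      arr[f, ch, 1L, , ] <- pmax(round(matrix(img, h, w)), 0)
    }
    truth[[f]] <- mutate(nuc, frame = f - 1L, true_ratio = ramp[f],
                         x_um = .data$x_px * optics$pixel_size_um,
                         y_um = .data$y_px * optics$pixel_size_um)
  }
  list(
    movie = movie(arr, optics$pixel_size_um, optics$frame_interval_s,
                  channel_names = c("mask", "probe", "target")),
    nuclei = bind_rows(truth) %>%
      select("frame", "nucleus_id", "parent_id", "x_px", "y_px",
             "x_um", "y_um", "radius_px", "true_ratio")
  )
}
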