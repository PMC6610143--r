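#' Link localizations into tracks by nearest-neighbour search
#'
#' For every pair of consecutive frames, candidate matches between active
#' tracks and next-frame localizations within `max_disp` are assigned
#' greedily in ascending order of pairwise distance (globally, one-to-one;
#' exact ties are broken by lower row index, so linking is deterministic and
#' independent of input row order). Unclaimed localizations seed new tracks;
#' a track unmatched for more than `memory_frames` consecutive frames is
#' terminated. The default `memory_frames = 0` forbids gaps, matching the
#' consecutive-frame requirement of the bound-molecule filter.
#'
#' @param locs tibble with `frame` (integer), `x_um`, `y_um` and optionally
#'   `channel` (linking is per channel).
#' @param max_disp maximum frame-to-frame displacement, um (> 0).
#' @param memory_frames frames a track may go unmatched before termination.
#' @return tibble: the input rows plus `track_id`, ordered by track then
#'   frame.
#' @export
link_nearest_neighbor <- function(locs, max_disp = 0.22, memory_frames = 0L) {
  check_number(max_disp, "max_disp", min = .Machine$double.eps)
  memory_frames <- check_count(memory_frames, "memory_frames", min = 0L)
  needed <- c("frame", "x_um", "y_um")
  if (!all(needed %in% names(locs))) {
    abort("`locs` needs columns frame, x_um, y_um.")
  }
  if (nrow(locs) == 0) return(mutate(locs, track_id = integer()))
  if (!"channel" %in% names(locs)) locs$channel <- 1L
  locs <- locs %>% arrange(.data$channel, .data$frame, .data$x_um, .data$y_um)
  out <- vector("list", length(unique(locs$channel)))
  next_id <- 1L
  for (ci in seq_along(unique(locs$channel))) {
    ch <- unique(locs$channel)[ci]
    sub <- filter(locs, .data$channel == ch)
    sub$track_id <- NA_integer_
    frames <- sort(unique(sub$frame))
    # active tracks: id, last x/y, last frame
    act <- tibble(track_id = integer(), x = numeric(), y = numeric(),
                  last_frame = integer())
    for (f in frames) {
      rows <- which(sub$frame == f)
      act <- filter(act, f - .data$last_frame <= memory_frames + 1L)
      claimed_row <- rep(FALSE, length(rows))
      claimed_trk <- rep(FALSE, nrow(act))
      if (nrow(act) > 0 && length(rows) > 0) {
        d2 <- outer(act$x, sub$x_um[rows], "-")^2 +
          outer(act$y, sub$y_um[rows], "-")^2
        cand <- which(d2 <= max_disp^2, arr.ind = TRUE)
        if (nrow(cand) > 0) {
          ord <- order(d2[cand], cand[, 1], cand[, 2])
          for (k in ord) {
            i <- cand[k, 1]; j <- cand[k, 2]
            if (claimed_trk[i] || claimed_row[j]) next
            claimed_trk[i] <- TRUE; claimed_row[j] <- TRUE
            id <- act$track_id[i]
            sub$track_id[rows[j]] <- id
            act$x[i] <- sub$x_um[rows[j]]; act$y[i] <- sub$y_um[rows[j]]
            act$last_frame[i] <- f
          }
        }
      }
      new_rows <- rows[!claimed_row]
      if (length(new_rows) > 0) {
        ids <- next_id + seq_along(new_rows) - 1L
        next_id <- next_id + length(new_rows)
        sub$track_id[new_rows] <- ids
        act <- bind_rows(act, tibble(
          track_id = ids, x = sub$x_um[new_rows], y = sub$y_um[new_rows],
          last_frame = f
        ))
      }
    }
    out[[ci]] <- sub
  }
  bind_rows(out) %>% arrange(.data$track_id, .data$frame)
}

#' Keep only tracks consistent with stably bound molecules
#'
#' The classic mobility filter used to isolate chromatin-bound molecules
#' from freely diffusing ones: a track is retained only if it lasts at least
#' `min_length_frames` consecutive frames AND every frame-to-frame jump is
#' strictly below `max_jump_nm`. The defaults (16 frames, 220 nm) are the
#' gate commonly used to distinguish bound from unbound nuclear factors.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_um`, `y_um`.
#' @param min_length_frames minimum track length, frames (>= 2).
#' @param max_jump_nm maximum allowed jump, nanometres (> 0).
#' @return the retained rows, original order preserved. Idempotent.
#' @export
filter_bound <- function(tracks, min_length_frames = 16L, max_jump_nm = 220) {
  min_length_frames <- check_count(min_length_frames, "min_length_frames", min = 2L)
  check_number(max_jump_nm, "max_jump_nm", min = .Machine$double.eps)
  if (nrow(tracks) == 0) return(tracks)
  keep <- tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    summarise(
      n_frames = dplyr::n(),
      max_jump_um = if (dplyr::n() > 1) {
        max(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2))
      } else NA_real_,
      .groups = "drop"
    ) %>%
    filter(.data$n_frames >= min_length_frames,
           .data$max_jump_um < max_jump_nm / 1000) %>%
    pull("track_id")
  filter(tracks, .data$track_id %in% keep)
}

#' Per-track summary: mean position, mean jump, length
#'
#' The mean jump is the arithmetic mean of per-step Euclidean displacements
#' (the quantity mobility maps are coloured by); it is `NA` for length-1
#' tracks.
#'
#' @param tracks tibble with `track_id`, `frame`, `x_um`, `y_um`.
#' @return tibble `track_id`, `n_frames`, `mean_jump_um`, `mean_x_um`,
#'   `mean_y_um`.
#' @export
track_jump_stats <- function(tracks) {
  if (nrow(tracks) == 0) {
    return(tibble(track_id = integer(), n_frames = integer(),
                  mean_jump_um = numeric(), mean_x_um = numeric(),
                  mean_y_um = numeric()))
  }
  tracks %>%
    group_by(.data$track_id) %>%
    arrange(.data$frame, .by_group = TRUE) %>%
    summarise(
      n_frames = dplyr::n(),
      mean_jump_um = if (dplyr::n() > 1) {
        mean(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2))
      } else NA_real_,
      mean_x_um = mean(.data$x_um),
      mean_y_um = mean(.data$y_um),
      .groups = "drop"
    )
}
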