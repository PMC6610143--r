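#' Segment nuclei in a 2-D frame
#'
#' Threshold, connected components, discard components below `min_area`,
#' return an integer-labelled mask. Intended for a dedicated nuclear-marker
#' channel (bright nuclei on dark background) of a max-projected frame.
#'
#' @param frame 2-D numeric matrix.
#' @param threshold `"otsu"` (default), `"mean_sd"` (mean + `nsd` * SD) or
#'   `"fixed"` (use `thr_value`).
#' @param thr_value fixed threshold value.
#' @param nsd SD multiplier for `"mean_sd"`.
#' @param min_area minimum component area, px^2.
#' @return integer label matrix, 0 = background. No surviving component
#'   gives an all-zero labelling.
#' @export
segment_nuclei <- function(frame, threshold = c("otsu", "mean_sd", "fixed"),
                           thr_value = NULL, nsd = 2, min_area = 20) {
  threshold <- match.arg(threshold)
  if (!is.matrix(frame)) abort("`frame` must be a 2-D matrix.")
  thr <- switch(threshold,
    otsu = {
      rng <- range(frame)
      if (diff(rng) == 0) Inf
      else rng[1] + EBImage::otsu(EBImage::Image((frame - rng[1]) / diff(rng)),
                                  range = c(0, 1)) * diff(rng)
    },
    mean_sd = mean(frame) + nsd * sd(frame),
    fixed = {
      if (is.null(thr_value)) abort("`thr_value` required for threshold = 'fixed'.")
      thr_value
    }
  )
  bw <- frame > thr
  if (!any(bw)) return(matrix(0L, nrow(frame), ncol(frame)))
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  lab[!(lab %in% keep)] <- 0L
  # relabel compactly, preserving order
  relab <- match(lab, c(0L, keep)) - 1L
  matrix(as.integer(relab), nrow(frame), ncol(frame))
}

#' Measure labelled regions: area and centroid
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @return tibble `label`, `area_px2`, `x_px`, `y_px` (0-based centroids).
#' @export
region_table <- function(labels) {
  idx <- which(labels > 0)
  if (!length(idx)) {
    return(tibble(label = integer(), area_px2 = integer(),
                  x_px = numeric(), y_px = numeric()))
  }
  rows <- ((idx - 1) %% nrow(labels))
  cols <- ((idx - 1) %/% nrow(labels))
  tibble(label = labels[idx], y = rows, x = cols) %>%
    group_by(.data$label) %>%
    summarise(area_px2 = dplyr::n(), x_px = mean(.data$x), y_px = mean(.data$y),
              .groups = "drop")
}

# exact Euclidean dilation distance: for every pixel, distance to the
# nearest pixel of `mask` (0 inside the mask)
dist_to_mask <- function(mask) {
  inv <- matrix(1, nrow(mask), ncol(mask))
  inv[mask] <- 0
  as.matrix(EBImage::distmap(inv, metric = "euclidean"))
}

#' Cytoplasmic ring masks around labelled nuclei
#'
#' Per nucleus, the ring is `dilate(mask, outer) \ dilate(mask, inner)` with
#' an exact Euclidean disk structuring element — i.e. the pixels at
#' morphological distance in `(inner, outer]` from that nucleus. Pixels
#' within `inner` of *any* nucleus are excluded (so rings never touch
#' neighbouring nuclei), rings are clipped at the frame edges, and a pixel
#' reachable from several nuclei is assigned to the nearer one (ties to the
#' lower label), making the assignment deterministic.
#'
#' @param labels integer label matrix.
#' @param outer_dilation_px,inner_dilation_px dilation radii, px;
#'   `outer > inner >= 0`. Defaults 4 and 1, the classic perinuclear ring.
#' @return integer matrix of ring labels (same label ids as `labels`).
#' @export
cytoplasm_ring <- function(labels, outer_dilation_px = 4, inner_dilation_px = 1) {
  check_number(outer_dilation_px, "outer_dilation_px", min = 0)
  check_number(inner_dilation_px, "inner_dilation_px", min = 0)
  if (outer_dilation_px <= inner_dilation_px) {
    abort("`outer_dilation_px` must be > `inner_dilation_px`.")
  }
  ids <- sort(unique(labels[labels > 0]))
  ring <- matrix(0L, nrow(labels), ncol(labels))
  if (!length(ids)) return(ring)
  dmin <- matrix(Inf, nrow(labels), ncol(labels))
  owner <- matrix(0L, nrow(labels), ncol(labels))
  for (id in ids) {
    d <- dist_to_mask(labels == id)
    upd <- d < dmin          # strict: tie keeps the lower (earlier) label
    dmin[upd] <- d[upd]
    owner[upd] <- id
  }
  sel <- dmin > inner_dilation_px & dmin <= outer_dilation_px
  ring[sel] <- owner[sel]
  ring
}

#' Region-to-ring intensity ratios (Nuc/Cyt, Mito/Bg)
#'
#' For each label, the mean intensity inside the region divided by the mean
#' intensity in its cytoplasmic ring (nuclear-to-cytoplasmic ratio), or by
#' the mean over a caller-supplied background mask (`background_mask`, the
#' mitochondria-to-background convention). Labels whose ring is empty are
#' dropped with a warning.
#'
#' @param frame 2-D intensity matrix.
#' @param region_labels integer label matrix.
#' @param ring_labels matching ring labels from [cytoplasm_ring()]; ignored
#'   when `background_mask` is given.
#' @param background_mask optional logical matrix: one shared background
#'   region.
#' @return tibble `label`, `area_px2`, `mean_in`, `mean_ring`, `ratio`.
#' @export
region_ratio <- function(frame, region_labels, ring_labels = NULL,
                         background_mask = NULL) {
  if (!all(dim(frame) == dim(region_labels))) {
    abort("`frame` and `region_labels` must share dimensions.")
  }
  ids <- sort(unique(region_labels[region_labels > 0]))
  if (!length(ids)) {
    return(tibble(label = integer(), area_px2 = integer(),
                  mean_in = numeric(), mean_ring = numeric(), ratio = numeric()))
  }
  mean_in <- vapply(ids, function(id) mean(frame[region_labels == id]), numeric(1))
  area <- vapply(ids, function(id) sum(region_labels == id), numeric(1))
  if (!is.null(background_mask)) {
    if (!any(background_mask)) abort("`background_mask` is empty.")
    mean_ring <- rep(mean(frame[background_mask]), length(ids))
  } else {
    if (is.null(ring_labels)) abort("supply `ring_labels` or `background_mask`.")
    mean_ring <- vapply(ids, function(id) {
      px <- frame[ring_labels == id]
      if (length(px)) mean(px) else NA_real_
    }, numeric(1))
  }
  out <- tibble(label = ids, area_px2 = as.integer(area),
                mean_in = mean_in, mean_ring = mean_ring,
                ratio = mean_in / mean_ring)
  if (anyNA(out$mean_ring)) {
    warn(sprintf("%d region(s) dropped: empty cytoplasmic ring.", sum(is.na(out$mean_ring))))
    out <- filter(out, !is.na(.data$mean_ring))
  }
  out
}

#' Ratio of two means with first-order propagated SEM
#'
#' `ratio = m1 / m2`; by the delta method
#' `sem = |ratio| * sqrt((sem1 / m1)^2 + (sem2 / m2)^2)`. This is the
#' standard way to report a fold difference between two group means with an
#' uncertainty.
#'
#' @param m1,sem1 numerator mean and its SEM.
#' @param m2,sem2 denominator mean and its SEM (`m2 != 0`).
#' @return tibble `ratio`, `sem`.
#' @export
ratio_of_means <- function(m1, sem1, m2, sem2) {
  check_number(m1, "m1"); check_number(m2, "m2")
  check_number(sem1, "sem1", min = 0); check_number(sem2, "sem2", min = 0)
  if (m2 == 0) abort("`m2` must be nonzero.")
  ratio <- m1 / m2
  tibble(ratio = ratio,
         sem = abs(ratio) * sqrt((sem1 / m1)^2 + (sem2 / m2)^2))
}

#' Normalized spot-count run-off curve with cell-to-cell SEM
#'
#' Each cell's spot counts are divided by that cell's own pre-drug mean, so
#' the pre-drug segment averages 1 by construction; the curve is the mean of
#' the normalized counts across cells with the across-cell SEM. Cells with a
#' zero pre-drug mean are excluded (with a warning).
#'
#' @param counts tibble `cell`, `t_s`, `n_spots` and optionally `channel`.
#' @param drug_time_s drug addition time, s; at least one pre-drug time
#'   point per cell is required.
#' @return tibble `channel`, `t_s`, `mean_norm`, `sem_norm`, `n_cells`.
#' @export
runoff_curve <- function(counts, drug_time_s) {
  check_number(drug_time_s, "drug_time_s", min = 0)
  if (!all(c("cell", "t_s", "n_spots") %in% names(counts))) {
    abort("`counts` needs columns cell, t_s, n_spots.")
  }
  if (!"channel" %in% names(counts)) counts$channel <- 1L
  if (!any(counts$t_s < drug_time_s)) abort("no pre-drug time points.")
  pre <- counts %>%
    filter(.data$t_s < drug_time_s) %>%
    group_by(.data$cell, .data$channel) %>%
    summarise(pre_mean = mean(.data$n_spots), .groups = "drop")
  bad <- filter(pre, .data$pre_mean == 0)
  if (nrow(bad) > 0) {
    warn(sprintf("%d cell/channel series excluded: zero pre-drug spot count.", nrow(bad)))
  }
  counts %>%
    left_join(filter(pre, .data$pre_mean > 0), by = c("cell", "channel")) %>%
    filter(!is.na(.data$pre_mean)) %>%
    mutate(norm = .data$n_spots / .data$pre_mean) %>%
    group_by(.data$channel, .data$t_s) %>%
    summarise(
      mean_norm = mean(.data$norm),
      sem_norm = if (dplyr::n() > 1) sd(.data$norm) / sqrt(dplyr::n()) else 0,
      n_cells = dplyr::n(),
      .groups = "drop"
    )
}

#' Colocalization of two spot tables by mutual nearest neighbour
#'
#' Per frame, spots of table A are paired with spots of table B by mutual
#' nearest neighbour within `radius_um` (both tables must already be in one
#' coordinate frame — register the second camera first). The colocalized
#' fraction is `matched_A / total_A`.
#'
#' @param table_a,table_b tibbles with `frame`, `x_um`, `y_um`.
#' @param radius_um matching radius, um.
#' @return list with `pairs` (tibble `frame`, `x_a`, `y_a`, `x_b`, `y_b`,
#'   `dist_um`) and `fraction` (scalar; `NA` when table A is empty).
#' @export
colocalize_spots <- function(table_a, table_b, radius_um = 0.5) {
  check_number(radius_um, "radius_um", min = .Machine$double.eps)
  if (nrow(table_a) == 0) {
    return(list(pairs = tibble(frame = integer(), x_a = numeric(), y_a = numeric(),
                               x_b = numeric(), y_b = numeric(), dist_um = numeric()),
                fraction = NA_real_))
  }
  pairs <- list()
  for (f in sort(unique(table_a$frame))) {
    a <- filter(table_a, .data$frame == f)
    b <- filter(table_b, .data$frame == f)
    if (nrow(b) == 0) next
    p <- pair_mutual_nn(
      tibble(x_px = a$x_um, y_px = a$y_um),
      tibble(x_px = b$x_um, y_px = b$y_um),
      gate = radius_um
    )
    if (nrow(p) > 0) {
      pairs[[length(pairs) + 1L]] <- tibble(
        frame = f, x_a = p$ref_x, y_a = p$ref_y, x_b = p$mov_x, y_b = p$mov_y,
        dist_um = sqrt((p$ref_x - p$mov_x)^2 + (p$ref_y - p$mov_y)^2)
      )
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(frame = integer(), x_a = numeric(), y_a = numeric(),
           x_b = numeric(), y_b = numeric(), dist_um = numeric())
  list(pairs = pairs, fraction = nrow(pairs) / nrow(table_a))
}

#' Box-whisker style distribution summary
#'
#' Median, 25-75% box, 5-95% whiskers (linear-interpolation quantiles,
#' R type 7), plus mean, SEM and n — the convention used for population
#' panels of per-cell measurements.
#'
#' @param values numeric vector, `n >= 1`; NAs are dropped.
#' @return one-row tibble `median`, `p25`, `p75`, `p5`, `p95`, `mean`,
#'   `sem`, `n`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) abort("`values` is empty.")
  q <- quantile(values, c(0.5, 0.25, 0.75, 0.05, 0.95), type = 7, names = FALSE)
  tibble(
    median = q[1], p25 = q[2], p75 = q[3], p5 = q[4], p95 = q[5],
    mean = mean(values),
    sem = if (length(values) > 1) sd(values) / sqrt(length(values)) else 0,
    n = length(values)
  )
}

#' Track nuclei through divisions and emit lineage statistics
#'
#' Frame-to-frame identity is assigned by mask overlap: each nucleus in
#' frame `t` is matched to the previous-frame nucleus whose mask, dilated by
#' `link_dilation_px`, overlaps it most (ties to the lower label). A parent
#' with one child continues its lineage; a parent with several children
#' divides, each child starting a new lineage branch linked to the parent.
#' When `intensity_frames` is supplied, each nucleus also gets its
#' nuclear-to-cytoplasmic ratio via [cytoplasm_ring()] + [region_ratio()].
#'
#' @param label_frames list of integer label matrices (one per frame).
#' @param intensity_frames optional list of intensity matrices for ratios.
#' @param link_dilation_px dilation used for overlap matching, px.
#' @param outer_dilation_px,inner_dilation_px ring parameters for the ratio.
#' @return list with `nuclei` (tibble `frame`, `lineage_id`,
#'   `parent_lineage`, `label`, `area_px2`, `x_px`, `y_px`, `ratio`) and
#'   `per_frame` (tibble `frame`, `n_nuclei`, `mean_area_px2`, `mean_ratio`).
#' @export
track_nuclei <- function(label_frames, intensity_frames = NULL,
                         link_dilation_px = 4,
                         outer_dilation_px = 4, inner_dilation_px = 1) {
  if (!length(label_frames)) abort("`label_frames` is empty.")
  if (!is.null(intensity_frames) && length(intensity_frames) != length(label_frames)) {
    abort("`intensity_frames` must match `label_frames` in length.")
  }
  next_lineage <- 1L
  prev_labels <- NULL
  prev_lineage_of <- NULL   # named: label -> lineage
  rows <- list()
  for (f in seq_along(label_frames)) {
    lab <- label_frames[[f]]
    tab <- region_table(lab)
    if (nrow(tab) == 0) {
      if (f < length(label_frames)) warn(sprintf("frame %d has zero nuclei; lineages terminated.", f - 1L))
      prev_labels <- NULL; prev_lineage_of <- NULL
      next
    }
    ratio <- rep(NA_real_, nrow(tab))
    if (!is.null(intensity_frames)) {
      ring <- cytoplasm_ring(lab, outer_dilation_px, inner_dilation_px)
      rr <- region_ratio(intensity_frames[[f]], lab, ring)
      ratio <- rr$ratio[match(tab$label, rr$label)]
    }
    lineage <- integer(nrow(tab))
    parent <- rep(NA_integer_, nrow(tab))
    if (is.null(prev_labels)) {
      lineage <- next_lineage + seq_len(nrow(tab)) - 1L
      next_lineage <- next_lineage + nrow(tab)
    } else {
      # overlap of each current nucleus with each dilated previous nucleus
      prev_ids <- as.integer(names(prev_lineage_of))
      best_prev <- rep(NA_integer_, nrow(tab))
      best_ovl <- rep(0, nrow(tab))
      for (pid in prev_ids) {
        dil <- dist_to_mask(prev_labels == pid) <= link_dilation_px
        for (i in seq_len(nrow(tab))) {
          ovl <- sum(dil & (lab == tab$label[i]))
          if (ovl > best_ovl[i]) { best_ovl[i] <- ovl; best_prev[i] <- pid }
        }
      }
      kids_of <- table(best_prev[!is.na(best_prev)])
      for (i in seq_len(nrow(tab))) {
        if (is.na(best_prev[i])) {
          lineage[i] <- next_lineage; next_lineage <- next_lineage + 1L
        } else {
          par_lin <- prev_lineage_of[[as.character(best_prev[i])]]
          if (kids_of[[as.character(best_prev[i])]] == 1L) {
            lineage[i] <- par_lin          # lineage continues
          } else {
            lineage[i] <- next_lineage     # division: new branch
            parent[i] <- par_lin
            next_lineage <- next_lineage + 1L
          }
        }
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      frame = f - 1L, lineage_id = lineage, parent_lineage = parent,
      label = tab$label, area_px2 = tab$area_px2,
      x_px = tab$x_px, y_px = tab$y_px, ratio = ratio
    )
    prev_labels <- lab
    prev_lineage_of <- as.list(setNames(lineage, tab$label))
  }
  nuclei <- if (length(rows)) bind_rows(rows) else
    tibble(frame = integer(), lineage_id = integer(), parent_lineage = integer(),
           label = integer(), area_px2 = integer(), x_px = numeric(),
           y_px = numeric(), ratio = numeric())
  per_frame <- nuclei %>%
    group_by(.data$frame) %>%
    summarise(n_nuclei = dplyr::n(),
              mean_area_px2 = mean(.data$area_px2),
              mean_ratio = mean(.data$ratio),
              .groups = "drop")
  list(nuclei = nuclei, per_frame = per_frame)
}
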