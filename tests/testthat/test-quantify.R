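test_that("nuclear segmentation labels bright disks and ignores noise", {
  lab2 <- disk_labels(8, 96, cx = 24, cy = 24)
  lab2[disk_labels(8, 96, cx = 70, cy = 70) > 0] <- 1L
  img <- matrix(10, 96, 96); img[lab2 > 0] <- 500
  seg <- segment_nuclei(img)
  expect_equal(max(seg), 2)

  expect_equal(max(segment_nuclei(matrix(3, 64, 64))), 0)

  emb <- make_embryo_sequence(4, 10, 11, 12, seed = 21)
  final <- segment_nuclei(movie_frame(emb$movie, 11, 1))
  truth <- emb$nuclei[emb$nuclei$frame == 10, ]
  expect_equal(max(final), 8)
  found <- region_table(final)
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((found$x_px - truth$x_px[i])^2 + (found$y_px - truth$y_px[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("cytoplasmic rings equal the brute-force morphological distance shell", {
  lab <- disk_labels(10, 64)
  ring <- cytoplasm_ring(lab, 4, 1)
  bf <- brute_force_dist(lab > 0)
  expect_identical(unname(ring > 0), unname(bf > 1 & bf <= 4))

  # rings are disjoint from the 1-px-dilated nucleus, exactly
  expect_equal(sum(ring > 0 & bf <= 1), 0)

  expect_error(cytoplasm_ring(lab, 2, 2), "outer")

  # a mask touching the frame edge has a clipped (smaller) ring
  lab_edge <- disk_labels(10, 64, cx = 2, cy = 31.5)
  ring_edge <- cytoplasm_ring(lab_edge, 4, 1)
  expect_lt(sum(ring_edge > 0), sum(ring > 0))

  # two nearby nuclei: overlap pixels go to the nearer nucleus
  lab2 <- disk_labels(6, 64, cx = 24, cy = 32)
  lab2[disk_labels(6, 64, cx = 40, cy = 32) > 0] <- 2L
  r2 <- cytoplasm_ring(lab2, 4, 1)
  d1 <- brute_force_dist(lab2 == 1); d2 <- brute_force_dist(lab2 == 2)
  both <- which(r2 > 0 & d1 <= 4 & d2 <= 4)
  expect_true(all((r2[both] == 1) == (d1[both] < d2[both]) |
                    (d1[both] == d2[both] & r2[both] == 1)))
})

test_that("region ratios are exact on constructed intensity fields", {
  lab <- disk_labels(10, 64)
  ring <- cytoplasm_ring(lab, 4, 1)

  uni <- matrix(7, 64, 64)
  expect_equal(region_ratio(uni, lab, ring)$ratio, 1)

  # region twice as bright as its ring
  img2 <- matrix(50, 64, 64); img2[lab > 0] <- 100
  expect_equal(region_ratio(img2, lab, ring)$ratio, 2)

  # invariance to positive scaling
  expect_equal(region_ratio(img2 * 3.7, lab, ring)$ratio, 2, tolerance = 1e-12)

  # caller-supplied background region (the organelle-to-background convention)
  bg <- matrix(FALSE, 64, 64); bg[1:10, 1:10] <- TRUE
  rb <- region_ratio(img2, lab, background_mask = bg)
  expect_equal(rb$ratio, 2)

  # synthetic embryo at true ratio 2.5: measured within 10%
  emb <- make_embryo_sequence(4, 10, 21, 14, seed = 22)
  labf <- segment_nuclei(movie_frame(emb$movie, 21, 1))
  rr <- region_ratio(movie_frame(emb$movie, 21, 2), labf, cytoplasm_ring(labf))
  expect_lt(abs(mean(rr$ratio) - 2.5) / 2.5, 0.1)
})

test_that("ratio of means propagates SEM by the delta method", {
  # the mitochondrial signal-amplification worked example
  r <- ratio_of_means(16.6, 1.5, 3.5, 0.2)
  expect_equal(round(r$ratio, 1), 4.7)
  expect_equal(round(r$sem, 1), 0.5)

  expect_equal(unlist(ratio_of_means(3, 0, 3, 0)), c(ratio = 1, sem = 0))
  r2 <- ratio_of_means(10, 1, 5, 0)
  expect_equal(r2$ratio, 2)
  expect_equal(r2$sem, 0.2)
  expect_error(ratio_of_means(1, 0.1, 0, 0.1), "nonzero")
})

test_that("run-off curves self-normalize per cell with cell-to-cell SEM", {
  const <- tidyr::expand_grid(cell = 1:3, t_s = seq(0, 90, by = 10))
  const$n_spots <- 20
  cv <- runoff_curve(const, drug_time_s = 50)
  expect_true(all(cv$mean_norm == 1))
  expect_true(all(cv$sem_norm == 0))
  expect_true(all(abs(cv$mean_norm[cv$t_s < 50] - 1) < 1e-12))

  sc <- runoff_scene(n_cells = 6, spots_per_cell = 40, drug_time_s = 100,
                     runoff_rate = 0.02)
  sim <- make_runoff_scene(sc, optics(frame_interval_s = 10), n_frames = 40, seed = 23)
  cv2 <- runoff_curve(sim$counts, 100)
  ch1 <- cv2[cv2$channel == 1 & cv2$t_s > 100, ]
  expected <- exp(-0.02 * (ch1$t_s - 100))
  # binomial error on 6 x 40 spots, plus the cell-to-cell SEM
  binom <- 4 * sqrt(expected * (1 - expected) / 240)
  expect_true(all(abs(ch1$mean_norm - expected) <= 2 * ch1$sem_norm + binom + 0.01))
  # the persistent mRNA channel stays at 1
  expect_true(all(abs(cv2$mean_norm[cv2$channel == 2] - 1) < 1e-12))

  # a cell with zero pre-drug spots is excluded with a warning
  bad <- dplyr::bind_rows(const, tibble::tibble(cell = 9, t_s = seq(0, 90, by = 10),
                                                n_spots = 0))
  expect_warning(cvb <- runoff_curve(bad, 50), "excluded")
  expect_true(all(cvb$n_cells == 3))
})

test_that("spot colocalization counts mutual pairs within the radius", {
  set.seed(24)
  a <- tibble::tibble(frame = rep(0:1, each = 50),
                      x_um = runif(100) * 30, y_um = runif(100) * 30)
  expect_equal(colocalize_spots(a, a, 0.5)$fraction, 1)

  off <- dplyr::mutate(a, x_um = x_um + 2)
  expect_equal(colocalize_spots(a, off, 0.5)$fraction, 0)

  # 70% of channel-A spots sit on channel-B positions
  b <- dplyr::bind_rows(a[c(1:35, 51:85), ],
                        tibble::tibble(frame = rep(0:1, each = 15),
                                       x_um = runif(30) * 30 + 200,
                                       y_um = runif(30) * 30))
  expect_equal(colocalize_spots(a, b, 0.3)$fraction, 0.7, tolerance = 0.05)

  expect_true(is.na(colocalize_spots(a[0, ], a, 0.5)$fraction))
})

test_that("distribution summary uses linear-interpolation order statistics", {
  s <- summarize_distribution(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$p25, 25.75)
  expect_equal(s$p75, 75.25)
  expect_equal(s$p5, 5.95)
  expect_equal(s$p95, 95.05)

  s1 <- summarize_distribution(42)
  expect_true(all(unlist(s1[c("median", "p25", "p75", "p5", "p95", "mean")]) == 42))
  expect_equal(s1$sem, 0)

  set.seed(25)
  v <- rnorm(200)
  expect_equal(summarize_distribution(v), summarize_distribution(sample(v)))
})

test_that("nucleus tracking follows lineages through divisions", {
  emb <- make_embryo_sequence(4, 10, 21, 14, seed = 26)
  labs <- lapply(1:21, function(t) segment_nuclei(movie_frame(emb$movie, t, 1)))
  probes <- lapply(1:21, function(t) movie_frame(emb$movie, t, 2))
  res <- track_nuclei(labs, probes)
  pf <- res$per_frame
  expect_equal(pf$n_nuclei[pf$frame == 0], 4)
  expect_equal(pf$n_nuclei[pf$frame == 10], 8)
  expect_equal(pf$n_nuclei[pf$frame == 20], 16)

  # daughters point back to a parent lineage at division frames
  div <- res$nuclei[res$nuclei$frame == 10, ]
  expect_true(all(!is.na(div$parent_lineage)))

  # nuclear area roughly halves at each division
  a0 <- pf$mean_area_px2[pf$frame == 9]; a1 <- pf$mean_area_px2[pf$frame == 10]
  expect_lt(abs(a1 / a0 - 0.5), 0.2 * 0.5)

  # stationary nuclei: one unbroken lineage each
  lab_static <- disk_labels(8, 64)
  res2 <- track_nuclei(replicate(5, lab_static, simplify = FALSE))
  expect_equal(length(unique(res2$nuclei$lineage_id)), 1)
  expect_equal(nrow(res2$nuclei), 5)
})
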