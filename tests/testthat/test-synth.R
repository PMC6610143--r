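test_that("brownian tracks have the closed-form jump variance and D=0 is stationary", {
  tr0 <- make_tracks(motion_model("brownian", D = 0), 5, 20, 1,
                     bounds = c(0, 100, 0, 100), seed = 1)
  expect_equal(max(tapply(tr0$x_um, tr0$track_id, function(v) diff(range(v)))), 0)

  # 10^4 jumps at D = 0.1, dt = 1: mean squared displacement 4 D dt = 0.4
  tr <- make_tracks(motion_model("brownian", D = 0.1), 100, 101, 1,
                    bounds = c(0, 1e4, 0, 1e4), seed = 2)
  jumps2 <- unlist(tapply(seq_len(nrow(tr)), tr$track_id, function(i) {
    diff(tr$x_um[i])^2 + diff(tr$y_um[i])^2
  }))
  expect_equal(length(jumps2), 1e4)
  expect_lt(abs(mean(jumps2) - 0.4), 4 * sd(jumps2) / sqrt(length(jumps2)))

  # per-axis increments are Gaussian at matched variance 2 D dt
  dx <- unlist(tapply(seq_len(nrow(tr)), tr$track_id, function(i) diff(tr$x_um[i])))
  expect_gt(stats::shapiro.test(sample(dx, 4999))$p.value, 0.01)
  expect_lt(abs(var(dx) - 0.2), 0.01)
})

test_that("generators are deterministic under a fixed seed", {
  mm <- motion_model("brownian", D = 0.05)
  expect_identical(make_tracks(mm, 10, 10, 1, seed = 7),
                   make_tracks(mm, 10, 10, 1, seed = 7))
  opt <- optics(field_px = c(32, 32))
  tr <- make_tracks(mm, 3, 4, opt$frame_interval_s, bounds = c(1, 3, 1, 3), seed = 1)
  expect_identical(render_movie(tr, opt, seed = 3)[, , , , ],
                   render_movie(tr, opt, seed = 3)[, , , , ])
  expect_identical(make_frap_trace(0.01, noise_sd = 0.05, seed = 5),
                   make_frap_trace(0.01, noise_sd = 0.05, seed = 5))
  expect_identical(make_sensorgram(1e5, 1e-3, 100, 5e-8, noise_sd = 1, seed = 5),
                   make_sensorgram(1e5, 1e-3, 100, 5e-8, noise_sd = 1, seed = 5))
  sc <- runoff_scene(n_cells = 2, spots_per_cell = 5)
  opt_slow <- optics(frame_interval_s = 10)
  expect_identical(make_runoff_scene(sc, opt_slow, n_frames = 30, seed = 2)$counts,
                   make_runoff_scene(sc, opt_slow, n_frames = 30, seed = 2)$counts)
  expect_identical(make_embryo_sequence(2, 5, 6, 8, seed = 4)$nuclei,
                   make_embryo_sequence(2, 5, 6, 8, seed = 4)$nuclei)
})

test_that("bound and motored motion models respect their parameters", {
  trb <- make_tracks(motion_model("bound", jitter_sd = 0.03), 50, 50, 1,
                     bounds = c(0, 100, 0, 100), seed = 3)
  spread <- tapply(trb$x_um, trb$track_id, sd)
  expect_lt(abs(mean(spread) - 0.03), 0.005)

  seg <- data.frame(duration_s = 5, speed_um_s = 2, heading_rad = 0)
  trm <- make_tracks(motion_model("motored", D = 0, segments = seg, pause_s = 3),
                     1, 15, 1, bounds = c(0, 100, 0, 100), seed = 1)
  # directed frames move at exactly the segment velocity along the heading
  d <- trm[trm$state == "directed", ]
  expect_equal(diff(d$x_um), rep(2, nrow(d) - 1), tolerance = 1e-12)
  expect_equal(diff(d$y_um), rep(0, nrow(d) - 1), tolerance = 1e-12)
  expect_error(motion_model("motored"), "segments")
  expect_error(make_tracks(motion_model("brownian", D = NaN), 1, 2, 1), "finite")
})

test_that("rendered movies conserve the photon budget and handle limit cases", {
  img <- render_single_spot(16, 16, amp = 100, bg = 10, sigma = 1.0)
  expect_lt(abs(sum(img) - (10 * length(img) + 100 * 2 * pi * 1^2)) /
              (100 * 2 * pi), 0.01)

  # a zero-amplitude emitter renders as pure background
  opt0 <- optics(photons_per_spot = 0, background_level = 50,
                 read_noise_sd = 0, field_px = c(32, 32))
  trk <- tibble::tibble(track_id = 1L, frame = 0L, x_um = 2, y_um = 2)
  m0 <- render_movie(trk, opt0, noise = FALSE, digitize = FALSE)
  expect_true(all(movie_frame(m0, 1) == 50))

  # empty track table is a valid pure-background movie
  m_empty <- render_movie(tibble::tibble(), opt0, n_frames = 2, noise = FALSE)
  expect_equal(dim(m_empty)[1], 2)
  expect_true(all(m_empty == 50))

  # instant bleaching: emitter visible in at most the first frame
  opt <- optics(photons_per_spot = 500, background_level = 0,
                read_noise_sd = 0, frame_interval_s = 1, field_px = c(32, 32))
  trk5 <- tibble::tibble(track_id = 1L, frame = 0:4, x_um = 2, y_um = 2)
  mb <- render_movie(trk5, opt, photo_kinetics(bleach_rate = 100),
                     noise = FALSE, digitize = FALSE, seed = 1)
  expect_true(all(apply(mb[2:5, 1, 1, , ], 1, max) == 0))

  expect_error(optics(psf_sigma_px = -1), "psf_sigma_px")
})

test_that("FRAP trace generator matches its closed form", {
  k <- log(2) / 141
  tr <- make_frap_trace(k, mobile_fraction = 1, bleach_depth = 0.6,
                        pre_frames = 10, post_frames = 400, dt = 1,
                        noise_sd = 0, background_value = 0)
  post <- tr[tr$phase == "post", ]
  t_post <- post$time_s - post$time_s[1]
  expect_equal(post$roi_intensity, 0.4 + 0.6 * (1 - exp(-k * t_post)), tolerance = 1e-12)
  # half of the recovery amplitude is reached at exactly t_half = ln2 / k
  target <- 0.4 + 0.6 / 2
  expect_equal(approx(post$roi_intensity, t_post, xout = target)$y, 141,
               tolerance = 1e-3)

  # immobile pool: flat at the bleached level
  tr0 <- make_frap_trace(k, mobile_fraction = 0, bleach_depth = 0.6,
                         noise_sd = 0, background_value = 0)
  expect_true(all(abs(tr0$roi_intensity[tr0$phase == "post"] - 0.4) < 1e-12))

  # k >> 1: full recovery by the first sampled post-bleach interval
  trf <- make_frap_trace(1e4, pre_frames = 5, post_frames = 10, dt = 1,
                         noise_sd = 0, background_value = 0)
  expect_equal(trf$roi_intensity[trf$phase == "post"][2], 1, tolerance = 1e-9)
  expect_error(make_frap_trace(0.01, dt = 0), "dt")
})

test_that("sensorgram generator matches one-to-one binding closed forms", {
  # C = 0: flat zero association
  s0 <- make_sensorgram(1e5, 1e-3, 100, 0, t_assoc = 100, t_dissoc = 100)
  expect_true(all(s0$response == 0))

  # half-saturation identity: C = K_D gives R_eq = R_max / 2
  KD <- 1e-3 / 1e5
  sh <- make_sensorgram(1e5, 1e-3, 100, KD, t_assoc = 2e5, t_dissoc = 10)
  expect_equal(max(sh$response), 50, tolerance = 1e-4)

  # the in-vitro anchor: k_off/k_on = 14.7 nM, C = 100 nM -> R_eq/R_max = 100/114.7
  sa <- make_sensorgram(1e5, 1.47e-3, 100, 100e-9, t_assoc = 3e5, t_dissoc = 10)
  expect_equal(max(sa$response) / 100, 100 / 114.7, tolerance = 1e-3)

  expect_error(make_sensorgram(-1, 1e-3, 100, 1e-8), "k_on")
})

test_that("run-off scene follows the exponential survival law", {
  opt <- optics(frame_interval_s = 10)
  sc0 <- runoff_scene(n_cells = 2, spots_per_cell = 10, drug_time_s = 100,
                      runoff_rate = 0)
  sim0 <- make_runoff_scene(sc0, opt, n_frames = 30, seed = 1)
  expect_true(all(sim0$counts$n_spots == 10))

  schi <- runoff_scene(n_cells = 2, spots_per_cell = 10, drug_time_s = 100,
                       runoff_rate = 50)
  simhi <- make_runoff_scene(schi, opt, n_frames = 30, seed = 1)
  post <- simhi$counts[simhi$counts$channel == 1 & simhi$counts$t_s > 110, ]
  expect_true(all(post$n_spots == 0))

  sc <- runoff_scene(n_cells = 6, spots_per_cell = 40, drug_time_s = 100,
                     runoff_rate = 0.02)
  sim <- make_runoff_scene(sc, opt, n_frames = 40, seed = 2)
  ch1 <- sim$counts[sim$counts$channel == 1, ]
  for (tt in c(150, 200, 300)) {
    n <- sum(ch1$n_spots[ch1$t_s == tt])
    p <- exp(-0.02 * (tt - 100))
    expect_lt(abs(n - 240 * p), 3 * sqrt(240 * p * (1 - p)) + 1)
  }
  # mRNA channel persists
  expect_true(all(sim$counts$n_spots[sim$counts$channel == 2] == 40))
})

test_that("embryo sequence doubles nuclei on schedule and encodes the ramp", {
  emb <- make_embryo_sequence(n_start_nuclei = 4, division_period_frames = 10,
                              n_frames = 12, nucleus_radius_px = 12, seed = 1)
  counts <- table(emb$nuclei$frame)
  expect_equal(unname(counts[["9"]]), 4)
  expect_equal(unname(counts[["10"]]), 8)
  expect_equal(emb$nuclei$true_ratio[emb$nuclei$frame == 0][1], 1)

  # constant parity ramp: true ratio 1 everywhere
  embc <- make_embryo_sequence(2, 5, 6, 8, expression_ramp = c(1, 1), seed = 2)
  expect_true(all(embc$nuclei$true_ratio == 1))

  # ramp 1 -> 2.5 reaches exactly 2.5 at the final frame
  embr <- make_embryo_sequence(2, 10, 8, 8, expression_ramp = c(1, 2.5), seed = 3)
  expect_equal(max(embr$nuclei$true_ratio), 2.5)
  expect_error(make_embryo_sequence(2, 5, 6, nucleus_radius_px = 1.5), "radius")
})
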