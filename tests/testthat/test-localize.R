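test_that("spot detection finds rendered spots and nothing in flat frames", {
  expect_equal(nrow(detect_spots(matrix(5, 32, 32))), 0)
  expect_error(detect_spots(matrix(c(NA, rep(1, 32 * 32 - 1)), 32)), "finite")
  expect_error(detect_spots(matrix(1, 8, 8)), "16")

  img <- render_single_spot(20, 12, amp = 100, bg = 10)
  det <- detect_spots(img)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 20), 0.5)
  expect_lt(abs(det$y_px - 12), 0.5)

  # two spots 20 px apart give two components
  opt <- optics(psf_sigma_px = 1.3, photons_per_spot = 100, background_level = 10,
                read_noise_sd = 0, field_px = c(48, 48))
  trk <- tibble::tibble(track_id = 1:2, frame = 0L,
                        x_um = c(10, 30) * 0.13, y_um = c(24, 24) * 0.13)
  img2 <- movie_frame(render_movie(trk, opt, noise = FALSE, digitize = FALSE), 1)
  expect_equal(nrow(detect_spots(img2)), 2)

  # otsu strategy also works on a clean spot
  expect_equal(nrow(detect_spots(img, threshold = "otsu")), 1)
})

test_that("2-D Gaussian fit recovers all five parameters on a noiseless spot", {
  img <- render_single_spot(5.3, 4.7, amp = 100, bg = 10, sigma = 1.3,
                            field = c(16L, 16L))
  fit <- fit_gaussian_2d(img, 5, 5, window_halfwidth = 7)
  expect_true(fit$converged)
  expect_lt(abs(fit$I_BG - 10), 1e-3)
  expect_lt(abs(fit$I - 100), 1e-3)
  expect_lt(abs(fit$x0 - 5.3), 1e-3)
  expect_lt(abs(fit$y0 - 4.7), 1e-3)
  expect_lt(abs(fit$sigma_x - 1.3), 1e-3)
  expect_lt(abs(fit$sigma_y - 1.3), 1e-3)

  # basin check: perturbed initializations land on the same optimum
  for (dx in c(-0.5, 0.5)) for (dy in c(-0.5, 0.5)) {
    f2 <- fit_gaussian_2d(img, 5 + dx, 5 + dy, window_halfwidth = 7)
    expect_lt(abs(f2$x0 - fit$x0), 1e-3)
    expect_lt(abs(f2$y0 - fit$y0), 1e-3)
  }
})

test_that("gaussian fit degrades gracefully and absorbs constant offsets", {
  flat <- matrix(7, 16, 16)
  f <- fit_gaussian_2d(flat, 8, 8)
  expect_false(f$converged)
  expect_error(fit_gaussian_2d(matrix(1, 16, 16), 1, 1, window_halfwidth = 2), "5 x 5")

  img <- render_single_spot(7.2, 8.1, amp = 80, bg = 20, sigma = 1.1,
                            field = c(16L, 16L))
  f1 <- fit_gaussian_2d(img, 7, 8)
  f2 <- fit_gaussian_2d(img + 55.5, 7, 8)
  expect_lt(abs((f2$I_BG - f1$I_BG) - 55.5), 1e-9)
  expect_lt(abs(f2$I - f1$I), 1e-9)
  expect_lt(abs(f2$x0 - f1$x0), 1e-9)
  expect_lt(abs(f2$y0 - f1$y0), 1e-9)
  expect_lt(abs(f2$sigma_x - f1$sigma_x), 1e-9)
})

test_that("movie localization matches ground truth and scales with photon count", {
  px <- 0.13
  g <- expand.grid(x = seq(8, 56, by = 12), y = seq(8, 56, by = 12))
  base <- tibble::tibble(track_id = seq_len(nrow(g)))
  truth <- dplyr::bind_rows(lapply(0:19, function(f) {
    tibble::tibble(track_id = base$track_id, frame = f,
                   x_um = g$x * px, y_um = g$y * px)
  }))
  opt <- optics(photons_per_spot = 150, background_level = 100,
                read_noise_sd = 2, field_px = c(64, 64))
  mv <- render_movie(truth, opt, seed = 11)
  loc <- localize_movie(mv)
  # match every localization to the nearest ground-truth emitter of its frame
  matched <- 0; fp <- 0; err2 <- c()
  for (f in 0:19) {
    lt <- truth[truth$frame == f, ]; lf <- loc[loc$frame == f, ]
    for (i in seq_len(nrow(lf))) {
      d2 <- (lf$x_px[i] - lt$x_um / px)^2 + (lf$y_px[i] - lt$y_um / px)^2
      if (min(d2) < 1) { matched <- matched + 1; err2 <- c(err2, min(d2)) }
      else fp <- fp + 1
    }
  }
  expect_gte(matched / nrow(truth), 0.99)       # >= 99% of emitters recovered
  expect_lt(fp / max(nrow(loc), 1), 0.01)       # false positives < 1%
  expect_lt(sqrt(mean(err2)), 0.15)             # localization RMSE at SNR ~ 10

  # precision improves monotonically as the photon budget doubles
  rmse_at <- function(amp) {
    o <- optics(photons_per_spot = amp, background_level = 100,
                read_noise_sd = 2, field_px = c(64, 64))
    m <- render_movie(truth[truth$frame < 5, ], o, seed = 21)
    l <- localize_movie(m)
    e <- c()
    for (f in 0:4) {
      lt <- truth[truth$frame == f, ]; lf <- l[l$frame == f, ]
      for (i in seq_len(nrow(lf))) {
        d2 <- (lf$x_px[i] - lt$x_um / px)^2 + (lf$y_px[i] - lt$y_um / px)^2
        if (min(d2) < 1) e <- c(e, min(d2))
      }
    }
    sqrt(mean(e))
  }
  r <- vapply(c(100, 200, 400, 800), rmse_at, numeric(1))
  expect_true(all(diff(r) < 0))

  # empty movie gives an empty table
  m0 <- render_movie(tibble::tibble(), optics(field_px = c(32, 32)), n_frames = 3,
                     noise = FALSE)
  expect_equal(nrow(localize_movie(m0)), 0)
  expect_error(localize_movie(m0, channel = 2), "channel")
})

test_that("drift estimation recovers integer and sub-pixel shifts", {
  set.seed(4)
  base <- EBImage::gblur(matrix(rnorm(64 * 64), 64), 2)  # smooth scene
  shift_int <- function(m, dy, dx) {
    m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
  }
  arr <- array(0, c(3, 64, 64))
  arr[1, , ] <- base
  arr[2, , ] <- base
  arr[3, , ] <- shift_int(base, -2, 3)
  mv <- movie(arr, 0.13, 1)
  dr <- estimate_drift(mv)
  expect_equal(dr$dx_px[2], 0, tolerance = 1e-9)
  expect_equal(dr$dx_px[3], 3, tolerance = 0.05)
  expect_equal(dr$dy_px[3], -2, tolerance = 0.05)

  # half-pixel shift via Fourier interpolation, recovered within 0.2 px
  shift_sub <- function(m, dx) {
    Fm <- stats::fft(m)
    kx <- c(0:(ncol(m) / 2 - 1), -(ncol(m) / 2):-1)
    ph <- exp(-2i * pi * outer(rep(1, nrow(m)), kx) * dx / ncol(m))
    Re(stats::fft(Fm * ph, inverse = TRUE)) / length(m)
  }
  arr2 <- array(0, c(2, 64, 64))
  arr2[1, , ] <- base
  arr2[2, , ] <- shift_sub(base, 0.5)
  dr2 <- estimate_drift(movie(arr2, 0.13, 1))
  expect_lt(abs(dr2$dx_px[2] - 0.5), 0.2)
  expect_lt(abs(dr2$dy_px[2]), 0.2)

  # featureless frames: zero drift, flagged unconfident
  arr3 <- array(1, c(2, 32, 32))
  dr3 <- estimate_drift(movie(arr3, 0.13, 1))
  expect_true(all(dr3$dx_px == 0))
  expect_false(any(dr3$confident))
})

test_that("registration recovers translation, similarity and affine transforms", {
  ref <- fiducial_grid()
  # pure translation: exact recovery, zero residual
  mov <- dplyr::mutate(ref, x_px = x_px + 5, y_px = y_px - 3)
  tf <- fit_registration(ref, mov, "translation", gate_px = 10)
  expect_equal(tf$offset, c(-5, 3), tolerance = 1e-12)
  expect_lt(tf$rmse_px, 1e-12)

  # 2-degree rotation about the field centre + shift, similarity model
  th <- 2 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  P <- t(R %*% (t(as.matrix(ref)) - 128) + 128 + c(5, -3))
  mov2 <- tibble::tibble(x_px = P[, 1], y_px = P[, 2])
  tf2 <- fit_registration(ref, mov2, "similarity", gate_px = 12)
  expect_lt(tf2$rmse_px, 1e-6)
  expect_equal(abs(atan2(tf2$matrix[2, 1], tf2$matrix[1, 1])), th, tolerance = 1e-6)
  mapped <- apply_registration(tf2, mov2)
  expect_lt(max(abs(mapped$x_px - ref$x_px)), 1e-6)

  # 0.1 px noise on ~100 beads: residual sits at the noise floor
  set.seed(8)
  mov3 <- dplyr::mutate(mov2, x_px = x_px + rnorm(dplyr::n(), 0, 0.1),
                        y_px = y_px + rnorm(dplyr::n(), 0, 0.1))
  tf3 <- fit_registration(ref, mov3, "affine", gate_px = 12)
  expect_gt(tf3$n_pairs, 100)
  expect_lt(abs(tf3$rmse_px - 0.1 * sqrt(2)), 0.05)

  # residual never increases with model complexity
  r <- vapply(c("translation", "similarity", "affine"), function(m) {
    fit_registration(ref, mov3, m, gate_px = 12)$rmse_px
  }, numeric(1))
  expect_true(all(diff(r) <= 1e-9))

  expect_error(fit_registration(ref[1:2, ], mov[1:2, ], "affine"), "3")
})

test_that("apply_registration is invertible and identity-safe", {
  locs <- tibble::tibble(x_px = c(0, 10, 50), y_px = c(0, 5, 20),
                         x_um = c(0, 10, 50) * 0.13, y_um = c(0, 5, 20) * 0.13)
  ident <- structure(list(model = "translation", matrix = diag(2),
                          offset = c(0, 0), rmse_px = 0, n_pairs = 1),
                     class = "registration_transform")
  expect_equal(apply_registration(ident, locs, pixel_size_um = 0.13), locs)

  tr1 <- structure(list(model = "translation", matrix = diag(2),
                        offset = c(1, 1), rmse_px = 0, n_pairs = 1),
                   class = "registration_transform")
  one <- tibble::tibble(x_px = 0, y_px = 0)
  expect_equal(unlist(apply_registration(tr1, one)), c(x_px = 1, y_px = 1))

  aff <- structure(list(model = "affine",
                        matrix = matrix(c(1.01, 0.02, -0.03, 0.99), 2),
                        offset = c(2, -1), rmse_px = 0, n_pairs = 4),
                   class = "registration_transform")
  fwd <- apply_registration(aff, locs, pixel_size_um = 0.13)
  back <- apply_registration(aff, fwd, pixel_size_um = 0.13, inverse = TRUE)
  expect_lt(max(abs(back$x_px - locs$x_px)), 1e-9)
  expect_lt(max(abs(back$y_px - locs$y_px)), 1e-9)

  # JSON round trip
  p <- withr::local_tempfile(fileext = ".json")
  write_registration(aff, p)
  aff2 <- read_registration(p)
  expect_equal(aff2$matrix, aff$matrix)
  expect_equal(aff2$offset, aff$offset)
})
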