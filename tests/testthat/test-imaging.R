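# Small optics used throughout: rendering full 512x256 halves is only done
# once, in the density test.
small_optics <- function(...) optics_model(psf_sigma = 1.2,
                                           frame_shape = c(64L, 64L), ...)

const_traj <- function(I_D, I_A, n_frames = 5L, dt = 0.1) {
  structure(list(times = (seq_len(n_frames) - 1) * dt,
                 I_D = rep(I_D, n_frames), I_A = rep(I_A, n_frames),
                 truth = data.frame()), class = "molecule_trajectory")
}

test_that("rendering conserves flux and zero molecules give pure background", {
  opt <- small_optics(background = 0)
  tr <- const_traj(150, 250)
  mv <- render_movie(list(tr), opt, positions = cbind(x = 31.4, y = 30.7),
                     noise = FALSE)
  for (f in 1:5) {
    expect_equal(sum(mv$donor[, , f]), 150, tolerance = 1e-3)
    expect_equal(sum(mv$acceptor[, , f]), 250, tolerance = 1e-3)
  }
  empty <- render_movie(list(), optics_model(frame_shape = c(32L, 32L),
                                             background = 7), noise = FALSE)
  expect_true(all(empty$donor == 7) && all(empty$acceptor == 7))
})

test_that("spot detection controls false positives and localizes real spots", {
  opt <- small_optics(background = 20)
  set.seed(12)
  # pure background + Poisson noise: no detections at 5 sigma in >= 99%
  fp <- vapply(1:100, function(r) {
    frame <- matrix(stats::rpois(64 * 64, 20), 64, 64)
    nrow(detect_spots(frame, opt, threshold_sigmas = 5))
  }, numeric(1L))
  expect_gte(mean(fp == 0), 0.99)

  # a single spot at SNR 10 is found within 1 pixel
  tr <- const_traj(400, 0, n_frames = 1L)
  mv <- render_movie(list(tr), opt, positions = cbind(x = 25.3, y = 40.6),
                     noise = TRUE)
  sp <- detect_spots(mv$donor[, , 1], opt)
  expect_identical(nrow(sp), 1L)
  expect_lt(sqrt((sp$x - 25.3)^2 + (sp$y - 40.6)^2), 1)

  # two spots 6 sigma apart are resolved as exactly two
  mv2 <- render_movie(list(tr, tr), opt,
                      positions = cbind(x = c(20, 20 + 6 * 1.2), y = c(32, 32)),
                      noise = TRUE)
  expect_identical(nrow(detect_spots(mv2$donor[, , 1], opt)), 2L)

  expect_error(detect_spots(matrix(c(1, NA, 1, 1), 2, 2), opt), "non-finite")
})

test_that("detection recall and precision hold at the default field density", {
  set.seed(23)
  opt <- optics_model(psf_sigma = 1.2, frame_shape = c(512L, 256L),
                      background = 20)
  trajs <- rep(list(const_traj(400, 0, n_frames = 1L)), 400)
  mv <- render_movie(trajs, opt, noise = TRUE)
  sp <- detect_spots(mv$donor[, , 1], opt)
  dmat <- sqrt(outer(sp$x, mv$positions[, 1], "-")^2 +
                 outer(sp$y, mv$positions[, 2], "-")^2)
  recall <- mean(apply(dmat, 2, min) < 1)     # truth spots found
  precision <- mean(apply(dmat, 1, min) < 1)  # detections that are real
  expect_gte(recall * 400, 396)
  expect_gte(precision, 0.99)
})

test_that("channel pairing matches under offsets and is order-invariant", {
  spots <- data.frame(x = c(10, 30, 50.5), y = c(12, 44, 20),
                      intensity = c(5, 6, 7))
  opt0 <- small_optics()
  p <- pair_channels(spots, spots, opt0, tol_px = 2)
  expect_identical(nrow(p$pairs), 3L)
  expect_true(all(p$pairs$residual_px == 0))
  expect_identical(nrow(p$unmatched_donor), 0L)

  # acceptor list shifted by exactly the channel offset: all matched
  opt <- small_optics(channel_offset = c(3.5, -2))
  shifted <- transform(spots, x = x + 3.5, y = y - 2)
  p2 <- pair_channels(spots, shifted, opt, tol_px = 1)
  expect_identical(nrow(p2$pairs), 3L)
  expect_lt(max(p2$pairs$residual_px), 1e-9)

  # order invariance of the greedy matching
  perm <- spots[c(3, 1, 2), ]
  p3 <- pair_channels(perm, shifted, opt, tol_px = 1)
  expect_equal(sort(p3$pairs$x_d), sort(p2$pairs$x_d))

  # one empty channel: no pairs, everything unmatched
  none <- spots[0, ]
  p4 <- pair_channels(spots, none, opt0, tol_px = 2)
  expect_identical(nrow(p4$pairs), 0L)
  expect_identical(nrow(p4$unmatched_donor), 3L)

  expect_error(pair_channels(spots, spots, opt0, tol_px = 0), "positive")
})

test_that("the image path round-trips trajectories and FRET efficiency", {
  set.seed(31)
  co <- simulate_conversion_cohort(6, 1 / 3, 1 / 3, dt = 0.2, duration = 30,
                                   snr = 50, E_closed = 0.75, delta_E = 0.5)
  opt <- optics_model(psf_sigma = 1.2, frame_shape = c(96L, 96L),
                      background = 2, channel_offset = c(1.5, -0.5))
  mv <- render_movie(co, opt, noise = TRUE)

  # detect on temporal mean images so dark excursions don't lose molecules
  mean_frame <- function(stack) apply(stack, c(1, 2), mean)
  sp_d <- detect_spots(mean_frame(mv$donor), opt)
  sp_a <- detect_spots(mean_frame(mv$acceptor), opt)
  pairs <- pair_channels(sp_d, sp_a, opt, tol_px = 2)
  expect_identical(nrow(pairs$pairs), 6L)

  rec <- extract_trajectories(mv, pairs$pairs, aperture_radius_px = 4, dt = 0.2)

  # match recovered trajectories back to ground truth by position
  truth_idx <- apply(
    outer(pairs$pairs$x_d, mv$positions[, 1], "-")^2 +
      outer(pairs$pairs$y_d, mv$positions[, 2], "-")^2, 1, which.min)
  err_I <- err_E <- numeric(0)
  for (i in seq_along(rec)) {
    tru <- co[[truth_idx[i]]]
    bright <- tru$I_D + tru$I_A > 100
    err_I <- c(err_I,
               (rec[[i]]$I_D[bright] - tru$I_D[bright]) /
                 pmax(tru$I_D[bright], 1),
               (rec[[i]]$I_A[bright & tru$I_A > 0] -
                  tru$I_A[bright & tru$I_A > 0]) /
                 pmax(tru$I_A[bright & tru$I_A > 0], 1))
    E_rec <- fret_efficiency(rec[[i]], signal_floor = 50)$E
    E_tru <- fret_efficiency(tru, signal_floor = 50)$E
    ok <- !is.na(E_rec) & !is.na(E_tru) & bright
    err_E <- c(err_E, abs(E_rec[ok] - E_tru[ok]))
  }
  expect_lt(sqrt(mean(err_I^2)), 0.05)   # relative RMS intensity error
  expect_lt(mean(err_E), 0.02)           # mean absolute FRET error

  # event labels survive the image path
  det_img <- detected_class(classify_field_events(rec))
  inj <- attr(co, "injected")$class[truth_idx]
  expect_identical(unname(det_img), unname(inj))
})

test_that("noise-free round-trip is exact up to PSF truncation", {
  tr <- const_traj(300, 500, n_frames = 3L)
  opt <- small_optics(background = 0)
  mv <- render_movie(list(tr), opt, positions = cbind(x = 32, y = 32),
                     noise = FALSE)
  pairs <- data.frame(molecule_id = "m1", x_d = 32, y_d = 32,
                      x_a = 32, y_a = 32, residual_px = 0)
  rec <- extract_trajectories(mv, pairs, aperture_radius_px = 5)
  expect_equal(rec$m1$I_D, tr$I_D, tolerance = 0.01)
  expect_equal(rec$m1$I_A, tr$I_A, tolerance = 0.01)

  # aperture on an empty region reads ~0 after background subtraction
  pairs_far <- transform(pairs, x_d = 10, y_d = 10, x_a = 10, y_a = 10)
  rec0 <- extract_trajectories(mv, pairs_far, aperture_radius_px = 5)
  expect_lt(max(abs(rec0$m1$I_D)), 1)

  expect_error(extract_trajectories(mv, transform(pairs, x_d = 2, y_d = 2),
                                    aperture_radius_px = 5), "beyond frame")
})

test_that("movies round-trip through 16-bit TIFF stacks", {
  tr <- const_traj(120, 200, n_frames = 4L)
  opt <- optics_model(frame_shape = c(32L, 32L), background = 5)
  set.seed(3)
  mv <- render_movie(list(tr), opt, noise = TRUE)
  prefix <- file.path(tempdir(), "run1")
  paths <- write_movie_tiff(mv, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_movie_tiff(paths[["donor"]])
  expect_identical(dim(back), dim(mv$donor))
  # values preserved up to 16-bit quantization after max-normalization
  expect_lt(max(abs(back * max(mv$donor) - mv$donor)),
            max(mv$donor) / 65535 + 1e-9)
  unlink(paths)
})
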