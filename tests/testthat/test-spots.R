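# Spot detection, localization, linking, MSD and arrival clustering.

test_that("background-only frames yield no detections at the default gate", {
  cam <- test_camera()
  st <- render_frames(blank_arrival_truth(100, seed = 21), cam, seed = 21)
  det <- detect_spots(st, snr_min = 5)
  expect_lte(nrow(det), 1)  # at most 1% of 100 blank frames may fire
  # empty stack is an empty result, not an error
  st0 <- image_stack(array(0, c(8, 8, 0, 1)), cam)
  expect_equal(nrow(detect_spots(st0)), 0)
  expect_error(detect_spots(st, psf_sigma_um = 0.01), "sampling")
})

test_that("a single emitter is localized within half a pixel at SNR ~ 10", {
  cam <- test_camera()
  errs <- c()
  for (s in 1:6) {
    x <- 4 + s * 0.13; y <- 6 - s * 0.11
    st <- stationary_emitter_stack(x, y, camera = cam, seed = s)
    det <- detect_spots(st)
    expect_equal(nrow(det), 1)
    errs <- c(errs, sqrt((det$x_um - x)^2 + (det$y_um - y)^2))
  }
  expect_true(all(errs < 0.08))           # 0.5 pixel
  expect_lt(sqrt(mean(errs^2)), 0.08)     # RMSE bound as well
})

test_that("well-separated emitters are detected individually", {
  cam <- test_camera()
  tr <- structure(list(tracks = data.frame(id = c(1L, 2L), frame = 0L,
                                           x_um = c(3, 3 + 6 * 0.16),
                                           y_um = c(5, 5)),
                       diffusion_um2_per_s = 0, frame_interval_s = 2,
                       geometry = NULL, seed = 1), class = "track_truth")
  st <- render_frames(tr, cam, seed = 3, fov_um = c(10.24, 10.24))
  det <- detect_spots(st)
  expect_equal(nrow(det), 2)
})

test_that("greedy linking keeps identities, bridges gaps and never reuses detections", {
  # a slowly diffusing emitter, detected every frame
  cam <- test_camera()
  tr <- simulate_brownian_tracks(0.05, NULL, 1, 40, 2, seed = 5)
  tr$tracks$x_um <- tr$tracks$x_um + 5; tr$tracks$y_um <- tr$tracks$y_um + 5
  st <- render_frames(tr, cam, seed = 5, fov_um = c(10.24, 10.24))
  det <- detect_spots(st)
  linked <- link_tracks(det, max_disp_um = 1.5, max_gap_frames = 1)
  main <- table(linked$track_id)
  expect_gte(max(main) / 40, 0.95)  # one track holds >= 95% of truth frames
  # two distant stationary emitters never merge
  det2 <- data.frame(frame = rep(0:9, 2), channel = "ch1",
                     x_um = rep(c(1, 11), each = 10),
                     y_um = rep(c(1, 11), each = 10),
                     intensity = 1, snr = 10)
  linked2 <- link_tracks(det2, max_disp_um = 2)
  expect_equal(length(unique(linked2$track_id)), 2)
  expect_equal(anyDuplicated(linked2[, c("frame", "x_um", "y_um", "track_id")]), 0)
  # a one-frame dropout is bridged when max_gap_frames = 2
  det3 <- data.frame(frame = c(0, 1, 3, 4), channel = "ch1",
                     x_um = c(1, 1.05, 1.1, 1.12), y_um = 1,
                     intensity = 1, snr = 10)
  expect_equal(length(unique(link_tracks(det3, 1, max_gap_frames = 2)$track_id)), 1)
  expect_equal(length(unique(link_tracks(det3, 1, max_gap_frames = 0)$track_id)), 2)
  expect_error(link_tracks(data.frame(frame = 0:1, channel = c("a", "b"),
                                      x_um = 0, y_um = 0), 1), "single channel")
})

test_that("MSD matches closed forms and the diffusion fit inverts them", {
  still <- data.frame(frame = 0:19, x_um = 2, y_um = 3)
  expect_true(all(compute_msd(still, 2)$msd_um2 == 0))
  expect_equal(fit_diffusion(compute_msd(still, 2))$flag, "degenerate")
  # ballistic track: msd = v^2 lag^2
  v <- 0.3
  ball <- data.frame(frame = 0:39, x_um = v * (0:39) * 2, y_um = 0)
  m <- compute_msd(ball, 2)
  expect_equal(m$msd_um2, v^2 * m$lag_s^2, tolerance = 1e-10)
  # exact linear msd = 4 D lag inverts to D
  fake <- structure(data.frame(lag_s = 1:10, msd_um2 = 4 * 1.7 * (1:10),
                               n_pairs = 100:91),
                    class = c("msd_curve", "data.frame"))
  expect_equal(fit_diffusion(fake)$D_um2_per_s, 1.7, tolerance = 1e-12)
  expect_error(compute_msd(data.frame(frame = 0:5, x_um = 0, y_um = 0), 2),
               "insufficient")
})

test_that("ensemble diffusion recovery from simulated tracks is within 10%", {
  tr <- simulate_brownian_tracks(1.7, NULL, 50, 100, 2, seed = 12)
  curves <- lapply(split(tr$tracks, tr$tracks$id), compute_msd,
                   frame_interval_s = 2)
  fit <- fit_diffusion(pool_msd(curves))
  expect_equal(fit$D_um2_per_s, 1.7, tolerance = 0.1)
  expect_equal(fit$flag, "ok")
})

test_that("arrival clustering merges blinking molecules and separates distinct ones", {
  # one immobilized blinking emitter: one event at its first frame
  det <- data.frame(frame = c(0, 1, 2, 6, 7, 12), channel = "ch1",
                    x_um = 3 + rnorm(6, sd = 0.02),
                    y_um = 3 + rnorm(6, sd = 0.02), intensity = 1, snr = 10)
  ev <- cluster_arrivals(det, 2, radius_um = 0.32, max_frame_gap = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$arrival_time_s, 0)
  # two emitters 5 um apart: two events
  det2 <- rbind(det, within(det, x_um <- x_um + 5))
  expect_equal(nrow(cluster_arrivals(det2, 2)), 2)
  # cluster count is monotone non-increasing in the radius
  set.seed(9)
  detr <- data.frame(frame = sample(0:20, 60, TRUE), channel = "ch1",
                     x_um = runif(60, 0, 4), y_um = runif(60, 0, 4),
                     intensity = 1, snr = 10)
  ns <- vapply(c(0.1, 0.32, 0.6, 1, 2), function(r)
    nrow(cluster_arrivals(detr, 2, radius_um = r, min_detections = 1)),
    numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("recovered arrival counts track the generated Poisson process", {
  cam <- test_camera()
  ntrue <- nrec <- 0
  for (s in 1:4) {
    truth <- simulate_arrivals(2, 15, seed = 100 + s)
    st <- render_frames(truth, cam, seed = 100 + s)
    ev <- cluster_arrivals(detect_spots(st), 2)
    ntrue <- ntrue + nrow(truth$events); nrec <- nrec + nrow(ev)
  }
  expect_lt(abs(nrec - ntrue) / ntrue, 0.1)
})

test_that("polygon mask filtering matches an independent point-in-polygon oracle", {
  poly <- data.frame(x_um = c(2, 8, 9, 5, 1), y_um = c(1, 2, 7, 9, 6))
  det_in <- data.frame(frame = 0, channel = "ch1", x_um = c(4, 5, 6),
                       y_um = c(4, 5, 5), intensity = 1, snr = 10)
  expect_equal(nrow(mask_filter(det_in, poly)), 3)   # all inside: identity
  det_out <- within(det_in, x_um <- x_um + 20)
  expect_equal(nrow(mask_filter(det_out, poly)), 0)  # all outside: empty
  skip_if_not_installed("pracma")
  set.seed(31)
  pts <- data.frame(frame = 0, channel = "ch1",
                    x_um = runif(1000, -1, 11), y_um = runif(1000, -1, 11),
                    intensity = 1, snr = 10)
  mine <- nrow(mask_filter(pts, poly))
  oracle <- sum(pracma::inpolygon(pts$x_um, pts$y_um, poly$x_um, poly$y_um,
                                  boundary = FALSE))
  expect_equal(mine, oracle)
  # self-intersecting outlines are rejected
  bowtie <- data.frame(x_um = c(0, 4, 0, 4), y_um = c(0, 4, 4, 0))
  expect_error(mask_filter(pts, bowtie), "self-intersecting")
})
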