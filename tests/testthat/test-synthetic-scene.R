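# Ground-truth-known scene generator.

test_that("Brownian tracks have the right MSD statistics and respect confinement", {
  # D = 0: no motion
  geom0 <- compartment_geometry(5, 40, 1.5)
  still <- simulate_brownian_tracks(0, geom0, 3, 20, 2, seed = 1)
  expect_equal(nrow(unique(still$tracks[, c("id", "x_um", "y_um")])), 3)
  # free diffusion: ensemble MSD slope at small lags equals 4D within 5%
  tr <- simulate_brownian_tracks(1.7, NULL, 200, 100, 1, seed = 2)
  d1 <- do.call(rbind, lapply(split(tr$tracks, tr$tracks$id), function(t)
    cbind(diff(t$x_um), diff(t$y_um))))
  slope <- mean(d1[, 1]^2 + d1[, 2]^2)  # MSD at lag 1 s
  expect_equal(slope, 4 * 1.7, tolerance = 0.05)
  # confinement: displacements never exceed the chamber diameter
  geom <- compartment_geometry(5, 40, 1.5)
  conf <- simulate_brownian_tracks(1.7, geom, 10, 200, 2, seed = 3)
  r2max <- max((conf$tracks$x_um - 5)^2 + (conf$tracks$y_um - 5)^2)
  expect_lte(r2max, 25 + 1e-9)
  expect_error(simulate_brownian_tracks(-1, NULL, 1, 10, 2), ">= 0")
})

test_that("arrival process is Poisson with exponential inter-arrival times", {
  expect_equal(nrow(simulate_arrivals(0, 60, seed = 1)$events), 0)
  # mean count: rate 0.67/min x 60 min over many seeds
  counts <- vapply(1:300, function(s)
    nrow(simulate_arrivals(0.67, 60, seed = s)$events), numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 40.2), 2 * se + 0.5)
  # inter-arrival distribution: KS test against Exp(rate) passes at alpha=.01
  # in at least 95% of seeds
  pass <- vapply(1:100, function(s) {
    ev <- simulate_arrivals(2, 60, seed = s)$events
    stats::ks.test(diff(ev$time_s), "pexp", 2 / 60)$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("decay traces follow (1-A)exp(-t/tau)+A exactly when noiseless", {
  sim <- simulate_decay_trace(413.4, 0.27, noise_sd = 0, frame_interval_s = 413.4,
                              duration_s = 413.4 * 10, seed = 1)
  expect_equal(sim$intensity[1, 1], 1)
  expect_equal(sim$intensity[2, 1], 0.27 + 0.73 / exp(1), tolerance = 1e-12)
  expect_equal(sim$intensity[11, 1], 0.27, tolerance = 1e-3)  # t >> tau -> A
  # A = 1: constant at 1 regardless of tau
  flat <- simulate_decay_trace(5, 1, noise_sd = 0, frame_interval_s = 1,
                               duration_s = 30, seed = 1)
  expect_true(all(flat$intensity == 1))
  expect_error(simulate_decay_trace(100, 1.2), "immobile_fraction")
  expect_error(simulate_decay_trace(-5, 0.5), "tau_s")
})

test_that("camera model renders background, centroids and photon linearity faithfully", {
  cam <- test_camera()
  # zero emitters: per-pixel mean ~ em_gain x background within 2 s.e.
  st <- render_frames(blank_arrival_truth(20), cam, seed = 4)
  mu <- mean(st$counts)
  sem <- sd(st$counts) / sqrt(length(st$counts))
  expect_lt(abs(mu - cam$em_gain * cam$background_photons), 2 * sem + 1)
  # one bright emitter: centroid of a 7x7 crop within 0.5 pixel of truth
  bright <- test_camera(photons_per_frame = 2000)
  st1 <- stationary_emitter_stack(5.0, 5.0, camera = bright, seed = 5)
  fr <- get_frame(st1, 0)
  cx <- 5.0 / 0.16 + 1; cy <- 5.0 / 0.16 + 1
  win_y <- (round(cy) - 3):(round(cy) + 3); win_x <- (round(cx) - 3):(round(cx) + 3)
  patch <- fr[win_y, win_x] - median(fr)
  xbar <- sum(colSums(patch) * win_x) / sum(patch)
  ybar <- sum(rowSums(patch) * win_y) / sum(patch)
  expect_lt(abs(xbar - cx), 0.5)
  expect_lt(abs(ybar - cy), 0.5)
  # doubling photons doubles background-subtracted integrated intensity (5%)
  integrated <- function(photons, seed) {
    cam2 <- camera_model(frame_interval_s = 2, photons_per_frame = photons)
    st <- stationary_emitter_stack(5, 5, n_frames = 40, camera = cam2, seed = seed)
    bg <- median(st$counts)
    mean(vapply(seq_len(40) - 1, function(f)
      sum(get_frame(st, f)[win_y, win_x] - bg), numeric(1)))
  }
  expect_equal(integrated(800, 6) / integrated(400, 7), 2, tolerance = 0.05)
  # emitters outside the field of view are a hard error
  expect_error(stationary_emitter_stack(50, 5, fov = c(10.24, 10.24)),
               "field of view")
})

test_that("nucleoid population realizes the prescribed truth by construction", {
  # colocalized_fraction = 1: every spot sits on a blob centre (the spot
  # count floor of 1 means all spots are the colocalized ones)
  pop <- simulate_nucleoid_population(3, 20, 0.1, c(4, 6), c(1, 1), 1,
                                      seed = 1, spot_loc_noise_um = 0)
  d <- sqrt(outer(pop$spots$x_um, pop$blobs$x_um, "-")^2 +
              outer(pop$spots$y_um, pop$blobs$y_um, "-")^2)
  expect_true(all(apply(d, 1, min) < 0.32))
  # fixed cluster count: median is the fixed value
  pop5 <- simulate_nucleoid_population(5, 20, 0, c(5, 5), c(5, 5), 1, seed = 2)
  expect_equal(unname(median(table(pop5$spots$chromosome))), 5)
  # area sampling: empirical mean of true areas within 2 s.e. of the target
  pop50 <- simulate_nucleoid_population(50, 20, 0.2, c(3, 7), c(2, 9), 0.9,
                                        seed = 3)
  a <- pop50$regions$true_area_um2
  expect_lt(abs(mean(a) - 20), 2 * sd(a) / sqrt(50))
  # non-colocalized spots keep their clearance from every blob
  pop0 <- simulate_nucleoid_population(3, 20, 0, c(4, 4), c(8, 8), 0, seed = 4)
  d0 <- sqrt(outer(pop0$spots$x_um, pop0$blobs$x_um, "-")^2 +
               outer(pop0$spots$y_um, pop0$blobs$y_um, "-")^2)
  expect_true(all(apply(d0, 1, min) >= 0.5 - 1e-9))
  # each chromosome mask is one connected object of the drawn area
  expect_true(all(pop50$regions$true_area_um2 > 1))
  expect_error(simulate_nucleoid_population(2, 20, 0, c(3, 7), c(2, 9), 1.5),
               "colocalized_fraction")
})

test_that("rendered-then-thresholded nucleoid mask area matches truth within 10%", {
  pop <- simulate_nucleoid_population(4, 20, 0.15, c(3, 7), c(2, 9), 0.9, seed = 9)
  px <- pop$pixel_size_um
  # at the stated rendering threshold (50% of plateau) on the noiseless field
  area_at_half <- sum(pop$field_dna >= 0.5) * px^2
  expect_equal(area_at_half, sum(pop$regions$true_area_um2), tolerance = 0.1)
})

test_that("stretch kymograph follows the mono-exponential envelope", {
  epochs <- data.frame(start_s = c(0, 5), end_s = c(5, 10),
                       state = c("on", "off"))
  ky <- simulate_stretch_kymograph(5, 1, 1, epochs, profile_noise = 0,
                                   seed = 1, frame_interval_s = 0.1)
  ext <- measure_extension(ky)
  # at t = tau_on the extent is extension_max * (1 - 1/e) within one pixel
  expect_lt(abs(ext$extension_um[ext$t_s == 1] - 5 * (1 - exp(-1))), 0.16)
  # far into the OFF epoch the extent returns below 10% of the maximum
  expect_lt(ext$extension_um[nrow(ext)], 0.5)
  # tau_on -> 0 is step-like
  ky0 <- simulate_stretch_kymograph(5, 1e-6, 1, epochs, profile_noise = 0,
                                    seed = 1, frame_interval_s = 0.1)
  expect_gt(measure_extension(ky0)$extension_um[2], 5 - 0.2)
  expect_error(simulate_stretch_kymograph(5, -1, 1, epochs), "positive")
  bad <- data.frame(start_s = c(0, 3), end_s = c(5, 8), state = c("on", "off"))
  expect_error(simulate_stretch_kymograph(5, 1, 1, bad), "overlap")
})

test_that("identical seed and configuration reproduce scenes bit for bit", {
  a <- simulate_arrivals(0.67, 10, seed = 42)
  b <- simulate_arrivals(0.67, 10, seed = 42)
  expect_identical(a, b)
  cam <- test_camera()
  sa <- render_frames(a, cam, seed = 42)
  sb <- render_frames(b, cam, seed = 42)
  expect_identical(sa$counts, sb$counts)
  pa <- simulate_nucleoid_population(3, 20, 0.2, c(3, 7), c(2, 9), 0.9, seed = 7)
  pb <- simulate_nucleoid_population(3, 20, 0.2, c(3, 7), c(2, 9), 0.9, seed = 7)
  expect_identical(pa, pb)
})
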