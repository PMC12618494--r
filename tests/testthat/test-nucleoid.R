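# Segmentation, area series, blob detection, colocalization, dose-response.

test_that("segmentation finds nothing on blank frames and separates clear blobs", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(segment_chromosomes(blank, 0.16)$regions), 0)
  expect_error(segment_chromosomes(matrix(0, 8, 8)), "pixel_size_um")
  # two disks with 5 um clearance are two regions
  px <- 0.16
  xs <- (0:79) * px
  img <- outer(xs, xs, function(y, x)
    1000 * ((x - 3)^2 + (y - 3)^2 < 1.5^2) + 1000 * ((x - 10)^2 + (y - 9)^2 < 1.5^2))
  seg <- segment_chromosomes(img, px, background_radius_um = 4)
  expect_equal(nrow(seg$regions), 2)
})

test_that("segmented area recovers rendered truth across the compaction range", {
  cam <- test_camera(frame_interval_s = 2.5)
  for (target in c(3, 4.8, 20)) {
    rels <- c()
    for (s in 1:3) {
      pop <- simulate_nucleoid_population(3, target, 0, c(3, 5), c(2, 4), 0.9,
                                          seed = 200 + s)
      st <- render_frames(pop, cam, seed = 200 + s)
      seg <- segment_chromosomes(get_frame(st, 0, "dna"), cam$pixel_size_um)
      expect_equal(nrow(seg$regions), 3)
      rels <- c(rels, sum(seg$regions$area_um2) / sum(pop$regions$true_area_um2))
    }
    expect_lt(abs(mean(rels) - 1), 0.1)
  }
})

test_that("segmented area is invariant under translation and 90-degree rotation", {
  cam <- test_camera(frame_interval_s = 2.5)
  pop <- simulate_nucleoid_population(1, 20, 0, c(4, 4), c(2, 2), 1, seed = 33)
  st <- render_frames(pop, cam, seed = 33)
  img <- get_frame(st, 0, "dna")
  base <- sum(segment_chromosomes(img, 0.16)$regions$area_um2)
  shifted <- img[c(11:nrow(img), 1:10), c(6:ncol(img), 1:5)]
  rot <- t(img)[ncol(img):1, ]
  tol <- nrow(img) * 0.16^2  # one pixel-row of boundary discretization
  expect_lt(abs(sum(segment_chromosomes(shifted, 0.16)$regions$area_um2) - base), tol)
  expect_lt(abs(sum(segment_chromosomes(rot, 0.16)$regions$area_um2) - base), tol)
})

test_that("overlap linking follows the literal one-pixel rule without gap bridging", {
  mk <- function(mask) {
    lab <- chromtrap:::label_components(mask)
    n <- max(lab)
    npx <- if (n > 0) as.vector(table(lab[lab > 0])) else integer(0)
    structure(list(regions = data.frame(label = seq_len(n),
                                        area_um2 = npx * 0.16^2,
                                        x_um = numeric(n), y_um = numeric(n),
                                        mean_intensity = rep(1, n),
                                        n_pixels = npx),
                   labels = lab, pixel_size_um = 0.16),
              class = "chromosome_regions")
  }
  disk <- matrix(FALSE, 30, 30); disk[10:20, 10:20] <- TRUE
  segs <- list(mk(disk), mk(disk), mk(disk))
  linked <- link_regions(segs)
  expect_equal(length(unique(linked$series_id)), 1)
  expect_equal(nrow(linked), 3)
  # a one-frame disappearance starts a new series (no gap bridging)
  none <- mk(matrix(FALSE, 30, 30))
  linked2 <- link_regions(list(mk(disk), none, mk(disk)))
  expect_equal(length(unique(linked2$series_id)), 2)
  # slowly drifting blobs keep one series per true chromosome
  cam <- test_camera(frame_interval_s = 2.5)
  pop <- simulate_nucleoid_population(4, 20, 0.1, c(3, 5), c(2, 4), 0.9, seed = 44)
  st <- render_frames(pop, cam, seed = 44)
  seg1 <- segment_chromosomes(get_frame(st, 0, "dna"), 0.16)
  st2 <- render_frames(pop, cam, seed = 45)   # same truth, fresh noise
  seg2 <- segment_chromosomes(get_frame(st2, 0, "dna"), 0.16)
  linked3 <- link_regions(list(seg1, seg2))
  expect_equal(length(unique(linked3$series_id)), 4)
})

test_that("summed-area series is normalized, tracks truth and smooths gently", {
  lk <- data.frame(frame = rep(0:49, each = 2),
                   area_um2 = rep(10, 100))
  s1 <- summed_area_series(lk, 2.5, 10)
  expect_true(all(abs(s1$area_norm - 1) < 1e-12))
  expect_true(all(abs(s1$area_norm_smooth - 1) < 1e-12))
  # linear doubling: smoothed endpoint ~ 2 within 2% and mean preserved to 1%
  lk2 <- data.frame(frame = 0:99, area_um2 = seq(10, 20, length.out = 100))
  s2 <- summed_area_series(lk2, 1, 3)
  expect_equal(s2$area_norm_smooth[100], 2, tolerance = 0.02)
  expect_equal(mean(s2$area_norm_smooth), mean(s2$area_norm), tolerance = 0.01)
  expect_error(summed_area_series(lk2[1, , drop = FALSE], 1, 3), "2 frames")
  lk3 <- data.frame(frame = c(0, 0, 1), area_um2 = c(0, 0, 5))
  expect_error(summed_area_series(lk3, 1, 1), "initial")
})

test_that("blob detection finds decorated sub-blobs and respects its gates", {
  cam <- test_camera(frame_interval_s = 2.5)
  pop <- simulate_nucleoid_population(1, 20, 0, c(5, 5), c(5, 5), 1, seed = 55,
                                      spot_loc_noise_um = 0)
  st <- render_frames(pop, cam, seed = 55)
  img <- get_frame(st, 0, "dna")
  seg <- segment_chromosomes(img, 0.16)
  blobs <- detect_blobs(img, seg)
  expect_equal(nrow(blobs), 5)
  d <- sqrt(outer(blobs$x_um, pop$blobs$x_um, "-")^2 +
              outer(blobs$y_um, pop$blobs$y_um, "-")^2)
  expect_true(all(apply(d, 1, min) < 0.2))
  # uniform-intensity region: no blobs at any positive prominence
  flat <- matrix(0, 64, 64); flat[20:40, 20:40] <- 500
  segf <- segment_chromosomes(flat, 0.16, background_radius_um = 4)
  expect_equal(nrow(detect_blobs(flat, segf, prominence = 1e-6)), 0)
  # blob count is monotone non-increasing in the prominence gate
  ns <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.95), function(p)
    nrow(detect_blobs(img, seg, prominence = p)), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("colocalization applies the strict sub-0.32-um one-to-one rule", {
  pts <- data.frame(x_um = c(0, 10, 20), y_um = c(1, 1, 1))
  expect_equal(colocalize(pts, pts)$fraction_colocalized, 1)
  shifted <- within(pts, x_um <- x_um + 0.33)
  expect_equal(colocalize(pts, shifted)$fraction_colocalized, 0)
  at_threshold <- within(pts, x_um <- x_um + 0.32)
  expect_equal(colocalize(pts, at_threshold)$fraction_colocalized, 0)
  just_in <- within(pts, x_um <- x_um + 0.3199)
  expect_equal(colocalize(pts, just_in)$fraction_colocalized, 1)
  # each blob matches at most one spot and vice versa
  two_spots <- data.frame(x_um = c(0.05, 0.1), y_um = c(1, 1))
  cc <- colocalize(pts[1, , drop = FALSE], two_spots)
  expect_equal(cc$n_matched, 1)
  # fraction is monotone non-decreasing in the match radius
  set.seed(66)
  b <- data.frame(x_um = runif(30, 0, 10), y_um = runif(30, 0, 10))
  s <- data.frame(x_um = runif(30, 0, 10), y_um = runif(30, 0, 10))
  fr <- vapply(c(0.1, 0.32, 0.6, 1, 2, 4), function(r)
    colocalize(b, s, r)$fraction_colocalized, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("cluster counting per region reports the ensemble median", {
  cam <- test_camera(frame_interval_s = 2.5)
  pop <- simulate_nucleoid_population(5, 20, 0, c(5, 5), c(5, 5), 1, seed = 77)
  st <- render_frames(pop, cam, seed = 77)
  seg <- segment_chromosomes(get_frame(st, 0, "dna"), 0.16)
  spots <- detect_spots(st, channel = "spots")
  cc <- count_clusters(spots, seg)
  expect_equal(cc$median, 5)
  expect_equal(count_clusters(spots[0, ], seg)$counts$n_spots,
               rep(0L, nrow(seg$regions)))
  # variable counts: recovered median within 1 of the true sample median
  popv <- simulate_nucleoid_population(12, 20, 0.1, c(2, 4), c(2, 9), 1, seed = 78)
  stv <- render_frames(popv, cam, seed = 78)
  segv <- segment_chromosomes(get_frame(stv, 0, "dna"), 0.16)
  spv <- detect_spots(stv, channel = "spots")
  true_med <- median(table(factor(popv$spots$chromosome, levels = 1:12)))
  expect_lte(abs(count_clusters(spv, segv)$median - true_med), 1)
})

test_that("dose-response aggregation reports means with 15.9/84.1% quantile bands", {
  one <- dose_response(5, 2)
  expect_equal(one$mean_area_um2, 5)
  expect_equal(one$q_low, 5); expect_equal(one$q_high, 5)
  # normal sample: quantile band approximates mean +/- 1 sd
  set.seed(88)
  a <- rnorm(300, 20, 4)
  dr <- dose_response(a, rep(1, 300))
  expect_equal(dr$q_high - dr$q_low, 2 * 4, tolerance = 0.1)
  # a sigmoidal area-vs-PEG truth keeps its midpoint in the recovered means
  peg <- rep(seq(0, 10, by = 0.5), each = 40)
  mid_true <- 5.3
  areas <- 3 + 17 / (1 + exp((peg - mid_true) / 0.6)) + rnorm(length(peg), sd = 1)
  drs <- dose_response(areas, peg)
  half <- (max(drs$mean_area_um2) + min(drs$mean_area_um2)) / 2
  i <- max(which(drs$mean_area_um2 > half))
  mid_est <- drs$peg_percent[i] +
    (drs$mean_area_um2[i] - half) /
    (drs$mean_area_um2[i] - drs$mean_area_um2[i + 1]) *
    (drs$peg_percent[i + 1] - drs$peg_percent[i])
  expect_lt(abs(mid_est - mid_true), 0.5)
  expect_error(dose_response(numeric(0), numeric(0)), NA)
  expect_error(dose_response(c(1, 2), c(1)), "lengths differ")
})

test_that("Mann-Whitney comparison matches the brute-force enumeration oracle", {
  a <- c(1.2, 3.4, 5.1, 8.0); b <- c(2.2, 2.9, 4.4, 6.1)
  res <- compare_groups(a, b)
  oracle <- mw_enumerate(a, b)
  expect_equal(length(oracle$U_all), 70)
  expect_equal(res$U, oracle$U)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  # a second 4-vs-4 set with a clearer shift
  a2 <- c(10, 11, 12, 13); b2 <- c(1, 2, 3, 14)
  res2 <- compare_groups(a2, b2)
  oracle2 <- mw_enumerate(a2, b2)
  expect_equal(res2$U, oracle2$U)
  expect_equal(res2$p_value, oracle2$p, tolerance = 1e-12)
  # identical groups: p ~ 1, flagged
  same <- compare_groups(rep(2, 5), rep(2, 6))
  expect_equal(same$p_value, 1)
  expect_equal(same$flag, "degenerate_identical")
  # power: a 2-sd shift at n = 50 is essentially always significant
  set.seed(99)
  sig <- vapply(1:20, function(s) {
    x <- rnorm(50); y <- rnorm(50, 2)
    compare_groups(x, y)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})
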