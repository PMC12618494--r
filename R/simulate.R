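# Ground-truth-known scene generator: Brownian tracks, Poisson surface
# arrivals with photobleaching, dissociation decay traces, EM-CCD image
# formation, multi-blob nucleoid scenes, and stretch kymographs. Every
# generated object carries the parameters that produced it so downstream
# recovery is assertable without re-deriving truth.

#' Simulate Brownian emitter tracks
#'
#' Per-frame Gaussian displacements with variance `2 D dt` per axis. Inside a
#' compartment the chamber wall is reflecting; escape through the capillary is
#' accounted for analytically by [compartment_lifetime()], never
#' particle-by-particle, because no downstream analysis needs per-particle
#' escape. With `geometry = NULL` motion is free (used for MSD calibration).
#'
#' @param diffusion_um2_per_s Diffusion coefficient D (um^2/s), `>= 0`.
#' @param geometry A [compartment_geometry()] for confined motion, or `NULL`.
#' @param n_particles,n_frames Number of tracks and frames (`n_frames >= 2`).
#' @param frame_interval_s Frame interval in seconds.
#' @param seed Integer seed.
#' @return A `track_truth` object whose `$tracks` data.frame has columns
#'   `id`, `frame` (0-based), `x_um`, `y_um`.
#' @export
simulate_brownian_tracks <- function(diffusion_um2_per_s, geometry = NULL,
                                     n_particles = 1, n_frames = 100,
                                     frame_interval_s = 2, seed = 1) {
  if (diffusion_um2_per_s < 0)
    stop("simulate_brownian_tracks: 'diffusion_um2_per_s' must be >= 0", call. = FALSE)
  if (n_frames < 2)
    stop("simulate_brownian_tracks: 'n_frames' must be >= 2", call. = FALSE)
  set.seed(derive_seed(seed, "brownian"))
  sd_step <- sqrt(2 * diffusion_um2_per_s * frame_interval_s)
  R <- if (!is.null(geometry)) geometry$radius_um else Inf
  out <- vector("list", n_particles)
  for (p in seq_len(n_particles)) {
    if (is.finite(R)) {
      repeat {  # uniform start in the chamber disk (centre at (R, R))
        x0 <- stats::runif(2, -R, R)
        if (sum(x0^2) < R^2) break
      }
      x0 <- x0 + R
    } else x0 <- c(0, 0)
    xy <- matrix(0, n_frames, 2)
    xy[1, ] <- x0
    steps <- matrix(stats::rnorm(2 * (n_frames - 1), sd = sd_step), ncol = 2)
    for (i in 2:n_frames) {
      pos <- xy[i - 1, ] + steps[i - 1, ]
      if (is.finite(R)) pos <- reflect_in_disk(pos, R)
      xy[i, ] <- pos
    }
    out[[p]] <- data.frame(id = p, frame = 0:(n_frames - 1),
                           x_um = xy[, 1], y_um = xy[, 2])
  }
  structure(list(tracks = do.call(rbind, out),
                 diffusion_um2_per_s = diffusion_um2_per_s,
                 frame_interval_s = frame_interval_s,
                 geometry = geometry, seed = seed),
            class = "track_truth")
}

# Reflect a point into the disk of radius R centred at (R, R).
reflect_in_disk <- function(pos, R) {
  ctr <- c(R, R)
  for (k in 1:8) {
    d <- sqrt(sum((pos - ctr)^2))
    if (d <= R) break
    pos <- ctr + (pos - ctr) * (2 * R - d) / d
  }
  if (sqrt(sum((pos - ctr)^2)) > R)  # pathological large step: project
    pos <- ctr + (pos - ctr) * (R / sqrt(sum((pos - ctr)^2))) * 0.999
  pos
}

#' Simulate surface-capture arrival events
#'
#' Homogeneous Poisson arrivals of nascent proteins captured on the
#' compartment surface: event times uniform on the observation window at the
#' given rate, positions uniform over the capture area, each molecule visible
#' from its arrival until an exponential photobleaching time, optionally with
#' frame-wise blinking.
#'
#' @param rate_per_min Expected arrivals per minute, `>= 0`.
#' @param duration_min Observation window in minutes.
#' @param bleach_tau_s Mean exponential bleaching time in seconds. The
#'   default of 120 s reflects the few-minute photobleaching scale of
#'   far-red dyes under the imaging powers used here.
#' @param capture_area `c(width_um, height_um)` of the capture region.
#' @param seed Integer seed.
#' @param blink_prob Per-frame probability that a visible molecule is dark.
#' @return An `arrival_truth` object whose `$events` data.frame has columns
#'   `id`, `time_s`, `x_um`, `y_um`, `bleach_s`.
#' @export
simulate_arrivals <- function(rate_per_min, duration_min, bleach_tau_s = 120,
                              capture_area = c(10.24, 10.24), seed = 1,
                              blink_prob = 0.1) {
  if (rate_per_min < 0)
    stop("simulate_arrivals: 'rate_per_min' must be >= 0", call. = FALSE)
  if (duration_min <= 0)
    stop("simulate_arrivals: 'duration_min' must be positive", call. = FALSE)
  set.seed(derive_seed(seed, "arrivals"))
  n <- stats::rpois(1, rate_per_min * duration_min)
  events <- if (n > 0) {
    data.frame(id = seq_len(n),
               time_s = sort(stats::runif(n, 0, duration_min * 60)),
               x_um = stats::runif(n, 0, capture_area[1]),
               y_um = stats::runif(n, 0, capture_area[2]),
               bleach_s = stats::rexp(n, rate = 1 / bleach_tau_s))
  } else {
    data.frame(id = integer(), time_s = numeric(), x_um = numeric(),
               y_um = numeric(), bleach_s = numeric())
  }
  events$id <- seq_len(nrow(events))
  structure(list(events = events, rate_per_min = rate_per_min,
                 duration_min = duration_min, bleach_tau_s = bleach_tau_s,
                 capture_area = capture_area, blink_prob = blink_prob,
                 seed = seed),
            class = "arrival_truth")
}

#' Simulate normalized dissociation decay traces
#'
#' Forward model of ensemble bound-protein intensity after introducing the
#' cell-free system: `I(t) = (1 - A) exp(-t / tau) + A` plus i.i.d. Gaussian
#' noise, where `A` is the tightly bound (immobile) fraction. The noiseless
#' initial value is 1 by construction.
#'
#' @param tau_s Decay constant in seconds, `> 0`.
#' @param immobile_fraction Immobile fraction A in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param frame_interval_s Sampling interval in seconds.
#' @param duration_s Trace duration in seconds.
#' @param seed Integer seed.
#' @param n_traces Number of replicate traces (columns).
#' @return A `decay_trace_sim` with `$t_s` and an `[time, replicate]`
#'   `$intensity` matrix plus the generating parameters.
#' @export
simulate_decay_trace <- function(tau_s, immobile_fraction = 0, noise_sd = 0.02,
                                 frame_interval_s = 5, duration_s = 1500,
                                 seed = 1, n_traces = 1) {
  if (tau_s <= 0) stop("simulate_decay_trace: 'tau_s' must be positive", call. = FALSE)
  if (immobile_fraction < 0 || immobile_fraction > 1)
    stop("simulate_decay_trace: 'immobile_fraction' must lie in [0, 1]", call. = FALSE)
  set.seed(derive_seed(seed, "decay"))
  t_s <- seq(0, duration_s, by = frame_interval_s)
  clean <- (1 - immobile_fraction) * exp(-t_s / tau_s) + immobile_fraction
  intensity <- matrix(clean, length(t_s), n_traces) +
    matrix(stats::rnorm(length(t_s) * n_traces, sd = noise_sd),
           length(t_s), n_traces)
  structure(list(t_s = t_s, intensity = intensity, tau_s = tau_s,
                 immobile_fraction = immobile_fraction, noise_sd = noise_sd,
                 seed = seed),
            class = "decay_trace_sim")
}

#' Render ground-truth scenes into EM-CCD image stacks
#'
#' Image formation: each emitter is an integrated 2-D Gaussian PSF; Poisson
#' shot noise acts on signal plus background photons; electron multiplication
#' is a gamma-distributed multiplicative stage (shape = photon count, scale =
#' gain); additive Gaussian read noise follows; counts are clamped at zero.
#'
#' @param truth A `track_truth`, `arrival_truth` or `nucleoid_population`.
#' @param camera A [camera_model()].
#' @param seed Integer seed for the noise stages.
#' @param fov_um Field of view `c(width_um, height_um)`; defaults to the
#'   truth's own extent. Must cover all emitters.
#' @return An [image_stack()].
#' @export
render_frames <- function(truth, camera, seed = 1, fov_um = NULL) {
  UseMethod("render_frames")
}

#' @export
render_frames.track_truth <- function(truth, camera, seed = 1, fov_um = NULL) {
  px <- camera$pixel_size_um
  if (is.null(fov_um)) {
    if (!is.null(truth$geometry)) {
      fov_um <- rep(2 * truth$geometry$radius_um + 2, 2)
    } else {
      fov_um <- rep(2 * max(abs(c(truth$tracks$x_um, truth$tracks$y_um))) + 2, 2)
    }
  }
  tr <- truth$tracks
  off <- if (is.null(truth$geometry) && any(tr$x_um < 0 | tr$y_um < 0))
    fov_um / 2 else c(0, 0)
  check_fov(tr$x_um + off[1], tr$y_um + off[2], fov_um)
  frames <- sort(unique(tr$frame))
  pos <- lapply(frames, function(f)
    cbind(tr$x_um[tr$frame == f] + off[1], tr$y_um[tr$frame == f] + off[2]))
  stack <- render_emitters(pos, camera, fov_um, seed)
  stack$origin_offset_um <- off
  stack
}

#' @export
render_frames.arrival_truth <- function(truth, camera, seed = 1, fov_um = NULL) {
  if (is.null(fov_um)) fov_um <- truth$capture_area
  ev <- truth$events
  check_fov(ev$x_um, ev$y_um, fov_um)
  nf <- as.integer(floor(truth$duration_min * 60 / camera$frame_interval_s))
  set.seed(derive_seed(seed, "blink"))
  pos <- vector("list", nf)
  t_frame <- (seq_len(nf) - 1) * camera$frame_interval_s
  for (i in seq_len(nf)) {
    vis <- ev$time_s <= t_frame[i] & t_frame[i] < ev$time_s + ev$bleach_s
    if (any(vis) && truth$blink_prob > 0)
      vis[vis] <- stats::runif(sum(vis)) >= truth$blink_prob
    pos[[i]] <- cbind(ev$x_um[vis], ev$y_um[vis])
  }
  render_emitters(pos, camera, fov_um, seed)
}

#' @export
#' @rdname render_frames
#' @param dna_peak_photons Plateau photon level of the DNA channel (nucleoid
#'   scenes only). The default of 200 photons over ~20 background photons
#'   gives a per-pixel SNR near 10 after the EM excess noise.
render_frames.nucleoid_population <- function(truth, camera, seed = 1,
                                              fov_um = NULL,
                                              dna_peak_photons = 200) {
  if (is.null(fov_um)) fov_um <- truth$fov_um
  if (any(fov_um < truth$fov_um - 1e-9))
    stop("render_frames: field of view smaller than the simulated scene", call. = FALSE)
  px <- camera$pixel_size_um
  ny <- as.integer(round(fov_um[2] / px)); nx <- as.integer(round(fov_um[1] / px))
  # DNA channel: plateau scaled to its own photon level; condensin spots are
  # point emitters on the camera's single-molecule photon budget
  field <- matrix(0, ny, nx)
  fd <- truth$field_dna
  field[seq_len(nrow(fd)), seq_len(ncol(fd))] <- fd * dna_peak_photons
  set.seed(derive_seed(seed, "render-nucleoid"))
  dna <- camera_noise(field + camera$background_photons, camera)
  spots <- render_emitters(list(cbind(truth$spots$x_um, truth$spots$y_um)),
                           camera, fov_um, seed + 1)
  counts <- array(0, c(ny, nx, 1, 2))
  counts[, , 1, 1] <- dna
  counts[, , 1, 2] <- spots$counts[, , 1, 1]
  image_stack(counts, camera, channel_names = c("dna", "spots"))
}

check_fov <- function(x, y, fov_um) {
  if (length(x) && (min(x) < 0 || min(y) < 0 ||
                    max(x) > fov_um[1] || max(y) > fov_um[2]))
    stop("render_frames: emitters fall outside the field of view", call. = FALSE)
  invisible(TRUE)
}

# Shared emitter renderer: pos is a list (one entry per frame) of [n, 2]
# matrices of (x_um, y_um).
render_emitters <- function(pos, camera, fov_um, seed) {
  px <- camera$pixel_size_um
  nx <- as.integer(round(fov_um[1] / px))
  ny <- as.integer(round(fov_um[2] / px))
  nf <- length(pos)
  sig_px <- camera$psf_sigma_um / px
  r <- as.integer(ceiling(4 * sig_px))
  photons <- array(camera$background_photons, c(ny, nx, nf))
  for (i in seq_len(nf)) {
    p <- pos[[i]]
    if (is.null(p) || nrow(p) == 0) next
    for (e in seq_len(nrow(p))) {
      cx <- p[e, 1] / px + 1  # 1-based fractional pixel centre
      cy <- p[e, 2] / px + 1
      xs <- max(1L, as.integer(floor(cx)) - r):min(nx, as.integer(floor(cx)) + r)
      ys <- max(1L, as.integer(floor(cy)) - r):min(ny, as.integer(floor(cy)) + r)
      fx <- stats::pnorm(xs + 0.5, cx, sig_px) - stats::pnorm(xs - 0.5, cx, sig_px)
      fy <- stats::pnorm(ys + 0.5, cy, sig_px) - stats::pnorm(ys - 0.5, cy, sig_px)
      photons[ys, xs, i] <- photons[ys, xs, i] +
        camera$photons_per_frame * (fy %o% fx)
    }
  }
  set.seed(derive_seed(seed, "camera-noise"))
  counts <- camera_noise(photons, camera)
  image_stack(array(counts, c(ny, nx, nf, 1)), camera)
}

# Poisson shot noise -> gamma EM stage -> Gaussian read noise, clamped at 0.
camera_noise <- function(photons, camera) {
  d <- dim(photons)
  n <- stats::rpois(length(photons), photons)
  out <- numeric(length(n))
  posi <- n > 0
  if (any(posi))
    out[posi] <- stats::rgamma(sum(posi), shape = n[posi], scale = camera$em_gain)
  out <- out + stats::rnorm(length(out), sd = camera$read_noise_counts)
  out <- round(pmax(out, 0))  # integer ADU, keeps TIFF round trips lossless
  dim(out) <- d
  out
}

#' Simulate a population of multi-blob nucleoid scenes
#'
#' Each chromosome is rendered as a union of soft-edged, flat-top sub-blobs
#' (disks with a ~1-pixel Gaussian edge). The ground-truth area is the
#' rasterized pixel count of the union at the 50%-plateau rendering
#' threshold, matched to the drawn target area by bisection on a global size
#' scale, so segmentation accuracy can be asserted against an exactly known
#' area. Condensin-like spots are placed on sub-blob centres (colocalized,
#' with Gaussian localization jitter) or at 0.5-1 um clearance from every
#' blob (non-colocalized); the colocalized count is allocated across the whole
#' population so the realized blob-colocalized fraction matches the target.
#'
#' @param n_chromosomes Number of chromosomes in the field.
#' @param area_um2_mean,area_um2_cv Mean and coefficient of variation of the
#'   true mask areas (um^2); defaults are the open, low-crowding state.
#' @param n_subblobs_range Inclusive integer range of sub-blobs (DNA blobs)
#'   per chromosome.
#' @param mukb_spot_count_range Inclusive integer range of condensin spots
#'   per chromosome.
#' @param colocalized_fraction Target fraction of DNA blobs carrying a spot.
#' @param seed Integer seed.
#' @param pixel_size_um Rendering grid pitch (um).
#' @param spot_loc_noise_um Localization jitter of colocalized spots (um).
#' @return A `nucleoid_population` with `$regions`, `$blobs`, `$spots` truth
#'   tables, the noiseless DNA field `$field_dna` (plateau = 1), and `$fov_um`.
#' @export
simulate_nucleoid_population <- function(n_chromosomes,
                                         area_um2_mean = 20,
                                         area_um2_cv = 0.2,
                                         n_subblobs_range = c(3, 7),
                                         mukb_spot_count_range = c(2, 9),
                                         colocalized_fraction = 0.9,
                                         seed = 1,
                                         pixel_size_um = 0.16,
                                         spot_loc_noise_um = 0.05) {
  if (colocalized_fraction < 0 || colocalized_fraction > 1)
    stop("simulate_nucleoid_population: 'colocalized_fraction' must lie in [0, 1]",
         call. = FALSE)
  if (length(n_subblobs_range) != 2 || n_subblobs_range[1] > n_subblobs_range[2])
    stop("simulate_nucleoid_population: 'n_subblobs_range' must be a valid range",
         call. = FALSE)
  set.seed(derive_seed(seed, "nucleoid"))
  px <- pixel_size_um
  # lay chromosomes on a grid with clearance proportional to their size
  cell_um <- max(4, 2.6 * sqrt(area_um2_mean * (1 + 2 * area_um2_cv)))
  ncol_g <- ceiling(sqrt(n_chromosomes))
  nrow_g <- ceiling(n_chromosomes / ncol_g)
  fov_um <- c(ncol_g, nrow_g) * cell_um
  if (n_chromosomes * area_um2_mean > 0.5 * prod(fov_um))
    stop("simulate_nucleoid_population: requested areas cannot be packed", call. = FALSE)
  ny <- as.integer(round(fov_um[2] / px)); nx <- as.integer(round(fov_um[1] / px))
  mask_all <- matrix(FALSE, ny, nx)
  labels <- matrix(0L, ny, nx)
  field <- matrix(0, ny, nx)
  regions <- blobs <- list()
  for (k in seq_len(n_chromosomes)) {
    gi <- (k - 1) %% ncol_g; gj <- (k - 1) %/% ncol_g
    centre <- c((gi + 0.5), (gj + 0.5)) * cell_um
    target <- max(1, stats::rnorm(1, area_um2_mean, area_um2_cv * area_um2_mean))
    nb <- sample_range(n_subblobs_range)
    ctrs <- place_subblob_centres(nb, centre, spread_um = 0.55 * sqrt(target),
                                  min_sep_um = 1.3)
    rel <- stats::runif(nb, 0.75, 1.25)
    # a chromosome is one connected object: pull sub-blobs together until the
    # rasterized union is a single component (the area is re-matched each time)
    for (shrink in 1:25) {
      sc <- match_field_area(ctrs, rel, target, px)
      if (union_is_connected(ctrs, sc * rel, px)) break
      mid <- colMeans(ctrs)
      ctrs <- sweep(sweep(ctrs, 2, mid) * 0.88, 2, mid, "+")
    }
    # final decorated noiseless field on the global grid; the true area is
    # its super-threshold pixel count at the 0.5-plateau rendering threshold
    loc <- chromosome_field(ctrs, sc * rel, px, ny, nx)
    sub <- field[loc$ys, loc$xs]
    field[loc$ys, loc$xs] <- pmax(sub, loc$field)
    inmask <- loc$field >= 0.5
    mask_all[loc$ys, loc$xs] <- mask_all[loc$ys, loc$xs] | inmask
    lab_sub <- labels[loc$ys, loc$xs]
    lab_sub[inmask] <- k
    labels[loc$ys, loc$xs] <- lab_sub
    area_true <- sum(inmask) * px^2
    regions[[k]] <- data.frame(id = k, x_um = centre[1], y_um = centre[2],
                               true_area_um2 = area_true, n_subblobs = nb)
    blobs[[k]] <- data.frame(chromosome = k, blob = seq_len(nb),
                             x_um = ctrs[, 1], y_um = ctrs[, 2])
  }
  regions <- do.call(rbind, regions)
  blobs <- do.call(rbind, blobs)
  # population-level allocation of colocalized blobs
  nb_tot <- nrow(blobs)
  n_coloc <- round(colocalized_fraction * nb_tot)
  coloc_idx <- sample(nb_tot, n_coloc)
  blobs$has_spot <- FALSE; blobs$has_spot[coloc_idx] <- TRUE
  spots <- list()
  for (k in seq_len(n_chromosomes)) {
    bk <- blobs[blobs$chromosome == k, ]
    n_col_k <- sum(bk$has_spot)
    n_spots <- sample_range(mukb_spot_count_range)
    n_spots <- max(n_spots, n_col_k)
    sp <- list()
    if (n_col_k > 0) {
      on <- bk[bk$has_spot, ]
      sp[[1]] <- data.frame(
        chromosome = k,
        x_um = on$x_um + stats::rnorm(n_col_k, sd = spot_loc_noise_um),
        y_um = on$y_um + stats::rnorm(n_col_k, sd = spot_loc_noise_um),
        colocalized = TRUE)
    }
    n_far <- n_spots - n_col_k
    if (n_far > 0) {
      far <- place_far_spots(n_far, bk[, c("x_um", "y_um")],
                             clear_min = 0.5, clear_max = 1.0)
      sp[[length(sp) + 1]] <- data.frame(chromosome = k, x_um = far[, 1],
                                         y_um = far[, 2], colocalized = FALSE)
    }
    spots[[k]] <- do.call(rbind, sp)
  }
  spots <- do.call(rbind, spots)
  structure(list(regions = regions, blobs = blobs, spots = spots,
                 mask = mask_all, labels = labels, field_dna = field,
                 fov_um = fov_um, pixel_size_um = px,
                 colocalized_fraction = colocalized_fraction,
                 realized_colocalized_fraction = n_coloc / nb_tot,
                 spot_loc_noise_um = spot_loc_noise_um, seed = seed),
            class = "nucleoid_population")
}

# guard against sample()'s scalar expansion when the range is degenerate
sample_range <- function(rng) {
  if (rng[1] == rng[2]) return(as.integer(rng[1]))
  sample(rng[1]:rng[2], 1)
}

place_subblob_centres <- function(nb, centre, spread_um, min_sep_um) {
  ctrs <- matrix(NA_real_, nb, 2)
  for (b in seq_len(nb)) {
    for (try in 1:400) {
      cand <- centre + stats::runif(2, -spread_um, spread_um)
      if (b == 1) break
      dmin <- min(sqrt(rowSums((ctrs[seq_len(b - 1), , drop = FALSE] -
                                  matrix(cand, b - 1, 2, byrow = TRUE))^2)))
      if (dmin >= min_sep_um) break
    }
    ctrs[b, ] <- cand
  }
  ctrs
}

place_far_spots <- function(n, blob_xy, clear_min, clear_max) {
  out <- matrix(NA_real_, n, 2)
  bx <- as.matrix(blob_xy)
  for (i in seq_len(n)) {
    for (try in 1:400) {
      anchor <- bx[sample(nrow(bx), 1), ]
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, clear_min, clear_max)
      cand <- anchor + rad * c(cos(ang), sin(ang))
      d <- sqrt(rowSums((bx - matrix(cand, nrow(bx), 2, byrow = TRUE))^2))
      if (min(d) >= clear_min) break
    }
    out[i, ] <- cand
  }
  out
}

# Noiseless decorated chromosome field on a window of the global pixel grid:
# union-of-disks mask, soft edge (1 px Gaussian), multiplicative Gaussian
# bumps (amplitude 0.8, sigma 0.30 um) at the sub-blob centres. The 0.5 level
# of this field is the rendering threshold that defines the true area.
chromosome_field <- function(ctrs, radii, px, ny, nx, margin_px = 8L) {
  bump_sig_px <- 0.30 / px
  xmin <- max(1L, as.integer(floor(min(ctrs[, 1] - radii) / px)) - margin_px)
  xmax <- min(nx, as.integer(ceiling(max(ctrs[, 1] + radii) / px)) + margin_px)
  ymin <- max(1L, as.integer(floor(min(ctrs[, 2] - radii) / px)) - margin_px)
  ymax <- min(ny, as.integer(ceiling(max(ctrs[, 2] + radii) / px)) + margin_px)
  xs_um <- (xmin:xmax - 1) * px; ys_um <- (ymin:ymax - 1) * px
  inside <- matrix(FALSE, length(ys_um), length(xs_um))
  bumps <- matrix(0, length(ys_um), length(xs_um))
  for (b in seq_len(nrow(ctrs))) {
    d2 <- outer((ys_um - ctrs[b, 2])^2, (xs_um - ctrs[b, 1])^2, "+")
    inside <- inside | (d2 <= radii[b]^2)
    bumps <- bumps + exp(-d2 / (2 * (bump_sig_px * px)^2))
  }
  f <- gauss_blur(inside * 1, 1) * (1 + 0.8 * bumps)
  list(field = f, ys = ymin:ymax, xs = xmin:xmax)
}

# Bisection on the global radius scale so the decorated field's area at the
# 0.5 rendering threshold hits the drawn target.
match_field_area <- function(ctrs, rel, target_um2, px) {
  big <- 4096L  # window clamping is irrelevant during bisection
  area_at <- function(s) {
    f <- chromosome_field(ctrs, s * rel, px, big, big)
    sum(f$field >= 0.5) * px^2
  }
  lo <- 0.05; hi <- sqrt(target_um2)
  while (area_at(hi) < target_um2) hi <- hi * 1.5
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    if (area_at(mid) < target_um2) lo <- mid else hi <- mid
  }
  hi
}

union_is_connected <- function(ctrs, radii, px) {
  xs <- seq(min(ctrs[, 1]) - max(radii), max(ctrs[, 1]) + max(radii), by = px)
  ys <- seq(min(ctrs[, 2]) - max(radii), max(ctrs[, 2]) + max(radii), by = px)
  inside <- matrix(FALSE, length(ys), length(xs))
  for (b in seq_len(nrow(ctrs)))
    inside <- inside | (outer((ys - ctrs[b, 2])^2, (xs - ctrs[b, 1])^2, "+")
                        <= radii[b]^2)
  max(label_components(inside)) <= 1
}

#' Simulate a stretch/relax kymograph
#'
#' Space-time image of the 1-D fluorescence profile along the capillary while
#' an alternating electric field pulls the chromosome in (ON) and lets it
#' relax back (OFF). The super-threshold extent follows a mono-exponential
#' rise toward `extension_max_um` during ON epochs (time constant `tau_on_s`)
#' and a mono-exponential decay during OFF epochs (`tau_off_s`).
#'
#' @param extension_max_um Plateau extension in micrometres.
#' @param tau_on_s,tau_off_s Rise and decay time constants in seconds, `> 0`.
#' @param cycle_times data.frame with columns `start_s`, `end_s`, `state`
#'   (`"on"`/`"off"`); epochs must be non-overlapping and ordered.
#' @param profile_noise Gaussian noise sd added to the unit-height profile.
#' @param seed Integer seed.
#' @param frame_interval_s Sampling interval in seconds.
#' @param pixel_size_um Spatial pitch of the profile in micrometres.
#' @return A `kymograph` with `$profile` (`[frame, position]`), `$t_s`,
#'   `$x_um`, the true `$extension_um` series and `$epochs`.
#' @export
simulate_stretch_kymograph <- function(extension_max_um, tau_on_s, tau_off_s,
                                       cycle_times, profile_noise = 0.05,
                                       seed = 1, frame_interval_s = 0.1,
                                       pixel_size_um = 0.16) {
  if (tau_on_s <= 0 || tau_off_s <= 0)
    stop("simulate_stretch_kymograph: time constants must be positive", call. = FALSE)
  ep <- cycle_times[order(cycle_times$start_s), ]
  if (any(ep$end_s <= ep$start_s) ||
      (nrow(ep) > 1 && any(ep$start_s[-1] < ep$end_s[-nrow(ep)] - 1e-12)))
    stop("simulate_stretch_kymograph: epochs overlap or are degenerate", call. = FALSE)
  t_s <- seq(0, max(ep$end_s), by = frame_interval_s)
  ext <- numeric(length(t_s))
  e <- 0
  for (r in seq_len(nrow(ep))) {
    sel <- t_s >= ep$start_s[r] & t_s <= ep$end_s[r]
    tt <- t_s[sel] - ep$start_s[r]
    if (ep$state[r] == "on") {
      ext[sel] <- extension_max_um + (e - extension_max_um) * exp(-tt / tau_on_s)
    } else {
      ext[sel] <- e * exp(-tt / tau_off_s)
    }
    if (any(sel)) e <- ext[which(sel)[sum(sel)]]
  }
  x_um <- seq(0, extension_max_um * 1.4, by = pixel_size_um)
  set.seed(derive_seed(seed, "kymograph"))
  edge_w <- pixel_size_um  # soft front about one pixel wide
  profile <- t(vapply(seq_along(t_s), function(i)
    1 / (1 + exp((x_um - ext[i]) / edge_w)), numeric(length(x_um))))
  profile <- profile + matrix(stats::rnorm(length(profile), sd = profile_noise),
                              nrow = nrow(profile))
  structure(list(profile = profile, t_s = t_s, x_um = x_um,
                 extension_um = ext, epochs = ep,
                 extension_max_um = extension_max_um,
                 tau_on_s = tau_on_s, tau_off_s = tau_off_s, seed = seed),
            class = "kymograph")
}

#' Measure the super-threshold extension of a kymograph
#'
#' The per-frame extent is the largest position whose (lightly smoothed)
#' profile exceeds `threshold`, with linear sub-pixel interpolation at the
#' crossing.
#'
#' @param kymo A `kymograph`.
#' @param threshold Fraction of the unit profile height (default 0.5).
#' @return data.frame with `t_s` and `extension_um`.
#' @export
measure_extension <- function(kymo, threshold = 0.5) {
  ext <- vapply(seq_len(nrow(kymo$profile)), function(i) {
    p <- smooth_series(kymo$profile[i, ], 1)
    above <- which(p >= threshold)
    if (!length(above)) return(0)
    j <- max(above)
    if (j == length(p)) return(kymo$x_um[j])
    frac <- (p[j] - threshold) / (p[j] - p[j + 1])
    kymo$x_um[j] + frac * (kymo$x_um[j + 1] - kymo$x_um[j])
  }, numeric(1))
  data.frame(t_s = kymo$t_s, extension_um = ext)
}
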