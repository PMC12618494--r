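# Shared fixtures, built in code at test time.

test_camera <- function(frame_interval_s = 2, ...) {
  camera_model(frame_interval_s = frame_interval_s, ...)
}

# An arrival truth with no events: renders pure background frames.
blank_arrival_truth <- function(n_frames, seed = 1, fov = c(10.24, 10.24),
                                frame_interval_s = 2) {
  structure(list(events = data.frame(id = integer(), time_s = numeric(),
                                     x_um = numeric(), y_um = numeric(),
                                     bleach_s = numeric()),
                 rate_per_min = 0,
                 duration_min = n_frames * frame_interval_s / 60,
                 bleach_tau_s = 120, capture_area = fov, blink_prob = 0,
                 seed = seed),
            class = "arrival_truth")
}

# A stationary emitter at (x, y) um rendered over n frames.
stationary_emitter_stack <- function(x, y, n_frames = 1, camera = test_camera(),
                                     seed = 1, fov = c(10.24, 10.24)) {
  tr <- structure(list(
    tracks = data.frame(id = 1L, frame = 0:(n_frames - 1), x_um = x, y_um = y),
    diffusion_um2_per_s = 0, frame_interval_s = camera$frame_interval_s,
    geometry = NULL, seed = seed), class = "track_truth")
  render_frames(tr, camera, seed = seed, fov_um = fov)
}

# Brute-force Mann-Whitney U and exact two-sided p by enumerating all
# rank assignments (independent oracle; no ties assumed).
mw_enumerate <- function(a, b) {
  m <- length(a); n <- length(b)
  U_obs <- sum(outer(a, b, ">"))
  pooled <- c(a, b)
  combs <- utils::combn(m + n, m)
  U_all <- apply(combs, 2, function(idx)
    sum(outer(pooled[idx], pooled[-idx], ">")))
  p <- min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
  list(U = U_obs, p = p, U_all = U_all)
}
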