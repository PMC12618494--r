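# Single-molecule spot detection, sub-pixel localization, track linking,
# MSD/diffusion estimation, and clustering of appearances into arrival events.

#' Detect single-molecule spots in an image stack
#'
#' Each frame is variance-stabilized with a square-root transform (the EM-CCD
#' Poisson-gamma noise otherwise has a heavy right tail that inflates false
#' positives), band-pass filtered with a difference of Gaussians (sigma and
#' 2 sigma), and candidates are taken as 3x3 local maxima of the band image
#' gated on signal-to-noise against a robust per-frame background
#' (median / 1.4826 MAD of the band image). Positions are refined to
#' sub-pixel precision by an intensity-weighted centroid of the
#' background-subtracted raw image in a window of about `4 sigma + 1` pixels.
#' Detections are sorted by frame, then decreasing intensity.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name or index (default first).
#' @param psf_sigma_um PSF sigma in micrometres; defaults to the stack's
#'   camera model. Must be at least half a pixel.
#' @param snr_min Minimum SNR of the band-pass response (default 5).
#' @return data.frame with columns `frame` (0-based), `channel`, `x_um`,
#'   `y_um`, `intensity` (background-subtracted integrated counts), `snr`.
#' @export
detect_spots <- function(stack, channel = 1, psf_sigma_um = NULL, snr_min = 5) {
  ch <- resolve_channel(stack, channel)
  px <- stack$camera$pixel_size_um
  sig_um <- psf_sigma_um %||% stack$camera$psf_sigma_um
  if (sig_um < px / 2)
    stop("detect_spots: 'psf_sigma_um' below the pixel sampling limit", call. = FALSE)
  sig <- sig_um / px
  counts <- stack$counts[, , , ch, drop = FALSE]
  d <- dim(counts)
  ny <- d[1]; nx <- d[2]; nf <- d[3]
  dim(counts) <- c(ny, nx, nf)
  if (nf == 0 || ny == 0) return(empty_detections())
  stab <- sqrt(pmax(counts, 0))
  band <- gauss_blur(stab, sig) - gauss_blur(stab, 2 * sig)
  # robust per-frame location and noise scale of the band image
  bm <- matrix(band, ny * nx, nf)
  med <- apply(bm, 2, stats::median)
  mad <- apply(abs(sweep(bm, 2, med)), 2, stats::median) * 1.4826
  mad[mad <= 0] <- 1e-12
  raw_med <- apply(matrix(counts, ny * nx, nf), 2, stats::median)
  # sparse candidate pass: only super-threshold pixels are tested for maxima
  thr_arr <- rep(med + snr_min * mad, each = ny * nx)
  cand <- which(as.vector(band) >= thr_arr)
  if (!length(cand)) return(empty_detections())
  ci <- arrayInd(cand, c(ny, nx, nf))
  w <- as.integer(max(1, round(2 * sig)))  # half-window ~ 2 sigma
  res <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    cy <- ci[i, 1]; cx <- ci[i, 2]; f <- ci[i, 3]
    ys <- max(1, cy - 1):min(ny, cy + 1)
    xs <- max(1, cx - 1):min(nx, cx + 1)
    nb <- band[ys, xs, f]
    v <- band[cy, cx, f]
    if (v < max(nb)) next
    if (v == max(nb) && sum(nb == v) > 1 &&
        which(nb == v)[1] != (match(cy, ys) + (match(cx, xs) - 1) * length(ys)))
      next  # deterministic tie-break toward the lowest index
    ys <- max(1, cy - w):min(ny, cy + w)
    xs <- max(1, cx - w):min(nx, cx + w)
    patch <- pmax(counts[ys, xs, f] - raw_med[f], 0)
    s <- sum(patch)
    if (s <= 0) next
    ybar <- sum(rowSums(patch) * ys) / s
    xbar <- sum(colSums(patch) * xs) / s
    res[[i]] <- c(f - 1L, xbar, ybar, s, (v - med[f]) / mad[f])
  }
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty_detections())
  out <- data.frame(frame = as.integer(res[, 1]),
                    channel = stack$channel_names[ch],
                    x_um = (res[, 2] - 1) * px,
                    y_um = (res[, 3] - 1) * px,
                    intensity = res[, 4],
                    snr = res[, 5])
  out <- out[order(out$frame, -out$intensity), ]
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(frame = integer(), channel = character(), x_um = numeric(),
             y_um = numeric(), intensity = numeric(), snr = numeric())
}

#' Link detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment with cost equal to the
#' squared displacement. Links beyond `max_disp_um` are rejected; dropouts of
#' up to `max_gap_frames` frames are bridged. Each detection joins at most one
#' track. Ties are broken by smallest distance, then lowest detection index,
#' so linking is deterministic.
#'
#' @param detections Detections of a single channel, as from [detect_spots()].
#' @param max_disp_um Maximum frame-to-frame displacement in micrometres.
#' @param max_gap_frames Maximum number of bridged missing frames (default 0).
#' @return The detections with an added `track_id` column, ordered by track
#'   then frame; attribute `max_gap_frames` records the setting.
#' @export
link_tracks <- function(detections, max_disp_um, max_gap_frames = 0) {
  if (length(unique(detections$channel)) > 1)
    stop("link_tracks: detections must come from a single channel", call. = FALSE)
  n <- nrow(detections)
  det <- detections[order(detections$frame), ]
  det$.idx <- seq_len(n)
  track_of <- integer(n)
  last_frame <- numeric(0); last_x <- numeric(0); last_y <- numeric(0)
  next_track <- 1L
  for (f in sort(unique(det$frame))) {
    rows <- which(det$frame == f)
    open <- which(f - last_frame >= 1 & f - last_frame <= max_gap_frames + 1)
    if (length(open) && length(rows)) {
      dmat <- outer(last_x[open], det$x_um[rows], "-")^2 +
        outer(last_y[open], det$y_um[rows], "-")^2
      pairs <- which(dmat <= max_disp_um^2, arr.ind = TRUE)
      if (nrow(pairs)) {
        ord <- order(dmat[pairs], pairs[, 2])
        used_t <- logical(length(open)); used_d <- logical(length(rows))
        for (pidx in ord) {
          ti <- pairs[pidx, 1]; di <- pairs[pidx, 2]
          if (used_t[ti] || used_d[di]) next
          used_t[ti] <- TRUE; used_d[di] <- TRUE
          tr <- open[ti]
          track_of[det$.idx[rows[di]]] <- tr
          last_frame[tr] <- f; last_x[tr] <- det$x_um[rows[di]]
          last_y[tr] <- det$y_um[rows[di]]
        }
        rows <- rows[!used_d]
      }
    }
    for (di in rows) {  # unmatched detections start new tracks
      track_of[det$.idx[di]] <- next_track
      last_frame[next_track] <- f
      last_x[next_track] <- det$x_um[di]
      last_y[next_track] <- det$y_um[di]
      next_track <- next_track + 1L
    }
  }
  out <- detections
  out$track_id <- track_of
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "max_gap_frames") <- max_gap_frames
  out
}

#' Time-averaged mean squared displacement of a track
#'
#' MSD over all ordered position pairs per lag, for lags up to
#' `max_lag_fraction` of the track length.
#'
#' @param track data.frame with `frame`, `x_um`, `y_um` (a single track).
#' @param frame_interval_s Frame interval in seconds.
#' @param max_lag_fraction Largest lag as a fraction of track length
#'   (default 0.25).
#' @return An `msd_curve` data.frame with `lag_s`, `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(track, frame_interval_s, max_lag_fraction = 0.25) {
  track <- track[order(track$frame), ]
  nfr <- nrow(track)
  if (nfr < 10)
    stop("compute_msd: insufficient track length (need >= 10 frames)", call. = FALSE)
  # place positions on a frame-indexed grid so gaps enter the lag correctly
  f0 <- min(track$frame)
  span <- max(track$frame) - f0 + 1
  x <- rep(NA_real_, span); y <- rep(NA_real_, span)
  x[track$frame - f0 + 1] <- track$x_um
  y[track$frame - f0 + 1] <- track$y_um
  max_lag <- max(1L, floor(max_lag_fraction * span))
  lags <- seq_len(max_lag)
  msd <- n_pairs <- numeric(max_lag)
  for (L in lags) {
    dx <- x[(1 + L):span] - x[1:(span - L)]
    dy <- y[(1 + L):span] - y[1:(span - L)]
    ok <- !is.na(dx)
    n_pairs[L] <- sum(ok)
    msd[L] <- if (any(ok)) mean(dx[ok]^2 + dy[ok]^2) else NA_real_
  }
  out <- data.frame(lag_s = lags * frame_interval_s, msd_um2 = msd,
                    n_pairs = n_pairs)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Pool MSD curves from an ensemble of tracks
#'
#' Per-lag weighted mean of the individual curves, weighted by the number of
#' displacement pairs contributing at that lag.
#'
#' @param curves List of [compute_msd()] results.
#' @return An `msd_curve` data.frame.
#' @export
pool_msd <- function(curves) {
  all_lags <- sort(unique(unlist(lapply(curves, function(c) c$lag_s))))
  msd <- n <- numeric(length(all_lags))
  for (cu in curves) {
    i <- match(cu$lag_s, all_lags)
    ok <- !is.na(cu$msd_um2)
    msd[i[ok]] <- msd[i[ok]] + cu$msd_um2[ok] * cu$n_pairs[ok]
    n[i[ok]] <- n[i[ok]] + cu$n_pairs[ok]
  }
  out <- data.frame(lag_s = all_lags, msd_um2 = ifelse(n > 0, msd / n, NA),
                    n_pairs = n)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Weighted least-squares line through the origin, `msd = 4 D lag`, weighted
#' by the number of pairs per lag. A negative fitted slope is reported as
#' `D = 0` with a flag.
#'
#' @param msd An `msd_curve` (needs at least 4 lags).
#' @return List with `D_um2_per_s`, `se`, and `flag` (`"ok"`, `"negative"`,
#'   or `"degenerate"`).
#' @export
fit_diffusion <- function(msd) {
  ok <- !is.na(msd$msd_um2) & msd$n_pairs > 0
  if (sum(ok) < 4)
    stop("fit_diffusion: need at least 4 usable lags", call. = FALSE)
  t <- msd$lag_s[ok]; y <- msd$msd_um2[ok]; w <- msd$n_pairs[ok]
  if (all(y == 0))
    return(list(D_um2_per_s = 0, se = 0, flag = "degenerate"))
  slope <- sum(w * t * y) / sum(w * t^2)
  resid <- y - slope * t
  dfree <- max(1, sum(ok) - 1)
  se_slope <- sqrt(sum(w * resid^2) / dfree / sum(w * t^2))
  if (slope < 0)
    return(list(D_um2_per_s = 0, se = se_slope / 4, flag = "negative"))
  list(D_um2_per_s = slope / 4, se = se_slope / 4, flag = "ok")
}

#' Cluster repeated detections into arrival events
#'
#' Density-based clustering in (x, y, frame): two detections are neighbours
#' when their spatial distance is at most `radius_um` and their frame gap at
#' most `max_frame_gap`; clusters are the connected components of the
#' neighbour graph. Clusters with fewer than `min_detections` members are
#' discarded. Each cluster yields one arrival event timed at its earliest
#' member, which corrects the overcounting that per-frame detection causes
#' when one immobilized molecule blinks.
#'
#' @param detections Detections from the surface-capture channel.
#' @param frame_interval_s Frame interval in seconds.
#' @param radius_um Spatial clustering radius (default 0.32).
#' @param max_frame_gap Maximum temporal gap in frames (default 5).
#' @param min_detections Minimum cluster size (default 2).
#' @return An `arrival_events` data.frame with `cluster_id`,
#'   `arrival_time_s`, `x_um`, `y_um`, `n_detections`; parameters are kept as
#'   attributes.
#' @export
cluster_arrivals <- function(detections, frame_interval_s, radius_um = 0.32,
                             max_frame_gap = 5, min_detections = 2) {
  n <- nrow(detections)
  if (n == 0) {
    out <- data.frame(cluster_id = integer(), arrival_time_s = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      n_detections = integer())
    return(structure(out, class = c("arrival_events", "data.frame")))
  }
  det <- detections[order(detections$frame), ]
  # union-find over the neighbour graph, scanning a frame window
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  for (i in seq_len(n)) {
    js <- which(det$frame > det$frame[i] - 1e-9 &
                  det$frame <= det$frame[i] + max_frame_gap)
    js <- js[js > i]
    if (!length(js)) next
    d2 <- (det$x_um[js] - det$x_um[i])^2 + (det$y_um[js] - det$y_um[i])^2
    for (j in js[d2 <= radius_um^2]) unite(i, j)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- match(roots, unique(roots))
  keep <- tabulate(cl)[cl] >= min_detections
  det$cl <- cl
  det <- det[keep, ]
  if (!nrow(det)) {
    out <- data.frame(cluster_id = integer(), arrival_time_s = numeric(),
                      x_um = numeric(), y_um = numeric(),
                      n_detections = integer())
    return(structure(out, class = c("arrival_events", "data.frame")))
  }
  sp <- split(seq_len(nrow(det)), det$cl)
  out <- do.call(rbind, lapply(seq_along(sp), function(k) {
    rows <- det[sp[[k]], ]
    data.frame(cluster_id = k,
               arrival_time_s = min(rows$frame) * frame_interval_s,
               x_um = mean(rows$x_um), y_um = mean(rows$y_um),
               n_detections = nrow(rows))
  }))
  out <- out[order(out$arrival_time_s), ]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "radius_um") <- radius_um
  attr(out, "max_frame_gap") <- max_frame_gap
  attr(out, "min_detections") <- min_detections
  class(out) <- c("arrival_events", "data.frame")
  out
}

#' Keep only detections strictly inside a compartment outline
#'
#' Reproduces the manual step of outlining compartments to discard spurious
#' spots outside them. Point-in-polygon by the even-odd rule; points on the
#' boundary are excluded.
#'
#' @param detections data.frame with `x_um`, `y_um`.
#' @param polygon data.frame or matrix of polygon vertices (`x_um`, `y_um`),
#'   in order, not closed.
#' @return The subset of `detections` strictly inside the polygon.
#' @export
mask_filter <- function(detections, polygon) {
  poly <- as.matrix(polygon)
  if (nrow(poly) < 3)
    stop("mask_filter: polygon needs at least 3 vertices", call. = FALSE)
  if (polygon_self_intersects(poly[, 1], poly[, 2]))
    stop("mask_filter: polygon is self-intersecting", call. = FALSE)
  if (!nrow(detections)) return(detections)
  keep <- points_in_polygon(detections$x_um, detections$y_um,
                            poly[, 1], poly[, 2])
  out <- detections[keep, ]
  rownames(out) <- NULL
  out
}

#' Waiting times between consecutive arrival events
#'
#' The first waiting time is measured from the start of observation (time 0);
#' subsequent ones are differences between consecutive arrivals. For a
#' Poisson synthesis process these are the exponentially distributed times
#' whose cumulative distribution [fit_arrival_cdf()] fits.
#'
#' @param arrival_times_s Sorted or unsorted arrival times in seconds.
#' @return Numeric vector of waiting times.
#' @export
waiting_times <- function(arrival_times_s) {
  diff(c(0, sort(arrival_times_s)))
}
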