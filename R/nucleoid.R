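# Chromosome segmentation, area estimation and tracking, DNA-blob detection,
# condensin colocalization, cluster counting, and crowding dose-response.

#' Segment chromosomes in a DNA-stain frame
#'
#' Classical segmentation pipeline: background estimated by a large-scale
#' morphological opening and subtracted; Gaussian smoothing; global threshold
#' (Otsu by default, or a constant); 8-connected components; regions below
#' `min_area_um2` discarded; optionally, touching chromosomes are split by a
#' watershed on the distance transform.
#'
#' @param frame Numeric matrix of a single DNA-stain (e.g. SYBR Green I)
#'   frame, or an [image_stack()] (first frame of `channel` is used).
#' @param pixel_size_um Pixel size in micrometres (taken from the stack when
#'   a stack is supplied).
#' @param smoothing_sigma_um Gaussian smoothing sigma (default 0.16).
#' @param threshold_method `"otsu"` or a numeric constant threshold on the
#'   background-subtracted, smoothed image.
#' @param min_area_um2 Minimum region area (default 1).
#' @param split_touching Split touching regions by watershed (default FALSE).
#' @param background_radius_um Structuring-element radius of the opening used
#'   for background estimation (default 8; must exceed the half-width of the
#'   largest chromosome or the opening eats into the foreground).
#' @param channel Channel used when `frame` is a stack (default `"dna"` if
#'   present, else 1).
#' @return A `chromosome_regions` object: `$regions` data.frame (`label`,
#'   `area_um2`, `x_um`, `y_um`, `mean_intensity`, `n_pixels`) and `$labels`
#'   integer label matrix.
#' @export
segment_chromosomes <- function(frame, pixel_size_um = NULL,
                                smoothing_sigma_um = 0.16,
                                threshold_method = "otsu",
                                min_area_um2 = 1,
                                split_touching = FALSE,
                                background_radius_um = 8,
                                channel = NULL) {
  if (inherits(frame, "image_stack")) {
    ch <- channel %||% (if ("dna" %in% frame$channel_names) "dna" else 1)
    pixel_size_um <- frame$camera$pixel_size_um
    frame <- get_frame(frame, 0, ch)
  }
  if (is.null(pixel_size_um))
    stop("segment_chromosomes: 'pixel_size_um' is required", call. = FALSE)
  px <- pixel_size_um
  img <- frame
  # background: morphological opening with a disc much larger than the PSF
  br <- max(3L, as.integer(round(background_radius_um / px)))
  if (br %% 2 == 0) br <- br + 1L
  bg <- EBImage::opening(EBImage::Image(img / max(img, 1)),
                         EBImage::makeBrush(br, shape = "disc"))
  sub <- pmax(img - as.matrix(EBImage::imageData(bg)) * max(img, 1), 0)
  sm <- gauss_blur(sub, smoothing_sigma_um / px)
  if (identical(threshold_method, "otsu")) {
    rng <- range(sm)
    if (diff(rng) <= 0) {
      mask <- matrix(FALSE, nrow(sm), ncol(sm))
    } else {
      norm <- (sm - rng[1]) / diff(rng)
      thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
      mask <- norm > thr
      # midpoint refinement: the raw Otsu threshold shifts with the
      # foreground/background pixel proportions (chromosomes cover a few
      # percent of a field), dilating or eroding small masks; the midpoint of
      # the two classes' median levels is proportion-independent and places
      # the boundary at the half-intensity contour
      if (any(mask) && !all(mask)) {
        thr <- (stats::median(norm[!mask]) + stats::median(norm[mask])) / 2
        mask <- norm > thr
      }
    }
  } else {
    mask <- sm > threshold_method
  }
  lab <- label_components(mask)
  if (split_touching && max(lab) > 0) {
    dm <- EBImage::distmap(EBImage::Image((lab > 0) * 1))
    ws <- EBImage::watershed(dm, tolerance = 1)
    lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(lab), ncol(lab))
  }
  regions <- region_table(lab, img, px, min_area_um2)
  # relabel the matrix to the surviving regions
  keep <- regions$label
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0] <- match(lab[lab > 0], keep)
  regions$label <- seq_len(nrow(regions))
  structure(list(regions = regions, labels = lab, pixel_size_um = px),
            class = "chromosome_regions")
}

region_table <- function(lab, img, px, min_area_um2) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    area <- nrow(idx) * px^2
    if (area < min_area_um2) return(NULL)
    inten <- img[lab == id]
    data.frame(label = id, area_um2 = area,
               x_um = (mean(idx[, 2]) - 1) * px,
               y_um = (mean(idx[, 1]) - 1) * px,
               mean_intensity = mean(inten), n_pixels = nrow(idx))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(), area_um2 = numeric(), x_um = numeric(),
                      y_um = numeric(), mean_intensity = numeric(),
                      n_pixels = integer())
  rownames(out) <- NULL
  out
}

#' @export
print.chromosome_regions <- function(x, ...) {
  cat(sprintf("chromosome_regions: %d region(s), total area %.2f um^2\n",
              nrow(x$regions), sum(x$regions$area_um2)))
  invisible(x)
}

#' Link segmented regions over time by mask overlap
#'
#' Two regions in consecutive frames belong to the same series when their
#' masks share at least one pixel. One-to-many overlaps are resolved by the
#' largest overlap, then the lowest label; unlinked regions start new series.
#' No gap bridging: a region that disappears for a frame starts a new series.
#'
#' @param segmentations List of `chromosome_regions`, one per frame, on a
#'   common pixel grid.
#' @return data.frame with `series_id`, `frame` (0-based), `label`,
#'   `area_um2`.
#' @export
link_regions <- function(segmentations) {
  out <- list()
  prev_series <- integer(0)  # series id per previous-frame label
  next_id <- 1L
  prev_lab <- NULL
  for (f in seq_along(segmentations)) {
    seg <- segmentations[[f]]
    labs <- seg$regions$label
    series <- integer(length(labs))
    if (!is.null(prev_lab) && length(labs)) {
      for (i in seq_along(labs)) {
        here <- seg$labels == labs[i]
        over <- prev_lab[here]
        over <- over[over > 0]
        if (length(over)) {
          tab <- sort(table(over), decreasing = TRUE)
          best <- as.integer(names(tab)[tab == max(tab)])
          series[i] <- prev_series[min(best)]
        }
      }
      # a series may be claimed by several regions: keep the largest overlap
      dup <- series[duplicated(series) & series > 0]
      for (s in unique(dup)) {
        cl <- which(series == s)
        keep <- cl[which.max(seg$regions$n_pixels[cl])]
        series[setdiff(cl, keep)] <- 0L
      }
    }
    for (i in which(series == 0L)) { series[i] <- next_id; next_id <- next_id + 1L }
    out[[f]] <- data.frame(series_id = series,
                           frame = rep(f - 1L, length(labs)), label = labs,
                           area_um2 = seg$regions$area_um2)
    prev_series <- integer(max(labs, 0))
    prev_series[labs] <- series
    prev_lab <- seg$labels
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalized summed-area time series
#'
#' Sum of all region areas per frame, normalized by the frame-0 sum, plus a
#' Gaussian-smoothed copy (reflective edges, kernel normalized so the series
#' mean is preserved).
#'
#' @param linked data.frame from [link_regions()] (needs `frame`,
#'   `area_um2`), or a list of `chromosome_regions`.
#' @param frame_interval_s Frame interval in seconds.
#' @param smoothing_sigma_s Gaussian kernel sigma in seconds.
#' @return data.frame with `t_s`, `area_norm`, `area_norm_smooth`.
#' @export
summed_area_series <- function(linked, frame_interval_s, smoothing_sigma_s) {
  if (is.list(linked) && !is.data.frame(linked))
    linked <- do.call(rbind, lapply(seq_along(linked), function(f)
      data.frame(frame = f - 1L, area_um2 = linked[[f]]$regions$area_um2)))
  frames <- sort(unique(linked$frame))
  if (length(frames) < 2)
    stop("summed_area_series: need at least 2 frames", call. = FALSE)
  total <- vapply(frames, function(f) sum(linked$area_um2[linked$frame == f]),
                  numeric(1))
  if (total[1] <= 0)
    stop("summed_area_series: zero initial summed area", call. = FALSE)
  norm <- total / total[1]
  sm <- smooth_series(norm, smoothing_sigma_s / frame_interval_s)
  data.frame(t_s = frames * frame_interval_s, area_norm = norm,
             area_norm_smooth = sm)
}

#' Detect DNA blobs inside a chromosome region
#'
#' Laplacian-of-Gaussian response (scale-normalized, computed as a difference
#' of Gaussians) restricted to the region mask; local maxima above the
#' `prominence` gate are kept and refined to sub-pixel centroids.
#'
#' @param image Numeric matrix (DNA channel frame).
#' @param regions A `chromosome_regions` from [segment_chromosomes()]; blobs
#'   are searched inside its masks.
#' @param blob_sigma_um Expected blob scale (default 0.3).
#' @param prominence Minimum band-pass response, as a fraction of the largest
#   response inside the masks (default 0.45).
#' @param max_edge_ratio Hessian-based edge rejection: candidates whose
#'   trace-squared over determinant exceeds this are ridges (chromosome
#'   boundary responses), not blobs, and are dropped. An isotropic peak
#'   scores 4; the default 5 keeps mildly elliptical blobs.
#' @return data.frame with `region`, `x_um`, `y_um`, `response`.
#' @export
detect_blobs <- function(image, regions, blob_sigma_um = 0.3,
                         prominence = 0.45, max_edge_ratio = 5) {
  px <- regions$pixel_size_um
  sig <- blob_sigma_um / px
  band <- gauss_blur(image, sig) - gauss_blur(image, 1.6 * sig)
  # erode the mask so ridge responses along the region boundary are excluded
  er <- 2L * as.integer(ceiling(sig)) + 1L
  mask <- as.matrix(EBImage::imageData(EBImage::erode(
    EBImage::Image((regions$labels > 0) * 1), EBImage::makeBrush(er, "disc")))) > 0
  ny <- nrow(band); nx <- ncol(band)
  ismax <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- matrix(-Inf, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy); xs <- max(1, 1 + dx):min(nx, nx + dx)
    sh[ys, xs] <- band[ys - dy, xs - dx]
    ismax <- ismax & (band > sh | (band == sh & (dy > 0 | (dy == 0 & dx > 0))))
  }
  top <- max(band[mask], -Inf)
  if (!is.finite(top) || top <= 0)
    return(data.frame(region = integer(), x_um = numeric(), y_um = numeric(),
                      response = numeric()))
  # contrast gate: a blob must be brighter than the regions' typical level;
  # boundary-curvature responses of a uniform region sit exactly at it
  img_sm <- gauss_blur(image, sig)
  med_r <- stats::median(img_sm[regions$labels > 0])
  cand <- which(ismax & mask & band >= prominence * top &
                  img_sm > med_r * 1.1, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(region = integer(), x_um = numeric(), y_um = numeric(),
                      response = numeric()))
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    if (cy > 1 && cy < ny && cx > 1 && cx < nx) {
      dxx <- band[cy, cx - 1] - 2 * band[cy, cx] + band[cy, cx + 1]
      dyy <- band[cy - 1, cx] - 2 * band[cy, cx] + band[cy + 1, cx]
      dxy <- (band[cy + 1, cx + 1] - band[cy + 1, cx - 1] -
                band[cy - 1, cx + 1] + band[cy - 1, cx - 1]) / 4
      dt <- dxx * dyy - dxy^2
      if (dt <= 0 || (dxx + dyy)^2 / dt > max_edge_ratio) return(NULL)
    }
    # parabolic sub-pixel refinement of the band peak (robust to the
    # asymmetric plateau background, unlike an intensity centroid)
    dx <- dy <- 0
    if (cx > 1 && cx < nx) {
      den <- band[cy, cx - 1] - 2 * band[cy, cx] + band[cy, cx + 1]
      if (den < 0) dx <- 0.5 * (band[cy, cx - 1] - band[cy, cx + 1]) / den
    }
    if (cy > 1 && cy < ny) {
      den <- band[cy - 1, cx] - 2 * band[cy, cx] + band[cy + 1, cx]
      if (den < 0) dy <- 0.5 * (band[cy - 1, cx] - band[cy + 1, cx]) / den
    }
    data.frame(region = regions$labels[cy, cx],
               x_um = (cx + max(min(dx, 1), -1) - 1) * px,
               y_um = (cy + max(min(dy, 1), -1) - 1) * px,
               response = band[cy, cx])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$response), ]
  rownames(out) <- NULL
  out
}

#' Match DNA blobs to condensin spots within a distance threshold
#'
#' Greedy one-to-one nearest-pair matching under the strict rule
#' `distance < radius_um`; pairs at exactly the threshold are non-matches.
#' The colocalized fraction is the number of matched blobs over all blobs.
#'
#' @param blobs data.frame with `x_um`, `y_um` (DNA blobs).
#' @param spots data.frame with `x_um`, `y_um` (e.g. condensin detections),
#'   same frame.
#' @param radius_um Matching radius (default 0.32, i.e. two pixels).
#' @return A `coloc_result` list: `n_blobs`, `n_matched`,
#'   `fraction_colocalized`, `radius_um`, `pairs` data.frame.
#' @export
colocalize <- function(blobs, spots, radius_um = 0.32) {
  nb <- nrow(blobs); ns <- nrow(spots)
  pairs <- data.frame(blob = integer(), spot = integer(), dist_um = numeric())
  if (nb > 0 && ns > 0) {
    d <- sqrt(outer(blobs$x_um, spots$x_um, "-")^2 +
                outer(blobs$y_um, spots$y_um, "-")^2)
    ord <- order(d)
    used_b <- logical(nb); used_s <- logical(ns)
    for (k in ord) {
      if (d[k] >= radius_um) break
      b <- (k - 1) %% nb + 1; s <- (k - 1) %/% nb + 1
      if (used_b[b] || used_s[s]) next
      used_b[b] <- TRUE; used_s[s] <- TRUE
      pairs <- rbind(pairs, data.frame(blob = b, spot = s, dist_um = d[k]))
    }
  }
  structure(list(n_blobs = nb, n_matched = nrow(pairs),
                 fraction_colocalized = if (nb > 0) nrow(pairs) / nb else NA_real_,
                 radius_um = radius_um, pairs = pairs),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization: %d / %d blobs matched (%.0f%%) at < %.2f um\n",
              x$n_matched, x$n_blobs, 100 * x$fraction_colocalized, x$radius_um))
  invisible(x)
}

#' Count spots per chromosome region
#'
#' Assigns each spot to the region whose mask contains its nearest pixel and
#' reports per-region counts with ensemble summary statistics.
#'
#' @param spots data.frame with `x_um`, `y_um`.
#' @param regions A `chromosome_regions`.
#' @return List with `counts` data.frame (`label`, `n_spots`), `median`,
#'   `min`, `max`.
#' @export
count_clusters <- function(spots, regions) {
  px <- regions$pixel_size_um
  labs <- regions$regions$label
  n <- setNames(integer(length(labs)), labs)
  if (nrow(spots)) {
    ny <- nrow(regions$labels); nx <- ncol(regions$labels)
    for (i in seq_len(nrow(spots))) {
      cy <- min(max(round(spots$y_um[i] / px) + 1, 1), ny)
      cx <- min(max(round(spots$x_um[i] / px) + 1, 1), nx)
      l <- regions$labels[cy, cx]
      if (l == 0) {  # fall back to the nearest labeled pixel within 2 px
        win_y <- max(1, cy - 2):min(ny, cy + 2)
        win_x <- max(1, cx - 2):min(nx, cx + 2)
        sub <- regions$labels[win_y, win_x]
        if (any(sub > 0)) {
          idx <- which(sub > 0, arr.ind = TRUE)
          d2 <- (win_y[idx[, 1]] - cy)^2 + (win_x[idx[, 2]] - cx)^2
          l <- sub[idx[which.min(d2), , drop = FALSE]]
        }
      }
      if (l > 0) n[as.character(l)] <- n[as.character(l)] + 1L
    }
  }
  counts <- data.frame(label = labs, n_spots = as.integer(n))
  list(counts = counts, median = stats::median(counts$n_spots),
       min = if (nrow(counts)) min(counts$n_spots) else NA_integer_,
       max = if (nrow(counts)) max(counts$n_spots) else NA_integer_)
}

#' Aggregate chromosome areas into a crowding dose-response
#'
#' Per PEG condition: mean area and the 15.9% / 84.1% empirical quantiles
#' (the +/- 1 sd band of a normal distribution), using linear interpolation
#' between order statistics.
#'
#' @param areas_um2 Numeric vector of chromosome areas.
#' @param peg_percent Condition label (PEG % w/v) per area.
#' @return data.frame with `peg_percent`, `mean_area_um2`, `q_low`, `q_high`,
#'   `n_chromosomes`, ordered by PEG.
#' @export
dose_response <- function(areas_um2, peg_percent) {
  if (length(areas_um2) != length(peg_percent))
    stop("dose_response: 'areas_um2' and 'peg_percent' lengths differ", call. = FALSE)
  groups <- sort(unique(peg_percent))
  rows <- lapply(groups, function(g) {
    a <- areas_um2[peg_percent == g]
    if (!length(a))
      stop("dose_response: empty group at PEG ", g, call. = FALSE)
    q <- stats::quantile(a, c(0.159, 0.841), type = 7, names = FALSE)
    data.frame(peg_percent = g, mean_area_um2 = mean(a),
               q_low = q[1], q_high = q[2], n_chromosomes = length(a))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney U comparison of two area groups
#'
#' Exact U distribution for small samples without ties, normal approximation
#' with tie correction (and continuity correction) otherwise, as implemented
#' by [stats::wilcox.test()]. No multiple-testing correction is applied; this
#' is a reporting-layer statistic.
#'
#' @param areas_a,areas_b Numeric vectors, each of length at least 2.
#' @return List with `U`, `p_value`, `n_a`, `n_b`, `flag`.
#' @export
compare_groups <- function(areas_a, areas_b) {
  if (length(areas_a) < 2 || length(areas_b) < 2)
    stop("compare_groups: both groups need at least 2 values", call. = FALSE)
  if (length(unique(c(areas_a, areas_b))) == 1)
    return(list(U = length(areas_a) * length(areas_b) / 2, p_value = 1,
                n_a = length(areas_a), n_b = length(areas_b),
                flag = "degenerate_identical"))
  exact <- (length(areas_a) + length(areas_b)) <= 20 &&
    !any(duplicated(c(areas_a, areas_b)))
  wt <- suppressWarnings(stats::wilcox.test(areas_a, areas_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(areas_a), n_b = length(areas_b), flag = "ok")
}
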