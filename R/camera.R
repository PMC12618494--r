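#' EM-CCD camera and optics model
#'
#' Collects the acquisition parameters used both to render synthetic frames
#' and to interpret real stacks. The pixel size default (0.16 um) matches the
#' convention that two pixels correspond to 0.32 um; the photon budget,
#' background and read noise have no experimentally printed values and are
#' deliberately config-exposed.
#'
#' @param pixel_size_um Pixel size in micrometres (default 0.16).
#' @param frame_interval_s Time between consecutive frames of one channel, s.
#' @param exposure_s Exposure time per frame, s.
#' @param photons_per_frame Expected photons collected per emitter per frame.
#' @param background_photons Expected background photons per pixel per frame.
#' @param em_gain Mean multiplicative electron-multiplying gain.
#' @param read_noise_counts Gaussian read noise standard deviation, in counts.
#' @param psf_sigma_um Gaussian PSF standard deviation in micrometres. Must be
#'   at least half a pixel so the PSF is sampled above Nyquist.
#'
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_um = 0.16, frame_interval_s = 2,
                         exposure_s = 0.1, photons_per_frame = 400,
                         background_photons = 20, em_gain = 50,
                         read_noise_counts = 30, psf_sigma_um = 0.16) {
  if (pixel_size_um <= 0)
    stop("camera_model: 'pixel_size_um' must be positive", call. = FALSE)
  if (frame_interval_s <= 0)
    stop("camera_model: 'frame_interval_s' must be positive", call. = FALSE)
  if (psf_sigma_um < pixel_size_um / 2)
    stop("camera_model: 'psf_sigma_um' must be at least half a pixel (Nyquist sampling)",
         call. = FALSE)
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 exposure_s = exposure_s,
                 photons_per_frame = photons_per_frame,
                 background_photons = background_photons,
                 em_gain = em_gain,
                 read_noise_counts = read_noise_counts,
                 psf_sigma_um = psf_sigma_um),
            class = "camera_model")
}

#' Multi-frame, multi-channel image stack
#'
#' Thin container for camera counts plus the acquisition metadata every
#' downstream stage needs. Counts are stored as an array indexed
#' `[row, col, frame, channel]`; positions are continuous micrometres with the
#' origin at the centre of the top-left pixel, `x` along columns and `y` along
#' rows; the time of frame i (0-based) is `i * frame_interval_s`.
#'
#' @param counts Numeric array `[row, col, frame, channel]` (2-D and 3-D input
#'   is promoted) of non-negative camera counts.
#' @param camera A [camera_model()].
#' @param channel_names Character vector of channel labels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(counts, camera, channel_names = NULL) {
  if (is.matrix(counts)) dim(counts) <- c(dim(counts), 1L, 1L)
  if (length(dim(counts)) == 3L) dim(counts) <- c(dim(counts), 1L)
  if (length(dim(counts)) != 4L)
    stop("image_stack: 'counts' must be a [row, col, frame, channel] array", call. = FALSE)
  if (any(counts < 0)) stop("image_stack: counts must be non-negative", call. = FALSE)
  if (!inherits(camera, "camera_model"))
    stop("image_stack: 'camera' must be a camera_model", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(counts)[4]))
  if (length(channel_names) != dim(counts)[4])
    stop("image_stack: one name per channel required", call. = FALSE)
  structure(list(counts = counts, camera = camera,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("image_stack: %d x %d px, %d frame(s), %d channel(s) [%s], %g um/px, dt = %g s\n",
              d[1], d[2], d[3], d[4], paste(x$channel_names, collapse = ", "),
              x$camera$pixel_size_um, x$camera$frame_interval_s))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$counts)

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$counts)[3]

# Single frame of one channel as a plain matrix.
#' Extract one frame of one channel
#' @param stack An [image_stack()].
#' @param frame 0-based frame index.
#' @param channel Channel name or 1-based index.
#' @return Numeric matrix of counts.
#' @export
get_frame <- function(stack, frame = 0, channel = 1) {
  ch <- resolve_channel(stack, channel)
  stack$counts[, , frame + 1L, ch]
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ch <- match(channel, stack$channel_names)
    if (is.na(ch)) stop("unknown channel '", channel, "'", call. = FALSE)
    ch
  } else as.integer(channel)
}
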