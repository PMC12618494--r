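# TIFF and table I/O, run configuration, and the pipeline surface.

#' Write an image stack to multi-page TIFF with a metadata sidecar
#'
#' Pages are ordered frame-by-frame within each channel (one series per
#' channel). Counts are integers stored as 32-bit float pages on a recorded
#' linear scale, so the round trip is lossless. Acquisition metadata (pixel
#' size, frame interval, camera parameters, channel names) goes to a JSON
#' sidecar at `<path>.json`, since baseline TIFF tags cannot carry it.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$counts)
  scale <- 2^24
  if (max(stack$counts) >= scale)
    stop("write_stack: counts exceed the storable range", call. = FALSE)
  pages <- list()
  for (ch in seq_len(d[4])) for (f in seq_len(d[3]))
    pages[[length(pages) + 1]] <- stack$counts[, , f, ch] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(pixel_size_um = stack$camera$pixel_size_um,
               frame_interval_s = stack$camera$frame_interval_s,
               camera = unclass(stack$camera),
               channel_names = stack$channel_names,
               n_frames = d[3], n_channels = d[4], count_scale = scale,
               integer_counts = all(stack$counts == round(stack$counts)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' When the metadata sidecar is missing, pixel size and frame interval are
#' taken from `config` (fields `pixel_size_um`, `frame_interval_s`,
#' optionally `n_channels`) with a warning; without either source, reading
#' fails.
#'
#' @param path TIFF path.
#' @param config Optional list of fallback metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, config = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("read_stack: cannot read '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    cam <- do.call(camera_model, meta$camera[names(formals(camera_model))])
    scale <- meta$count_scale
    nf <- meta$n_frames; nc <- meta$n_channels
    channel_names <- meta$channel_names
    int_counts <- isTRUE(meta$integer_counts)
  } else {
    if (is.null(config) || is.null(config$pixel_size_um) ||
        is.null(config$frame_interval_s))
      stop("read_stack: no metadata sidecar and no config fallback for '",
           path, "'", call. = FALSE)
    warning("read_stack: metadata sidecar missing for '", path,
            "'; using pixel size and frame interval from config")
    cam <- camera_model(pixel_size_um = config$pixel_size_um,
                        frame_interval_s = config$frame_interval_s)
    scale <- config$count_scale %||% 1
    nc <- config$n_channels %||% 1L
    nf <- length(pages) / nc
    channel_names <- NULL
    int_counts <- TRUE
  }
  d1 <- dim(pages[[1]])
  counts <- array(0, c(d1[1], d1[2], nf, nc))
  k <- 1
  for (ch in seq_len(nc)) for (f in seq_len(nf)) {
    # the TIFF stage truncates to 1/2^32 steps; integer counts are restored
    # exactly by rounding
    counts[, , f, ch] <- if (int_counts) round(pages[[k]] * scale)
                         else pages[[k]] * scale
    k <- k + 1
  }
  image_stack(counts, cam, channel_names)
}

#' Read a run configuration file
#'
#' Single human-readable YAML file with parameter blocks (`geometry`,
#' `camera`, `detection`, `linking`, `clustering`, `segmentation`, `fitting`,
#' `dose_response`, `simulate`) and a global `seed`. A content hash is
#' attached so run logs can state exactly which configuration produced them;
#' stage seeds are derived deterministically from the global seed.
#'
#' @param path YAML file path.
#' @return The configuration list with attributes `hash` and `path`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config: no such file '", path, "'", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$seed <- cfg$seed %||% 1L
  attr(cfg, "hash") <- digest_config(cfg)
  attr(cfg, "path") <- path
  cfg
}

digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

write_run_log <- function(out_dir, subcommand, cfg, extra = list()) {
  log <- c(list(subcommand = subcommand,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                seed = cfg$seed, config_hash = attr(cfg, "hash") %||% digest_config(cfg),
                package_version = as.character(utils::packageVersion("chromtrap"))),
           extra)
  jsonlite::write_json(log, file.path(out_dir, paste0(subcommand, "_runlog.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(log)
}

#' Run one pipeline stage from a configuration
#'
#' Thin command surface over the package functions. Each subcommand reads its
#' inputs, runs the corresponding stage, writes its artifacts into `out_dir`,
#' and drops a JSON run log (inputs, parameters, seed, config hash, package
#' version).
#'
#' Subcommands: `lifetime` (compartment design report), `simulate`
#' (synthetic scene + truth tables; `config$simulate$what` one of `arrivals`,
#' `tracks`, `nucleoid`, `decay`), `detect`, `track`, `msd`, `arrivals`
#' (detect, cluster, waiting-time CDF fit), `decay` (normalize + fit),
#' `segment`, `areas` (per-frame segmentation, overlap linking, summed-area
#' series), `coloc` (segment + blobs + spots + matching), `doseresponse`,
#' `compare`.
#'
#' @param subcommand One of the stage names above.
#' @param config Configuration list or YAML path (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The stage's main result, invisibly.
#' @export
run_pipeline <- function(subcommand, config, out_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) stop("run_pipeline: invalid config", call. = FALSE)
  config$seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(
    subcommand,
    lifetime = pipeline_lifetime(config, out_dir),
    simulate = pipeline_simulate(config, out_dir),
    detect = pipeline_detect(config, out_dir),
    track = pipeline_track(config, out_dir),
    msd = pipeline_msd(config, out_dir),
    arrivals = pipeline_arrivals(config, out_dir),
    decay = pipeline_decay(config, out_dir),
    segment = pipeline_segment(config, out_dir),
    areas = pipeline_areas(config, out_dir),
    coloc = pipeline_coloc(config, out_dir),
    doseresponse = pipeline_doseresponse(config, out_dir),
    compare = pipeline_compare(config, out_dir),
    stop("run_pipeline: unknown subcommand '", subcommand,
         "' (see ?run_pipeline for the list)", call. = FALSE)
  )
  write_run_log(out_dir, subcommand, config,
                extra = list(parameters = config[[subcommand]] %||% list()))
  invisible(res)
}

pipeline_lifetime <- function(cfg, out_dir) {
  g <- cfg$geometry
  if (is.null(g)) stop("lifetime: config needs a 'geometry' block", call. = FALSE)
  geom <- compartment_geometry(g$radius_um, g$capillary_length_um,
                               g$capillary_width_um,
                               g$chamber_height_um %||% 1.5,
                               g$constriction_height_um %||% 0.4)
  Ds <- unlist(cfg$diffusion_um2_per_s)
  rep <- do.call(rbind, lapply(Ds, function(D) lifetime_report(geom, D)))
  utils::write.csv(rep, file.path(out_dir, "lifetime.csv"), row.names = FALSE)
  rep
}

pipeline_simulate <- function(cfg, out_dir) {
  sc <- cfg$simulate %||% list()
  what <- sc$what %||% "arrivals"
  cam <- do.call(camera_model, cfg$camera %||% list())
  if (what == "arrivals") {
    truth <- simulate_arrivals(sc$rate_per_min %||% 0.67,
                               sc$duration_min %||% 60,
                               sc$bleach_tau_s %||% 30,
                               unlist(sc$capture_area %||% c(10.24, 10.24)),
                               seed = cfg$seed,
                               blink_prob = sc$blink_prob %||% 0.1)
    stack <- render_frames(truth, cam, seed = cfg$seed)
    write_stack(stack, file.path(out_dir, "stack.tif"))
    utils::write.csv(truth$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    truth
  } else if (what == "tracks") {
    geom <- if (!is.null(cfg$geometry))
      do.call(compartment_geometry, cfg$geometry) else NULL
    truth <- simulate_brownian_tracks(sc$diffusion_um2_per_s %||% 1.7, geom,
                                      sc$n_particles %||% 1,
                                      sc$n_frames %||% 100,
                                      cam$frame_interval_s, seed = cfg$seed)
    utils::write.csv(truth$tracks, file.path(out_dir, "tracks.csv"),
                     row.names = FALSE)
    truth
  } else if (what == "nucleoid") {
    truth <- simulate_nucleoid_population(
      sc$n_chromosomes %||% 10, sc$area_um2_mean %||% 20,
      sc$area_um2_cv %||% 0.2,
      unlist(sc$n_subblobs_range %||% c(3, 7)),
      unlist(sc$mukb_spot_count_range %||% c(2, 9)),
      sc$colocalized_fraction %||% 0.9, seed = cfg$seed,
      pixel_size_um = cam$pixel_size_um)
    stack <- render_frames(truth, cam, seed = cfg$seed)
    write_stack(stack, file.path(out_dir, "stack.tif"))
    utils::write.csv(truth$regions, file.path(out_dir, "regions.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$spots, file.path(out_dir, "spots.csv"),
                     row.names = FALSE)
    truth
  } else if (what == "decay") {
    truth <- simulate_decay_trace(sc$tau_s %||% 413.4, sc$immobile_fraction %||% 0.27,
                                  sc$noise_sd %||% 0.02, sc$frame_interval_s %||% 5,
                                  sc$duration_s %||% 1500, seed = cfg$seed,
                                  n_traces = sc$n_traces %||% 4)
    utils::write.csv(cbind(t_s = truth$t_s, as.data.frame(truth$intensity)),
                     file.path(out_dir, "decay_traces.csv"), row.names = FALSE)
    truth
  } else stop("simulate: unknown 'what' = ", what, call. = FALSE)
}

pipeline_detect <- function(cfg, out_dir) {
  stack <- read_stack(cfg$input %||% file.path(out_dir, "stack.tif"), cfg)
  det <- detect_spots(stack, channel = cfg$detection$channel %||% 1,
                      snr_min = cfg$detection$snr_min %||% 5)
  utils::write.csv(det, file.path(out_dir, "detections.csv"), row.names = FALSE)
  det
}

pipeline_track <- function(cfg, out_dir) {
  det <- utils::read.csv(cfg$input %||% file.path(out_dir, "detections.csv"))
  tr <- link_tracks(det, cfg$linking$max_disp_um %||% 2,
                    cfg$linking$max_gap_frames %||% 1)
  utils::write.csv(tr, file.path(out_dir, "tracks.csv"), row.names = FALSE)
  tr
}

pipeline_msd <- function(cfg, out_dir) {
  tr <- utils::read.csv(cfg$input %||% file.path(out_dir, "tracks.csv"))
  idcol <- if ("track_id" %in% names(tr)) "track_id" else "id"
  dt <- cfg$camera$frame_interval_s %||% 2
  curves <- lapply(split(tr, tr[[idcol]]), function(d)
    if (nrow(d) >= 10) compute_msd(d, dt) else NULL)
  curves <- Filter(Negate(is.null), curves)
  pooled <- pool_msd(curves)
  fit <- fit_diffusion(pooled)
  utils::write.csv(pooled, file.path(out_dir, "msd.csv"), row.names = FALSE)
  jsonlite::write_json(fit, file.path(out_dir, "diffusion.json"),
                       auto_unbox = TRUE, digits = NA)
  fit
}

pipeline_arrivals <- function(cfg, out_dir) {
  stack <- read_stack(cfg$input %||% file.path(out_dir, "stack.tif"), cfg)
  det <- detect_spots(stack, snr_min = cfg$detection$snr_min %||% 5)
  cl <- cfg$clustering %||% list()
  ev <- cluster_arrivals(det, stack$camera$frame_interval_s,
                         radius_um = cl$radius_um %||% 0.32,
                         max_frame_gap = cl$max_frame_gap %||% 5,
                         min_detections = cl$min_detections %||% 2)
  utils::write.csv(ev, file.path(out_dir, "arrival_events.csv"), row.names = FALSE)
  fit <- fit_arrival_cdf(waiting_times(ev$arrival_time_s), "mono")
  jsonlite::write_json(fit[setdiff(names(fit), "ecdf")],
                       file.path(out_dir, "arrival_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  fit
}

pipeline_decay <- function(cfg, out_dir) {
  df <- utils::read.csv(cfg$input %||% file.path(out_dir, "decay_traces.csv"))
  trace <- normalize_trace(df$t_s, as.matrix(df[, -1, drop = FALSE]),
                           cfg$fitting$background %||% 0)
  fit <- fit_decay(trace)
  jsonlite::write_json(unclass(fit), file.path(out_dir, "decay_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  fit
}

pipeline_segment <- function(cfg, out_dir) {
  stack <- read_stack(cfg$input %||% file.path(out_dir, "stack.tif"), cfg)
  sg <- cfg$segmentation %||% list()
  seg <- segment_chromosomes(stack, smoothing_sigma_um = sg$smoothing_sigma_um %||% 0.16,
                             min_area_um2 = sg$min_area_um2 %||% 1)
  utils::write.csv(seg$regions, file.path(out_dir, "regions.csv"), row.names = FALSE)
  tiff::writeTIFF(seg$labels / max(max(seg$labels), 1),
                  file.path(out_dir, "labels.tif"), bits.per.sample = 16)
  seg
}

pipeline_areas <- function(cfg, out_dir) {
  stack <- read_stack(cfg$input %||% file.path(out_dir, "stack.tif"), cfg)
  sg <- cfg$segmentation %||% list()
  segs <- lapply(seq_len(n_frames(stack)) - 1, function(f)
    segment_chromosomes(get_frame(stack, f), stack$camera$pixel_size_um,
                        min_area_um2 = sg$min_area_um2 %||% 1))
  linked <- link_regions(segs)
  series <- summed_area_series(linked, stack$camera$frame_interval_s,
                               sg$smoothing_sigma_s %||% 3 * stack$camera$frame_interval_s)
  utils::write.csv(linked, file.path(out_dir, "linked_regions.csv"), row.names = FALSE)
  utils::write.csv(series, file.path(out_dir, "area_series.csv"), row.names = FALSE)
  series
}

pipeline_coloc <- function(cfg, out_dir) {
  stack <- read_stack(cfg$input %||% file.path(out_dir, "stack.tif"), cfg)
  dna <- get_frame(stack, 0, 1)
  seg <- segment_chromosomes(dna, stack$camera$pixel_size_um)
  blobs <- detect_blobs(dna, seg)
  spots <- detect_spots(stack, channel = min(2, dim(stack)[4]),
                        snr_min = cfg$detection$snr_min %||% 5)
  res <- colocalize(blobs, spots, cfg$coloc$radius_um %||% 0.32)
  jsonlite::write_json(res[c("n_blobs", "n_matched", "fraction_colocalized",
                             "radius_um")],
                       file.path(out_dir, "coloc.json"), auto_unbox = TRUE,
                       digits = NA)
  res
}

pipeline_doseresponse <- function(cfg, out_dir) {
  df <- utils::read.csv(cfg$input %||% file.path(out_dir, "areas.csv"))
  dr <- dose_response(df$area_um2, df$peg_percent)
  utils::write.csv(dr, file.path(out_dir, "doseresponse.csv"), row.names = FALSE)
  dr
}

pipeline_compare <- function(cfg, out_dir) {
  df <- utils::read.csv(cfg$input %||% file.path(out_dir, "areas.csv"))
  gcol <- cfg$compare$group_column %||% "group"
  groups <- unique(df[[gcol]])
  if (length(groups) != 2)
    stop("compare: input must contain exactly 2 groups", call. = FALSE)
  res <- compare_groups(df$area_um2[df[[gcol]] == groups[1]],
                        df$area_um2[df[[gcol]] == groups[2]])
  jsonlite::write_json(res, file.path(out_dir, "compare.json"),
                       auto_unbox = TRUE, digits = NA)
  res
}
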