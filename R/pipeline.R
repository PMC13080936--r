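# Configuration-driven orchestration of the full pipeline with
# reproducibility metadata.

config_defaults <- function() list(
  input = list(path = NA, axis_order = "TCYX", n_channels = 2L,
               pixel_size_um = 0.13, frame_interval_s = 1),
  output_dir = "livespot_out",
  seed = 1L,
  log_level = "info",
  simulate = list(enabled = FALSE, ki = 0.04, ke = 5, L_total = 2000,
                  n_spots = 80, n_frames = 360, frame_interval_s = 5,
                  fov_y = 512L, fov_x = 512L, psf_sigma_px = 1.3,
                  spot_amplitude = 300, background_level = 100,
                  read_noise_sd = 2, bleach_rate = 0.001,
                  diffusion_coeff_px2s = 0.005, fraction_translating = 1),
  bleach = list(enabled = FALSE, channel = 1L, use_spot_mask = FALSE,
                mask_dilate_px = 8L),
  segment = list(enabled = FALSE, method = "watershed", channel = 1L,
                 intensity_threshold = NA, min_area_px = 50L,
                 min_peak_separation_px = 7L, smooth_sigma = 2,
                 mask_path = NA),
  detect = list(enabled = FALSE, channels = 1L, sigma_px = 1.3,
                threshold = "auto", min_separation_px = 5,
                cluster_multiplier = 4, drop_clusters = FALSE),
  track = list(enabled = FALSE, max_disp_px = 3, memory = 1L,
               min_track_len = 10L, method = "assignment"),
  intensity = list(enabled = FALSE, method = "bg_sub", gap_policy = "skip",
                   disk_radius_px = NA, ring_width_px = 3),
  colocalize = list(enabled = FALSE, channel_a = 1L, channel_b = 2L,
                    d_max_px = 2, min_fraction = 0.5),
  correlate = list(enabled = FALSE, mode = "acf", channel = 2L,
                   max_lag_s = NA, L_eff = NA, g0 = "extrap",
                   n_boot = 0L)
)

# "not set" marker usable from YAML (~ or .na) and R (NULL or NA)
unset <- function(x) is.null(x) || (length(x) == 1 && is.na(x))

merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(defaults))
      stop("unknown configuration key: '", full, "'")
    d <- defaults[[k]]
    if (is.list(d) && !is.null(names(d))) {
      if (!is.list(user[[k]]))
        stop("configuration key '", full, "' must be a block")
      defaults[[k]] <- merge_config(d, user[[k]], full)
    } else {
      v <- user[[k]]
      defaults[[k]] <- if (is.null(v)) NA else v
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills defaults, rejects
#' unknown keys (naming the offender), and enforces cross-field constraints.
#' Every value ends up echoed into the run metadata by [run_pipeline()].
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_config(config_defaults(), config)
  if (!cfg$simulate$enabled && unset(cfg$input$path))
    stop("configuration needs input.path unless the simulate stage is enabled")
  if (!unset(cfg$intensity$disk_radius_px) &&
      cfg$intensity$disk_radius_px <= 0)
    stop("intensity.disk_radius_px must be > 0")
  if (cfg$intensity$ring_width_px <= 0)
    stop("intensity.ring_width_px must be > 0")
  if (cfg$detect$cluster_multiplier <= 1)
    stop("detect.cluster_multiplier must be > 1")
  if (!identical(cfg$detect$threshold, "auto") &&
      !is.numeric(cfg$detect$threshold))
    stop("detect.threshold must be a number or \"auto\"")
  if (cfg$correlate$enabled && cfg$correlate$mode == "acf" &&
      unset(cfg$correlate$L_eff))
    stop("correlate.L_eff (codons) is required for kinetic rate extraction")
  structure(cfg, class = "pipeline_config")
}

#' Serialize a pipeline configuration to YAML
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

log_msg <- function(level, stage, ...) {
  message(sprintf("[%s] %s: %s", level, stage, paste0(...)))
}

#' Run the full pipeline from a configuration
#'
#' Executes the enabled stages in order simulate/load -> segment -> detect
#' (on the raw movie) -> bleach (fit + correction; the corrected movie feeds
#' intensity extraction) -> track -> intensity -> colocalize -> correlate,
#' writing every
#' stage's outputs (TIFF/CSV/JSON) and a `metadata.json` capturing every
#' parameter, the package version and the seed, so identical config + seed
#' reproduce identical outputs.
#'
#' @param config A `pipeline_config`, a list, or a YAML path.
#' @param output_dir Overrides the configured output directory.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out <- output_dir %||% cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  meta <- run_metadata(random_seed = cfg$seed)
  meta <- meta_add(meta, "run", list(seed = cfg$seed,
                                     log_level = cfg$log_level))
  stage <- "init"
  result <- try({
    movie <- NULL
    truth <- NULL
    if (cfg$simulate$enabled) {
      stage <- "simulate"
      s <- cfg$simulate
      params <- simulation_params(
        ki = s$ki, ke = s$ke, L_total = s$L_total, n_spots = s$n_spots,
        n_frames = s$n_frames, frame_interval_s = s$frame_interval_s,
        fov_yx = c(s$fov_y, s$fov_x), psf_sigma_px = s$psf_sigma_px,
        spot_amplitude = s$spot_amplitude,
        background_level = s$background_level,
        read_noise_sd = s$read_noise_sd, bleach_rate = s$bleach_rate,
        diffusion_coeff_px2s = s$diffusion_coeff_px2s,
        fraction_translating = s$fraction_translating, seed = cfg$seed)
      log_msg(cfg$log_level, stage, "rendering ", s$n_frames, " frames")
      sim <- simulate_movie(params)
      movie <- sim$movie
      truth <- sim$truth
      save_movie(movie, file.path(out, "movie.tif"))
      write.csv(truth, file.path(out, "truth.csv"), row.names = FALSE,
                na = "")
      meta <- meta_add(meta, "simulate",
                       params[setdiff(names(params), "probe_positions")])
      meta <- meta_add(meta, "simulate",
                       list(probe_positions = params$probe_positions))
    } else {
      stage <- "load"
      if (!file.exists(cfg$input$path))
        stop("input movie not found: ", cfg$input$path)
      movie <- load_movie(cfg$input$path,
                          axis_order = cfg$input$axis_order,
                          n_channels = cfg$input$n_channels,
                          pixel_size_um = cfg$input$pixel_size_um,
                          frame_interval_s = cfg$input$frame_interval_s)
      meta <- meta_add(meta, "load", cfg$input)
    }

    mask <- NULL
    if (cfg$segment$enabled) {
      stage <- "segment"
      sg <- cfg$segment
      if (sg$method == "import") {
        mask <- import_mask(sg$mask_path, dim(movie$data)[3:4])
      } else {
        ref <- get_plane(movie, 1, sg$channel)
        thr <- if (unset(sg$intensity_threshold))
          as.numeric(quantile(ref, 0.9)) else sg$intensity_threshold
        mask <- watershed_segment(ref, thr, sg$min_area_px,
                                  sg$min_peak_separation_px, sg$smooth_sigma)
      }
      export_mask(mask, file.path(out, "mask.tif"))
      meta <- meta_add(meta, "segment", list(
        method = sg$method, n_cells = n_cells(mask)))
    }

    # Detection runs on the raw movie: a single global LoG threshold
    # assumes stationary noise, and bleach rescaling (exp(+kb t)) amplifies
    # late-frame noise across any fixed threshold. The bleach-corrected
    # movie is used downstream for intensity extraction.
    spots <- NULL
    if (cfg$detect$enabled) {
      stage <- "detect"
      d <- cfg$detect
      parts <- lapply(d$channels, function(ch)
        detect_movie(movie, channel = ch, sigma_px = d$sigma_px,
                     threshold = d$threshold,
                     min_separation_px = d$min_separation_px,
                     cluster_multiplier = d$cluster_multiplier,
                     drop_clusters = d$drop_clusters))
      thresholds <- vapply(parts, attr, numeric(1), which = "threshold")
      spots <- do.call(rbind, parts)
      if (!is.null(mask)) spots <- assign_spots_to_cells(spots, mask)
      meta <- meta_add(meta, "detect", list(
        sigma = d$sigma_px, threshold = thresholds,
        channel = d$channels, min_separation_px = d$min_separation_px,
        cluster_multiplier = d$cluster_multiplier))
    }

    if (cfg$bleach$enabled) {
      stage <- "bleach"
      b <- cfg$bleach
      bmask <- NULL
      if (b$use_spot_mask) {
        bmask <- spot_region_mask(movie, b$channel,
                                  sigma_px = cfg$detect$sigma_px,
                                  dilate_px = b$mask_dilate_px)
      } else if (!is.null(mask)) {
        bmask <- mask_plane(mask, 1)
      }
      model <- fit_bleach(movie, channel = b$channel, mask = bmask)
      movie <- correct_bleach(movie, model, channel = b$channel)
      save_movie(movie, file.path(out, "movie_corrected.tif"))
      meta <- meta_add(meta, "bleach", list(
        channel = b$channel, kb = model$kb, amplitude = model$amplitude,
        offset = model$offset, fit_r2 = model$fit_r2,
        clipped_px = attr(movie, "clipped_px")))
    }

    if (cfg$track$enabled && !is.null(spots)) {
      stage <- "track"
      tr <- cfg$track
      spots <- link_multichannel(spots, list(
        max_disp_px = tr$max_disp_px, memory = tr$memory,
        min_track_len = tr$min_track_len, method = tr$method))
      meta <- meta_add(meta, "track", tr[names(tr) != "enabled"])
    }

    if (!is.null(spots)) {
      stage <- "export-spots"
      sp <- spots
      if (!"track_id" %in% names(sp)) sp$track_id <- NA_integer_
      sp$intensity_total <- NA_real_
      sp$intensity_bg_sub <- NA_real_
      sp$snr <- NA_real_
      for (i in seq_len(nrow(sp))) {
        m <- try(measure_spot(get_plane(movie, sp$frame[i], sp$channel[i]),
                              sp$y_px[i], sp$x_px[i],
                              disk_radius_px = ceiling(2.5 * cfg$detect$sigma_px)),
                 silent = TRUE)
        if (!inherits(m, "try-error")) {
          sp$intensity_total[i] <- m$total
          sp$intensity_bg_sub[i] <- m$bg_sub
          sp$snr[i] <- m$snr
        }
      }
      export_table(sp[, intersect(table_schemas$spots, names(sp))],
                   file.path(out, "spots.csv"), schema = "spots")
    }

    traces <- NULL
    if (cfg$intensity$enabled && !is.null(spots)) {
      stage <- "intensity"
      it <- cfg$intensity
      traces <- extract_traces(movie, spots, method = it$method,
                               gap_policy = it$gap_policy,
                               disk_radius_px = if (unset(it$disk_radius_px))
                                 NULL else it$disk_radius_px,
                               sigma_px = cfg$detect$sigma_px,
                               ring_width_px = it$ring_width_px)
      export_table(as.data.frame(traces), file.path(out, "traces.csv"),
                   schema = "traces")
      meta <- meta_add(meta, "intensity", it[names(it) != "enabled"])
    }

    if (cfg$colocalize$enabled && !is.null(spots) &&
        "track_id" %in% names(spots)) {
      stage <- "colocalize"
      cl <- cfg$colocalize
      pairs <- colocalize_tracks(
        spots[spots$channel == cl$channel_a, ],
        spots[spots$channel == cl$channel_b, ],
        d_max_px = cl$d_max_px, min_fraction = cl$min_fraction)
      coloc <- data.frame(frame = NA_integer_, id_a = pairs$id_a,
                          id_b = pairs$id_b,
                          distance_px = pairs$mean_distance_px,
                          fraction = pairs$colocalized_fraction,
                          method = "distance")
      export_table(coloc, file.path(out, "coloc.csv"), schema = "coloc")
      meta <- meta_add(meta, "colocalize", cl[names(cl) != "enabled"])
    }

    if (cfg$correlate$enabled && !is.null(traces)) {
      stage <- "correlate"
      co <- cfg$correlate
      tsub <- traces[traces$channel == co$channel, ]
      if (co$mode == "acf") {
        kin <- translation_kinetics(tsub, L_eff = co$L_eff,
                                    max_lag_s = if (unset(co$max_lag_s))
                                      NULL else co$max_lag_s,
                                    g0_choice = co$g0, n_boot = co$n_boot,
                                    seed = cfg$seed)
        export_table(as.data.frame(kin$correlation),
                     file.path(out, "correlation.csv"),
                     schema = "correlation")
        jsonlite::write_json(
          list(tau_c_s = kin$estimates$tau_c_s, ke = kin$estimates$ke,
               ki = kin$estimates$ki, g0 = kin$estimates$g0,
               L_eff = kin$estimates$L_eff, ci = kin$ci),
          file.path(out, "kinetics.json"), auto_unbox = TRUE, digits = NA,
          null = "null")
        meta <- meta_add(meta, "correlate", list(
          mode = co$mode, L_eff = co$L_eff, g0_choice = co$g0,
          tau_c_s = kin$estimates$tau_c_s, ki = kin$estimates$ki,
          ke = kin$estimates$ke))
      }
    }
    TRUE
  }, silent = TRUE)
  if (inherits(result, "try-error")) {
    writeLines(c(stage, attr(result, "condition")$message),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(result, "condition")$message)
  }
  export_metadata(meta, file.path(out, "metadata.json"))
  invisible(out)
}

#' Build a spot-region mask for photobleach fitting
#'
#' Detects spots on a sample of frames spread across the movie and dilates
#' the pooled positions into disks, so the bleach model is fitted where there
#' is signal instead of being diluted over empty background. Pooling several
#' frames keeps slowly diffusing spots inside the mask for the whole movie;
#' a mask built from a single frame would leak wandering spots and inflate
#' the apparent decay rate.
#'
#' @param movie A [movie_stack()].
#' @param channel Channel index.
#' @param sigma_px Spot sigma for detection.
#' @param dilate_px Disk radius around each detected spot.
#' @param sample_frames Number of frames pooled.
#' @return Binary integer matrix `(Y, X)` (1 inside spot regions).
#' @export
spot_region_mask <- function(movie, channel = 1L, sigma_px = 1.3,
                             dilate_px = 8L, sample_frames = 5L) {
  idx <- unique(round(seq(1, n_frames(movie),
                          length.out = min(sample_frames, n_frames(movie)))))
  planes <- lapply(idx, function(t) get_plane(movie, t, channel))
  thr <- as.numeric(auto_threshold(planes, sigma_px))
  spots <- do.call(rbind, lapply(planes, detect_spots, sigma_px = sigma_px,
                                 threshold = thr))
  m <- matrix(0L, dim(movie$data)[3], dim(movie$data)[4])
  if (nrow(spots) == 0) return(m + 1L)    # fall back to the whole frame
  dd <- (-dilate_px):dilate_px
  disk <- expand.grid(dy = dd, dx = dd)
  disk <- disk[disk$dy^2 + disk$dx^2 <= dilate_px^2, ]
  for (i in seq_len(nrow(spots))) {
    py <- round(spots$y_px[i]) + disk$dy
    px <- round(spots$x_px[i]) + disk$dx
    ok <- py >= 1 & py <= nrow(m) & px >= 1 & px <= ncol(m)
    m[cbind(py[ok], px[ok])] <- 1L
  }
  m
}
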