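# Movie container and TIFF/CSV/metadata I/O shared by all pipeline stages.

#' Construct a movie stack
#'
#' A `movie_stack` is the canonical in-memory representation of a time-lapse
#' fluorescence movie: a dense `(T, C, Y, X)` array of 16-bit unsigned counts
#' together with its physical calibration. Single-channel or single-frame
#' movies still carry all four axes.
#'
#' @param data Numeric or integer array with dimensions `(T, C, Y, X)`.
#'   Values are rounded and clipped into `[0, 65535]`.
#' @param pixel_size_um Pixel size in microns (> 0).
#' @param frame_interval_s Time between consecutive frames in seconds (> 0).
#'   Frame `t` (1-based) is acquired at `(t - 1) * frame_interval_s`.
#' @param channel_names Optional character vector of channel labels; defaults
#'   to `"ch1"`, `"ch2"`, ...
#'
#' @return An object of class `movie_stack` with elements `data`,
#'   `pixel_size_um`, `frame_interval_s`, `channel_names`.
#' @examples
#' m <- movie_stack(array(0L, c(3, 1, 8, 8)), 0.13, 5)
#' dim(m$data)
#' @export
movie_stack <- function(data, pixel_size_um = 0.13, frame_interval_s = 1,
                        channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-axis (T, C, Y, X) array")
  if (any(dim(data) < 1L)) stop("all movie axes must have length >= 1")
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0,
            is.numeric(frame_interval_s), frame_interval_s > 0)
  if (anyNA(data)) stop("movie data must not contain missing values")
  if (!is.integer(data)) {
    data <- array(as.integer(pmin(pmax(round(data), 0), 65535)), dim(data))
  } else if (min(data) < 0L || max(data) > 65535L) {
    data <- array(pmin(pmax(data, 0L), 65535L), dim(data))
  }
  nc <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("`channel_names` must have one entry per channel")
  structure(list(data = data,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_names = as.character(channel_names)),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d frame(s) x %d channel(s) x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size %.4g um, frame interval %.4g s, channels: %s\n",
              x$pixel_size_um, x$frame_interval_s,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Movie dimensions and time base
#'
#' @param movie A [movie_stack()].
#' @return `n_frames()`/`n_channels()` return integers; `frame_times()`
#'   returns the acquisition time in seconds of every frame (frame 1 at 0 s).
#' @export
n_frames <- function(movie) dim(movie$data)[1]

#' @rdname n_frames
#' @export
n_channels <- function(movie) dim(movie$data)[2]

#' @rdname n_frames
#' @export
frame_times <- function(movie)
  (seq_len(n_frames(movie)) - 1) * movie$frame_interval_s

#' Extract a single (Y, X) plane from an in-memory movie
#'
#' @param movie A [movie_stack()].
#' @param t Frame index (1-based).
#' @param c Channel index (1-based).
#' @return Integer matrix `(Y, X)`.
#' @export
get_plane <- function(movie, t, c) {
  d <- dim(movie$data)
  if (t < 1 || t > d[1]) stop("frame index out of range")
  if (c < 1 || c > d[2]) stop("channel index out of range")
  matrix(movie$data[t, c, , ], d[3], d[4])
}

#' Write a movie stack to a multi-page TIFF
#'
#' Pages are written 16-bit unsigned, uncompressed, in `(T, C)`-major order:
#' all channels of frame 1, then all channels of frame 2, and so on
#' (`axis_order = "TCYX"` flattened row-major).
#'
#' @param movie A [movie_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_movie <- function(movie, path) {
  d <- dim(movie$data)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[k]] <- matrix(movie$data[t, c, , ], d[3], d[4]) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

read_tiff_pages <- function(path, pages = TRUE) {
  if (grepl("\\.lif$", path, ignore.case = TRUE))
    stop("LIF files are not supported; convert the acquisition to ",
         "multi-page TIFF first and load the TIFF")
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tiff::readTIFF(path, all = pages, as.is = TRUE)
  if (!is.list(out)) out <- list(out)
  out
}

check_pixel_values <- function(pages, rescale) {
  rng <- range(vapply(pages, range, numeric(2)))
  integral <- all(vapply(pages, function(p) all(p == round(p)), logical(1)))
  if (!integral || rng[1] < 0 || rng[2] > 65535) {
    if (!rescale)
      stop("pixel values outside unsigned 16-bit range (observed [",
           signif(rng[1], 6), ", ", signif(rng[2], 6),
           "]); pass rescale = TRUE to map the observed range onto [0, 65535]")
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    pages <- lapply(pages, function(p) round((p - rng[1]) / span * 65535))
  }
  pages
}

#' Load a movie from a multi-page TIFF
#'
#' The TIFF page sequence is interpreted according to `axis_order` and
#' returned in canonical `(T, C, Y, X)` order. Physical calibration is never
#' read from TIFF tags (tag dialects are unreliable); it must be given
#' explicitly or via a pipeline configuration.
#'
#' @param path Path to a multi-page TIFF.
#' @param axis_order One of `"TCYX"` (pages = frames x channels, frame-major),
#'   `"CTYX"` (channel-major pages) or `"TYXC"` (one multi-sample page per
#'   frame, channels within the page).
#' @param n_channels Number of channels `C` (required for `"TCYX"`/`"CTYX"`
#'   when > 1; inferred from the page for `"TYXC"`).
#' @param pixel_size_um,frame_interval_s,channel_names Calibration, passed to
#'   [movie_stack()].
#' @param rescale If `TRUE`, out-of-range (e.g. 32-bit float) data are
#'   linearly rescaled into `[0, 65535]`; otherwise such files are rejected.
#' @return A [movie_stack()].
#' @export
load_movie <- function(path, axis_order = c("TCYX", "TYXC", "CTYX"),
                       n_channels = 1L, pixel_size_um = 0.13,
                       frame_interval_s = 1, channel_names = NULL,
                       rescale = FALSE) {
  axis_order <- match.arg(axis_order)
  pages <- check_pixel_values(read_tiff_pages(path), rescale)
  np <- length(pages)
  dims <- dim(pages[[1]])
  if (axis_order == "TYXC") {
    nc <- if (length(dims) == 3L) dims[3] else 1L
    nt <- np
    data <- array(0L, c(nt, nc, dims[1], dims[2]))
    for (t in seq_len(nt)) {
      pg <- pages[[t]]
      if (nc == 1L && length(dim(pg)) == 2L) dim(pg) <- c(dim(pg), 1L)
      for (c in seq_len(nc)) data[t, c, , ] <- pg[, , c]
    }
  } else {
    nc <- as.integer(n_channels)
    if (np %% nc != 0L)
      stop("page count ", np, " is not a multiple of n_channels = ", nc)
    nt <- np %/% nc
    data <- array(0L, c(nt, nc, dims[1], dims[2]))
    for (k in seq_len(np)) {
      if (axis_order == "TCYX") {
        t <- (k - 1L) %/% nc + 1L; c <- (k - 1L) %% nc + 1L
      } else {                            # CTYX: channel-major
        c <- (k - 1L) %/% nt + 1L; t <- (k - 1L) %% nt + 1L
      }
      data[t, c, , ] <- pages[[k]]
    }
  }
  movie_stack(data, pixel_size_um = pixel_size_um,
              frame_interval_s = frame_interval_s,
              channel_names = channel_names)
}

#' Open a movie for lazy frame access
#'
#' Returns a lightweight handle holding only the file path and axis geometry;
#' [get_frame()] then reads single TIFF pages on demand, so arbitrarily long
#' movies can be processed without materializing the full stack in memory.
#'
#' @inheritParams load_movie
#' @return An object of class `movie_ref` with fields `path`, `axis_order`,
#'   `n_frames`, `n_channels`, `dim_yx`.
#' @export
open_movie <- function(path, axis_order = c("TCYX", "TYXC", "CTYX"),
                       n_channels = 1L) {
  axis_order <- match.arg(axis_order)
  if (!file.exists(path)) stop("file not found: ", path)
  info <- tiff::readTIFF(path, all = TRUE, payload = FALSE)
  np <- nrow(info)
  if (axis_order == "TYXC") {
    nc <- as.integer(info$samples.per.pixel[1])
    nt <- np
  } else {
    nc <- as.integer(n_channels)
    if (np %% nc != 0L)
      stop("page count ", np, " is not a multiple of n_channels = ", nc)
    nt <- np %/% nc
  }
  structure(list(path = path, axis_order = axis_order,
                 n_frames = nt, n_channels = nc,
                 dim_yx = c(info$length[1], info$width[1])),
            class = "movie_ref")
}

#' Read one 2D plane of an on-disk movie
#'
#' Only the requested TIFF page is read; the rest of the file stays on disk.
#' The returned plane is identical to `get_plane(load_movie(path, ...), t, c)`.
#'
#' @param movie_ref Handle from [open_movie()].
#' @param t Frame index (1-based).
#' @param c Channel index (1-based).
#' @return Integer matrix `(Y, X)`.
#' @export
get_frame <- function(movie_ref, t, c = 1L) {
  stopifnot(inherits(movie_ref, "movie_ref"))
  if (t < 1 || t > movie_ref$n_frames) stop("frame index out of range")
  if (c < 1 || c > movie_ref$n_channels) stop("channel index out of range")
  nt <- movie_ref$n_frames; nc <- movie_ref$n_channels
  page <- switch(movie_ref$axis_order,
                 TCYX = (t - 1L) * nc + c,
                 CTYX = (c - 1L) * nt + t,
                 TYXC = t)
  pg <- read_tiff_pages(movie_ref$path, pages = as.integer(page))[[1]]
  if (movie_ref$axis_order == "TYXC" && length(dim(pg)) == 3L)
    pg <- pg[, , c]
  storage.mode(pg) <- "integer"
  pg
}

# ---- tabular exports --------------------------------------------------------

table_schemas <- list(
  spots = c("frame", "channel", "track_id", "y_px", "x_px", "cell_label",
            "is_cluster", "intensity_total", "intensity_bg_sub",
            "gauss_amplitude", "gauss_sigma_px", "gauss_offset", "snr"),
  traces = c("track_id", "channel", "frame", "time_s", "method", "intensity"),
  correlation = c("lag_s", "G", "sem", "n_pairs"),
  coloc = c("frame", "id_a", "id_b", "distance_px", "fraction", "method")
)

#' Export a stage output table as CSV
#'
#' Writes RFC-4180 CSV with the exact canonical header for the given schema.
#' Missing values (e.g. the intensity at an unresolved gap frame) are written
#' as empty fields, never as 0. Columns absent from `records` are filled with
#' missing values; unknown columns are an error.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param schema One of `"spots"`, `"traces"`, `"correlation"`, `"coloc"`, or
#'   `NULL` to write the columns as they are.
#' @return `path`, invisibly.
#' @export
export_table <- function(records, path, schema = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(schema)) {
    schema <- match.arg(schema, names(table_schemas))
    cols <- table_schemas[[schema]]
    unknown <- setdiff(names(records), cols)
    if (length(unknown))
      stop("unknown column(s) for schema '", schema, "': ",
           paste(unknown, collapse = ", "))
    for (missing_col in setdiff(cols, names(records)))
      records[[missing_col]] <- rep(NA, nrow(records))
    records <- records[, cols, drop = FALSE]
  }
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a CSV written by [export_table()]
#'
#' @param path CSV path.
#' @return A data frame with empty fields restored as `NA`.
#' @export
read_table_csv <- function(path) {
  read.csv(path, na.strings = "", stringsAsFactors = FALSE)
}

# ---- run metadata -----------------------------------------------------------

#' Reproducibility metadata for a pipeline run
#'
#' A `run_metadata` object accumulates every parameter and threshold used by
#' each stage of a run, plus the package version, the random seed, and
#' start/end timestamps, and serializes losslessly to JSON so that a run can
#' be reconstructed exactly.
#'
#' @param random_seed Optional integer seed recorded for the run.
#' @return An object of class `run_metadata`.
#' @export
run_metadata <- function(random_seed = NULL) {
  structure(list(parameters = list(),
                 software_version = as.character(packageVersion("livespot")),
                 random_seed = random_seed,
                 timestamps = list(
                   start = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   end = NULL)),
            class = "run_metadata")
}

#' Record a stage's parameters into run metadata
#'
#' Keys are stored flat as `"<stage>.<name>"`. Every pipeline stage that runs
#' must contribute at least one key.
#'
#' @param meta A [run_metadata()] object.
#' @param stage Stage name, e.g. `"detect"`.
#' @param params Named list of scalar parameters.
#' @return The updated `run_metadata`.
#' @export
meta_add <- function(meta, stage, params) {
  stopifnot(inherits(meta, "run_metadata"), is.list(params),
            !is.null(names(params)), all(nzchar(names(params))))
  for (k in names(params)) {
    v <- params[[k]]
    if (length(v) > 1) v <- paste(v, collapse = ",")
    meta$parameters[[paste0(stage, ".", k)]] <- v
  }
  meta
}

#' Close out and write run metadata as JSON
#'
#' @param meta A [run_metadata()] object.
#' @param path Output path (conventionally `metadata.json`).
#' @return `path`, invisibly.
#' @export
export_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "run_metadata"))
  if (length(meta$parameters) == 0)
    stop("metadata has no recorded parameters; add at least one stage")
  meta$timestamps$end <- meta$timestamps$end %||%
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(unclass(meta), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Reload run metadata written by [export_metadata()]
#'
#' @param path JSON path.
#' @return A `run_metadata` object equal (up to the recorded end timestamp)
#'   to the exported one.
#' @export
read_metadata <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$parameters <- lapply(x$parameters, function(v) v)
  structure(x, class = "run_metadata")
}
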