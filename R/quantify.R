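# Spot intensity quantification: disk photometry with ring background,
# 2D Gaussian fitting, and per-track intensity traces.

#' Disk photometry with ring background at one position
#'
#' Sums pixels whose centres lie within `disk_radius_px` of `(y, x)`;
#' the background per pixel is the median of the ring
#' `ring_inner_px < d <= ring_outer_px` (median, not mean, so a neighbouring
#' spot in the ring does not corrupt the estimate). SNR is the background-
#' subtracted peak over the ring standard deviation. If the window extends
#' beyond the image it is measured on the clipped region and flagged.
#'
#' @param image 2D numeric matrix.
#' @param y,x Position in pixel-centre coordinates.
#' @param disk_radius_px Photometry disk radius.
#' @param ring_inner_px,ring_outer_px Background ring radii
#'   (`ring_outer > ring_inner >= disk_radius`).
#' @return List: `total`, `bg_sub` (`total - median_bg * disk_area`), `snr`,
#'   `background` (per-pixel), `n_disk_px`, `clipped` (window off image).
#' @export
measure_spot <- function(image, y, x, disk_radius_px = 4,
                         ring_inner_px = disk_radius_px,
                         ring_outer_px = ring_inner_px + 3) {
  stopifnot(is.matrix(image), ring_outer_px > ring_inner_px,
            ring_inner_px >= disk_radius_px, disk_radius_px > 0)
  r <- ceiling(ring_outer_px)
  ys <- floor(y - r):ceiling(y + r)
  xs <- floor(x - r):ceiling(x + r)
  clipped <- any(ys < 1 | ys > nrow(image)) || any(xs < 1 | xs > ncol(image))
  ys <- ys[ys >= 1 & ys <= nrow(image)]
  xs <- xs[xs >= 1 & xs <= ncol(image)]
  sub <- image[ys, xs, drop = FALSE]
  d <- sqrt(outer((ys - y)^2, (xs - x)^2, "+"))
  disk <- d <= disk_radius_px
  ring <- d > ring_inner_px & d <= ring_outer_px
  if (!any(disk) || sum(ring) < 2)
    stop("photometry window contains no usable disk/ring pixels")
  total <- sum(sub[disk])
  bg <- median(sub[ring])
  ring_sd <- sd(sub[ring])
  list(total = total,
       bg_sub = total - bg * sum(disk),
       snr = if (ring_sd > 0) (max(sub[disk]) - bg) / ring_sd else Inf,
       background = bg, n_disk_px = sum(disk), clipped = clipped)
}

#' Fit a symmetric 2D Gaussian to an image patch
#'
#' Least-squares fit of `A * exp(-((y - y0)^2 + (x - x0)^2) / (2 sigma^2)) + c`
#' (Levenberg-Marquardt), initialized from border-median background and
#' moment estimates. Non-convergence, or a sigma escaping
#' `(0.3, min(dim(patch)) / 2)`, is reported via `converged = FALSE`, never
#' as an error.
#'
#' @param patch 2D numeric matrix, at least 7 x 7.
#' @param init Optional named list overriding the initial values
#'   (`amplitude`, `sigma_px`, `offset`, `y0`, `x0`).
#' @return Object of class `gauss_fit`: `amplitude`, `sigma_px`, `offset`,
#'   `center` (y, x within the patch), `converged`, `residual_rms`. The
#'   integrated intensity `amplitude * 2 * pi * sigma_px^2` is in
#'   `$integrated`.
#' @export
fit_gaussian2d <- function(patch, init = NULL) {
  stopifnot(is.matrix(patch), nrow(patch) >= 7, ncol(patch) >= 7)
  yy <- as.vector(row(patch)); xx <- as.vector(col(patch))
  v <- as.vector(patch)
  border <- row(patch) == 1 | row(patch) == nrow(patch) |
    col(patch) == 1 | col(patch) == ncol(patch)
  c0 <- median(patch[border])
  a0 <- max(patch) - c0
  w <- pmax(v - c0, 0)
  sigma_hi <- min(dim(patch)) / 2
  if (sum(w) <= 0) {
    return(structure(list(amplitude = 0, sigma_px = NA_real_, offset = c0,
                          center = c(NA_real_, NA_real_), converged = FALSE,
                          residual_rms = sd(v), integrated = 0),
                     class = "gauss_fit"))
  }
  y0 <- sum(w * yy) / sum(w); x0 <- sum(w * xx) / sum(w)
  s0 <- sqrt(max(sum(w * ((yy - y0)^2 + (xx - x0)^2)) / (2 * sum(w)), 0.2))
  start <- list(A = a0, y0 = y0, x0 = x0, s = min(max(s0, 0.4), sigma_hi * 0.9),
                c0 = c0)
  if (!is.null(init))
    start[c("A", "y0", "x0", "s", "c0")] <- list(
      init$amplitude %||% start$A, init$y0 %||% start$y0,
      init$x0 %||% start$x0, init$sigma_px %||% start$s,
      init$offset %||% start$c0)
  fit <- try(minpack.lm::nlsLM(
    v ~ A * exp(-((yy - y0)^2 + (xx - x0)^2) / (2 * s^2)) + c0,
    start = start,
    lower = c(A = 0, y0 = 1, x0 = 1, s = 0.25, c0 = -Inf),
    upper = c(A = Inf, y0 = nrow(patch), x0 = ncol(patch),
              s = sigma_hi * 1.2, c0 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(amplitude = a0, sigma_px = s0, offset = c0,
                          center = c(y0, x0), converged = FALSE,
                          residual_rms = NA_real_,
                          integrated = a0 * 2 * pi * s0^2),
                     class = "gauss_fit"))
  }
  p <- coef(fit)
  converged <- p[["s"]] > 0.3 && p[["s"]] < sigma_hi
  structure(list(amplitude = p[["A"]], sigma_px = p[["s"]],
                 offset = p[["c0"]], center = c(p[["y0"]], p[["x0"]]),
                 converged = converged,
                 residual_rms = sqrt(mean(residuals(fit)^2)),
                 integrated = p[["A"]] * 2 * pi * p[["s"]]^2),
            class = "gauss_fit")
}

#' @export
print.gauss_fit <- function(x, ...) {
  cat(sprintf(
    "gauss_fit: A = %.4g, sigma = %.3g px, offset = %.4g, centre (%.2f, %.2f), %s\n",
    x$amplitude, x$sigma_px, x$offset, x$center[1], x$center[2],
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Extract per-track intensity traces from a movie
#'
#' For every frame of every track, measures the spot intensity at the
#' detected position with the chosen method. At gap frames (bridged by
#' tracking memory, no detection): `gap_policy = "skip"` leaves the value
#' missing, `gap_policy = "interp"` measures at the linearly interpolated
#' position. Run this on a photobleach-corrected movie for kinetic analyses.
#' Negative background-subtracted or fitted values are floored at 0.
#'
#' @param movie A [movie_stack()].
#' @param spots Linked spot table (from [link_spots()] /
#'   [link_multichannel()]) with `frame`, `channel`, `track_id`, `y_px`,
#'   `x_px`.
#' @param method `"bg_sub"` (disk total minus ring-median background,
#'   default), `"total"`, or `"gauss"` (integrated 2D Gaussian fit).
#' @param gap_policy `"skip"` or `"interp"`.
#' @param disk_radius_px Photometry radius; defaults to `ceiling(2.5 *
#'   sigma_px)`.
#' @param sigma_px Spot sigma used for default radii and Gaussian patches.
#' @param ring_width_px Width of the background ring beyond the disk.
#' @return Tidy data frame of class `intensity_traces`: `track_id`,
#'   `channel`, `frame`, `time_s`, `method`, `intensity` (`NA` at skipped
#'   gaps).
#' @export
extract_traces <- function(movie, spots, method = c("bg_sub", "total", "gauss"),
                           gap_policy = c("skip", "interp"),
                           disk_radius_px = NULL, sigma_px = 1.3,
                           ring_width_px = 3) {
  method <- match.arg(method)
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(movie, "movie_stack"),
            all(c("frame", "channel", "track_id", "y_px", "x_px") %in%
                  names(spots)))
  disk_radius_px <- disk_radius_px %||% ceiling(2.5 * sigma_px)
  dt <- movie$frame_interval_s
  rows <- list()
  for (tr in split_tracks(spots)) {
    tr <- tr[order(tr$frame), ]
    id <- tr$track_id[1]; ch <- tr$channel[1]
    frames <- min(tr$frame):max(tr$frame)
    det <- match(frames, tr$frame)
    ys <- tr$y_px[det]; xs <- tr$x_px[det]
    gap <- is.na(det)
    if (any(gap) && gap_policy == "interp") {
      ys <- approx(tr$frame, tr$y_px, xout = frames)$y
      xs <- approx(tr$frame, tr$x_px, xout = frames)$y
    }
    vals <- rep(NA_real_, length(frames))
    for (i in seq_along(frames)) {
      if (is.na(ys[i])) next
      img <- get_plane(movie, frames[i], ch)
      vals[i] <- measure_one(img, ys[i], xs[i], method, disk_radius_px,
                             ring_width_px, sigma_px)
    }
    vals <- pmax(vals, 0)
    rows[[length(rows) + 1]] <- data.frame(
      track_id = id, channel = ch, frame = frames,
      time_s = (frames - 1) * dt, method = method, intensity = vals)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), channel = integer(), frame = integer(),
               time_s = numeric(), method = character(),
               intensity = numeric())
  rownames(out) <- NULL
  class(out) <- c("intensity_traces", "data.frame")
  out
}

measure_one <- function(img, y, x, method, disk_radius_px, ring_width_px,
                        sigma_px) {
  if (method == "gauss") {
    h <- max(3L, ceiling(disk_radius_px + ring_width_px))
    ys <- max(1, round(y) - h):min(nrow(img), round(y) + h)
    xs <- max(1, round(x) - h):min(ncol(img), round(x) + h)
    if (length(ys) < 7 || length(xs) < 7) return(NA_real_)
    f <- fit_gaussian2d(img[ys, xs])
    return(if (f$converged) f$integrated else NA_real_)
  }
  m <- measure_spot(img, y, x, disk_radius_px,
                    ring_inner_px = disk_radius_px,
                    ring_outer_px = disk_radius_px + ring_width_px)
  if (method == "total") m$total else m$bg_sub
}

#' Reshape tidy intensity traces into a frames x tracks matrix
#'
#' @param traces An `intensity_traces` data frame (one method).
#' @return Numeric matrix, rows = frames (union of all track spans, on the
#'   common frame grid), columns = tracks, `NA` where a track is unresolved.
#'   Row times are in `attr(, "time_s")`.
#' @export
traces_matrix <- function(traces) {
  stopifnot(is.data.frame(traces))
  frames <- seq(min(traces$frame), max(traces$frame))
  ids <- unique(traces$track_id)
  m <- matrix(NA_real_, length(frames), length(ids),
              dimnames = list(NULL, ids))
  m[cbind(match(traces$frame, frames), match(traces$track_id, ids))] <-
    traces$intensity
  dt <- if (nrow(traces) > 1) {
    s <- traces[order(traces$frame), ]
    d <- unique(diff(sort(unique(s$time_s))))
    if (length(d)) min(d) else 1
  } else 1
  attr(m, "time_s") <- (frames - frames[1]) * dt
  m
}
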