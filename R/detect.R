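# Spot detection: Laplacian-of-Gaussian filtering, hybrid automated
# threshold selection, non-maximum suppression, subpixel localization,
# and cluster flagging.

#' Laplacian-of-Gaussian kernel
#'
#' Negated, scale-normalized LoG: `(2 - r^2 / sigma^2) * G_sigma(r)`, with the
#' mean subtracted so a constant image gives exactly zero response. Bright
#' blobs of matched scale produce positive peaks.
#'
#' @param sigma_px Kernel scale in pixels (> 0).
#' @return Square numeric matrix of odd size `2 * ceiling(4 * sigma) + 1`.
#' @export
log_kernel <- function(sigma_px) {
  stopifnot(sigma_px > 0)
  r <- ceiling(4 * sigma_px)
  d <- (-r):r
  r2 <- outer(d^2, d^2, "+")
  k <- (2 - r2 / sigma_px^2) * exp(-r2 / (2 * sigma_px^2)) / (2 * pi * sigma_px^2)
  k - mean(k)
}

#' Band-pass filter an image for spot detection
#'
#' Convolves the image with the negated scale-normalized [log_kernel()]
#' (replicated borders). The operator is linear: `log_filter(a * img) ==
#' a * log_filter(img)`.
#'
#' @param image 2D numeric matrix.
#' @param sigma_px Expected spot sigma in pixels.
#' @return Filtered matrix of the same size; bright spots become positive
#'   peaks.
#' @export
log_filter <- function(image, sigma_px) {
  stopifnot(is.matrix(image))
  img <- matrix(as.numeric(image), nrow(image))
  EBImage::filter2(img, log_kernel(sigma_px), boundary = "replicate")
}

# Central response of log_filter to a unit-peak Gaussian spot of the same
# sigma; used to convert peak responses back to approximate amplitudes.
log_gain <- function(sigma_px) {
  r <- ceiling(4 * sigma_px)
  d <- (-r):r
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma_px^2))
  sum(log_kernel(sigma_px) * g)
}

# Local maxima (8-neighbourhood, >= comparison) of a response matrix at or
# above `floor`. Returns integer (y, x) and the response value.
local_maxima <- function(resp, floor) {
  ny <- nrow(resp); nx <- ncol(resp)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- resp
  mx <- resp
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    mx <- pmax(mx, pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)])
  }
  sel <- which(resp >= mx & resp >= floor)
  if (!length(sel)) return(data.frame(y = integer(), x = integer(),
                                      resp = numeric()))
  yy <- (sel - 1) %% ny + 1
  xx <- (sel - 1) %/% ny + 1
  data.frame(y = yy, x = xx, resp = resp[sel])
}

# Greedy non-maximum suppression on integer candidate positions, ordered by
# response (desc), then y, then x. A candidate is suppressed when within
# `min_sep` (Euclidean, strict) of an already kept, stronger candidate.
nms_points <- function(cand, min_sep, dim_yx) {
  if (nrow(cand) == 0) return(cand)
  ord <- order(-cand$resp, cand$y, cand$x)
  cand <- cand[ord, , drop = FALSE]
  if (min_sep <= 0) return(cand)
  occupied <- matrix(FALSE, dim_yx[1], dim_yx[2])
  rr <- ceiling(min_sep - 1e-9)
  dd <- (-rr):rr
  disk <- expand.grid(dy = dd, dx = dd)
  disk <- disk[disk$dy^2 + disk$dx^2 < min_sep^2, ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    y <- cand$y[i]; x <- cand$x[i]
    if (occupied[y, x]) next
    keep[i] <- TRUE
    py <- y + disk$dy; px <- x + disk$dx
    ok <- py >= 1 & py <= dim_yx[1] & px >= 1 & px <= dim_yx[2]
    occupied[cbind(py[ok], px[ok])] <- TRUE
  }
  cand[keep, , drop = FALSE]
}

#' Automated hybrid threshold selection
#'
#' Counts candidate spots `N(theta)` over a geometric grid of 50 thresholds
#' spanning the 50th to 99.99th percentile of the positive filtered response,
#' then combines two classic estimates: (A) the elbow (convex knee) of
#' `log N(theta)` -- the grid point of maximum below-chord distance, where
#' the steep noise fall-off hands over to the signal regime -- and (B) the
#' centre of the widest low-slope plateau of `N(theta)`, where the count is
#' stable against the threshold. The returned
#' threshold is the geometric mean of A and B; both are kept as attributes
#' (and recorded in pipeline metadata).
#'
#' @param images A matrix or list of matrices (sample frames).
#' @param sigma_px Expected spot sigma in pixels.
#' @param min_separation_px Non-maximum suppression radius used when counting.
#' @param n_grid Number of candidate thresholds.
#' @return The selected threshold (numeric scalar) with attributes `elbow`,
#'   `plateau`, `grid` and `counts` (mean spots/frame at each grid value).
#' @export
auto_threshold <- function(images, sigma_px, min_separation_px = 5,
                           n_grid = 50) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1)
  resps <- lapply(images, log_filter, sigma_px = sigma_px)
  # floor relative to the image scale: numerical jitter on flat fields is
  # not a detectable response
  eps <- 1e-10 * max(1e-12, abs(unlist(lapply(images, range))))
  pos <- unlist(lapply(resps, function(r) r[r > eps]))
  if (!length(pos)) stop("no positive filter response; cannot select a ",
                         "threshold automatically, set one manually")
  hi <- as.numeric(quantile(pos, 0.9999))
  lo <- max(as.numeric(quantile(pos, 0.5)), hi * 1e-6)
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  cand_resp <- unlist(lapply(resps, function(r) {
    cand <- local_maxima(r, floor = lo)
    nms_points(cand, min_separation_px, dim(r))$resp
  }))
  counts <- vapply(grid, function(th) sum(cand_resp >= th), numeric(1)) /
    length(images)
  if (all(counts == 0))
    stop("no spots found at any candidate threshold; set one manually")
  valid <- which(counts >= 1 / length(images))
  i0 <- valid[1]; i1 <- valid[length(valid)]
  idx <- i0:i1
  logn <- log(counts[idx])
  # (A) elbow: the convex knee of log N(theta) -- the grid point of maximum
  # distance *below* the chord joining the curve endpoints, on axes
  # normalized to [0, 1]; this is where the steep noise fall-off hands over
  # to the signal regime
  if (length(idx) >= 3 && diff(range(logn)) > 0) {
    xn <- (seq_along(idx) - 1) / (length(idx) - 1)
    yn <- (logn - logn[length(logn)]) / (logn[1] - logn[length(logn)])
    # chord from (0, 1) to (1, 0); below-chord distance ~ (1 - xn - yn)
    elbow <- grid[idx[which.max(1 - xn - yn)]]
  } else {
    elbow <- grid[i0]
  }
  # (B) plateau: widest run where the count changes <= 5% per grid step
  # (ties broken toward lower thresholds). A flat run starting at the very
  # first grid point is ignored when any other exists: the grid starts
  # inside the noise-response distribution, whose top is spuriously flat.
  dl <- abs(diff(logn))
  flat <- dl <= log(1.05)
  plateau <- if (any(flat)) {
    r <- rle(flat)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (length(runs) > 1 && starts[runs[1]] == 1) runs <- runs[-1]
    best <- runs[order(-r$lengths[runs], starts[runs])][1]
    centre <- round((starts[best] + ends[best] + 1) / 2)
    grid[idx[centre]]
  } else {
    grid[idx[which.min(dl)]]
  }
  structure(sqrt(elbow * plateau), elbow = elbow, plateau = plateau,
            grid = grid, counts = counts)
}

# Intensity-weighted centroid refinement in a window of about (4 sigma + 1)
# pixels on the raw image (window minimum subtracted).
refine_centroid <- function(image, y, x, sigma_px) {
  h <- max(1L, round(2 * sigma_px))
  ys <- max(1, y - h):min(nrow(image), y + h)
  xs <- max(1, x - h):min(ncol(image), x + h)
  w <- image[ys, xs, drop = FALSE] - min(image[ys, xs])
  sw <- sum(w)
  if (sw <= 0) return(c(y, x))
  c(sum(rowSums(w) * ys) / sw, sum(colSums(w) * xs) / sw)
}

#' Detect diffraction-limited spots in one frame
#'
#' Spots are local maxima of the [log_filter()] response at or above
#' `threshold`, pruned by non-maximum suppression within
#' `min_separation_px` (ties broken by response, then lower y, then lower x),
#' localized to subpixel precision by an intensity-weighted centroid in a
#' `(4 sigma + 1)`-sized window on the raw image, and measured for footprint
#' (size of the connected above-threshold response component). Spots whose
#' footprint exceeds `cluster_multiplier` times the nominal single-spot
#' footprint are flagged as clusters (see [flag_clusters()]).
#'
#' @param image 2D numeric matrix (one frame, one channel).
#' @param sigma_px Expected spot sigma in pixels.
#' @param threshold Filtered-response cutoff, or `"auto"` for
#'   [auto_threshold()] on this image.
#' @param min_separation_px Minimum distance between detections.
#' @param cluster_multiplier Footprint multiple above which a detection is
#'   flagged as a cluster.
#' @param drop_clusters Remove flagged clusters from the result.
#' @return Spot table: `y_px`, `x_px`, `peak_response`, `footprint_px`,
#'   `is_cluster`, `cell_label` (0 until assigned).
#' @export
detect_spots <- function(image, sigma_px, threshold = "auto",
                         min_separation_px = 5, cluster_multiplier = 4,
                         drop_clusters = FALSE) {
  stopifnot(is.matrix(image), sigma_px > 0, min_separation_px >= 1)
  if (identical(threshold, "auto"))
    threshold <- as.numeric(auto_threshold(image, sigma_px,
                                           min_separation_px))
  resp <- log_filter(image, sigma_px)
  cand <- nms_points(local_maxima(resp, floor = threshold),
                     min_separation_px, dim(resp))
  if (nrow(cand) == 0) {
    return(data.frame(y_px = numeric(), x_px = numeric(),
                      peak_response = numeric(), footprint_px = integer(),
                      is_cluster = logical(), cell_label = integer()))
  }
  lab <- EBImage::bwlabel(resp >= threshold)
  sizes <- tabulate(lab[lab > 0])
  foot <- sizes[lab[cbind(cand$y, cand$x)]]
  centres <- t(vapply(seq_len(nrow(cand)), function(i)
    refine_centroid(image, cand$y[i], cand$x[i], sigma_px), numeric(2)))
  spots <- data.frame(y_px = centres[, 1], x_px = centres[, 2],
                      peak_response = cand$resp,
                      footprint_px = as.integer(foot),
                      is_cluster = FALSE, cell_label = 0L)
  spots <- flag_clusters(spots, sigma_px, threshold, cluster_multiplier)
  if (drop_clusters) spots <- spots[!spots$is_cluster, , drop = FALSE]
  rownames(spots) <- NULL
  spots
}

# Footprint of a noiseless single spot of the given amplitude at the
# declared sigma, measured exactly as in detect_spots.
calibration_footprint <- function(sigma_px, threshold, amplitude) {
  r <- ceiling(6 * sigma_px) + nrow(log_kernel(sigma_px))
  d <- (-r):r
  patch <- amplitude * exp(-outer(d^2, d^2, "+") / (2 * sigma_px^2))
  resp <- log_filter(patch, sigma_px)
  lab <- EBImage::bwlabel(resp >= threshold)
  centre <- lab[r + 1, r + 1]
  if (centre == 0) return(1L)
  sum(lab == centre)
}

#' Flag cluster detections by footprint size
#'
#' A detection is a cluster when its above-threshold footprint exceeds
#' `cluster_multiplier` times the nominal footprint of a single spot at the
#' declared size. The nominal footprint is measured on a noiseless
#' calibration render at `sigma_px` whose amplitude matches the median
#' detected peak response.
#'
#' @param spots Spot table from [detect_spots()] (with `footprint_px`).
#' @param sigma_px Declared spot sigma in pixels.
#' @param threshold The response threshold the footprints were measured at.
#' @param cluster_multiplier Multiplier (> 1).
#' @return `spots` with `is_cluster` updated.
#' @export
flag_clusters <- function(spots, sigma_px, threshold, cluster_multiplier = 4) {
  stopifnot(is.data.frame(spots), cluster_multiplier > 1)
  if (nrow(spots) == 0) return(spots)
  amp <- median(spots$peak_response) / log_gain(sigma_px)
  nominal <- calibration_footprint(sigma_px, threshold, amp)
  spots$is_cluster <- spots$footprint_px > cluster_multiplier * nominal
  spots
}

#' Detect spots in every frame of a movie channel
#'
#' Resolves `threshold = "auto"` once on a sample of frames spread across the
#' movie, then runs [detect_spots()] frame by frame.
#'
#' @param movie A [movie_stack()].
#' @param channel Channel index.
#' @param sigma_px,threshold,min_separation_px,cluster_multiplier,drop_clusters
#'   As [detect_spots()].
#' @param sample_frames Number of frames used to resolve an automatic
#'   threshold.
#' @return Spot table with `frame` and `channel` columns prepended; the
#'   resolved threshold is attached as attribute `"threshold"`.
#' @export
detect_movie <- function(movie, channel = 1L, sigma_px, threshold = "auto",
                         min_separation_px = 5, cluster_multiplier = 4,
                         drop_clusters = FALSE, sample_frames = 8) {
  stopifnot(inherits(movie, "movie_stack"))
  nT <- n_frames(movie)
  if (identical(threshold, "auto")) {
    idx <- unique(round(seq(1, nT, length.out = min(sample_frames, nT))))
    threshold <- as.numeric(auto_threshold(
      lapply(idx, function(t) get_plane(movie, t, channel)),
      sigma_px, min_separation_px))
  }
  out <- vector("list", nT)
  for (t in seq_len(nT)) {
    s <- detect_spots(get_plane(movie, t, channel), sigma_px, threshold,
                      min_separation_px, cluster_multiplier, drop_clusters)
    if (nrow(s)) out[[t]] <- cbind(frame = t, channel = channel, s)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- cbind(frame = integer(), channel = integer(),
                 detect_spots(matrix(0, 8, 8), sigma_px, Inf))
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}
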