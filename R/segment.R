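# Cell segmentation: watershed, polygon ROIs, imported masks, and
# spot-to-cell assignment.

#' Construct a cell mask
#'
#' @param labels Non-negative integer matrix `(Y, X)` (static mask) or array
#'   `(T, Y, X)` (time-varying mask); 0 is background, k > 0 is cell k.
#' @param frame_varying Whether one plane per frame is carried; inferred from
#'   the number of axes when `NULL`.
#' @param relabel Renumber positive labels contiguously from 1.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(labels, frame_varying = NULL, relabel = TRUE) {
  nd <- length(dim(labels))
  if (!nd %in% 2:3) stop("labels must be a (Y, X) matrix or (T, Y, X) array")
  if (anyNA(labels) || min(labels) < 0) stop("labels must be non-negative")
  if (is.null(frame_varying)) frame_varying <- nd == 3L
  labels <- round(labels)
  if (relabel) {
    u <- sort(unique(labels[labels > 0]))
    if (length(u) && !identical(as.integer(u), seq_along(u))) {
      remap <- integer(max(u)); remap[u] <- seq_along(u)
      pos <- labels > 0
      labels[pos] <- remap[labels[pos]]
    }
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, frame_varying = frame_varying),
            class = "cell_mask")
}

#' Number of cells in a mask
#' @param mask A [cell_mask()].
#' @return Integer count of distinct positive labels.
#' @export
n_cells <- function(mask) length(unique(mask$labels[mask$labels > 0]))

# Plane of the mask that applies to frame t.
mask_plane <- function(mask, t) {
  if (!mask$frame_varying) return(mask$labels)
  d <- dim(mask$labels)
  if (t < 1 || t > d[1]) stop("mask has no plane for frame ", t)
  matrix(mask$labels[t, , ], d[2], d[3])
}

#' Threshold-based watershed segmentation
#'
#' The image is Gaussian-smoothed, thresholded into foreground, and touching
#' cells are split by a watershed on the distance transform: local maxima of
#' the distance map within a radius of about half `min_peak_separation_px`
#' seed the basins. Regions smaller than `min_area_px` are removed and labels
#' renumbered from 1. An empty mask is a valid result.
#'
#' @param image 2D numeric matrix.
#' @param intensity_threshold Foreground threshold applied to the smoothed
#'   image (same units as the image).
#' @param min_area_px Minimum region area kept, pixels.
#' @param min_peak_separation_px Minimum separation between watershed seeds.
#' @param smooth_sigma Pre-smoothing Gaussian sigma in pixels.
#' @return A static [cell_mask()].
#' @export
watershed_segment <- function(image, intensity_threshold, min_area_px = 50,
                              min_peak_separation_px = 7, smooth_sigma = 2) {
  stopifnot(is.matrix(image), intensity_threshold >= 0, min_area_px >= 0,
            min_peak_separation_px >= 1)
  img <- matrix(as.numeric(image), nrow(image))
  sm <- if (smooth_sigma > 0) EBImage::gblur(img, sigma = smooth_sigma) else img
  fg <- sm >= intensity_threshold
  if (!any(fg)) return(cell_mask(matrix(0L, nrow(image), ncol(image)),
                                 frame_varying = FALSE))
  dist <- EBImage::distmap(fg)
  ext <- max(1L, as.integer(round(min_peak_separation_px / 2)))
  lab <- EBImage::watershed(dist, tolerance = 1, ext = ext)
  lab <- matrix(as.integer(lab), nrow(image))
  if (min_area_px > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  cell_mask(lab, frame_varying = FALSE)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
points_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon ROI into a mask
#'
#' Pixels whose centres fall inside the polygon (even-odd rule) receive
#' `label`.
#'
#' @param vertices Matrix or data frame of `(y, x)` vertices (>= 3), in
#'   pixel-centre coordinates.
#' @param shape Output `(Y, X)` dimensions.
#' @param label Positive label to assign.
#' @return A static [cell_mask()].
#' @export
polygon_to_mask <- function(vertices, shape, label = 1L) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) stop("a polygon ROI needs at least 3 vertices")
  stopifnot(ncol(vertices) == 2, length(shape) == 2, label >= 1)
  g <- expand.grid(y = seq_len(shape[1]), x = seq_len(shape[2]))
  inside <- points_in_polygon(g$y, g$x, vertices[, 1], vertices[, 2])
  lab <- matrix(0L, shape[1], shape[2])
  lab[cbind(g$y[inside], g$x[inside])] <- as.integer(label)
  cell_mask(lab, frame_varying = FALSE, relabel = FALSE)
}

#' Import a label mask from a TIFF
#'
#' Reads a label image produced by an external segmentation tool (one page =
#' static mask; multiple pages = time-varying, one plane per frame). Labels
#' are renumbered contiguously from 1, preserving regions.
#'
#' @param path TIFF path.
#' @param shape Optional expected `(Y, X)` size to validate against.
#' @return A [cell_mask()] with `frame_varying` inferred from the page count.
#' @export
import_mask <- function(path, shape = NULL) {
  pages <- read_tiff_pages(path)
  dyx <- dim(pages[[1]])
  if (!is.null(shape) && !all(dyx == shape))
    stop("mask shape (", paste(dyx, collapse = "x"),
         ") does not match movie shape (", paste(shape, collapse = "x"), ")")
  if (length(pages) == 1L) {
    cell_mask(pages[[1]], frame_varying = FALSE)
  } else {
    arr <- array(0L, c(length(pages), dyx))
    for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
    cell_mask(arr, frame_varying = TRUE)
  }
}

#' Write a cell mask as a label TIFF
#'
#' @param mask A [cell_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  if (mask$frame_varying) {
    d <- dim(mask$labels)
    pages <- lapply(seq_len(d[1]), function(t)
      matrix(mask$labels[t, , ], d[2], d[3]) / 65535)
  } else {
    pages <- list(mask$labels / 65535)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Map detected spots to cells
#'
#' Each spot receives the mask label at its nearest pixel (rounded position);
#' time-varying masks use the plane matching the spot's frame. Spots outside
#' every cell get `cell_label = 0`.
#'
#' @param spots Spot table with columns `frame`, `y_px`, `x_px`.
#' @param mask A [cell_mask()].
#' @return `spots` with the `cell_label` column filled.
#' @export
assign_spots_to_cells <- function(spots, mask) {
  stopifnot(is.data.frame(spots), inherits(mask, "cell_mask"))
  if (nrow(spots) == 0) {
    spots$cell_label <- integer(0)
    return(spots)
  }
  dyx <- if (mask$frame_varying) dim(mask$labels)[2:3] else dim(mask$labels)
  yi <- pmin(pmax(round(spots$y_px), 1), dyx[1])
  xi <- pmin(pmax(round(spots$x_px), 1), dyx[2])
  lab <- integer(nrow(spots))
  for (t in unique(spots$frame)) {
    pl <- mask_plane(mask, t)
    sel <- spots$frame == t
    lab[sel] <- pl[cbind(yi[sel], xi[sel])]
  }
  spots$cell_label <- lab
  spots
}
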