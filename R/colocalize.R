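# Two-channel colocalization by distance-gated one-to-one assignment.

#' Match spots between two channels within one frame
#'
#' One-to-one assignment minimizing the total distance among pairs within
#' `d_max_px` (a translation site is one mRNA plus one nascent-protein
#' signal, so all-neighbours counting is deliberately not used). Unmatched
#' spots are reported separately.
#'
#' @param spots_a,spots_b Spot tables from the same frame with `y_px`,
#'   `x_px` and optionally `spot_id` (defaults to row number).
#' @param d_max_px Maximum pairing distance, pixels.
#' @return List with `pairs` (data frame `id_a`, `id_b`, `distance_px`) and
#'   `unmatched_a` / `unmatched_b` (ids).
#' @export
match_spots_frame <- function(spots_a, spots_b, d_max_px = 2) {
  stopifnot(is.data.frame(spots_a), is.data.frame(spots_b), d_max_px >= 0)
  ida <- spots_a$spot_id %||% seq_len(nrow(spots_a))
  idb <- spots_b$spot_id %||% seq_len(nrow(spots_b))
  pa <- cbind(spots_a$y_px, spots_a$x_px)
  pb <- cbind(spots_b$y_px, spots_b$x_px)
  pairs <- gated_assignment(pa, pb, d_max_px, squared = FALSE)
  dd <- if (nrow(pairs)) sqrt((pa[pairs[, 1], 1] - pb[pairs[, 2], 1])^2 +
                                (pa[pairs[, 1], 2] - pb[pairs[, 2], 2])^2)
        else numeric()
  list(pairs = data.frame(id_a = ida[pairs[, 1]], id_b = idb[pairs[, 2]],
                          distance_px = dd),
       unmatched_a = setdiff(ida, ida[pairs[, 1]]),
       unmatched_b = setdiff(idb, idb[pairs[, 2]]))
}

#' Colocalize tracks across channels
#'
#' For every track pair the colocalized fraction is the share of co-resolved
#' frames (both tracks detected) at distance `<= d_max_px`. Pairs with
#' fraction `>= min_fraction` are reported, each track in at most one pair:
#' candidates are ranked by fraction (ties by smaller mean distance) and
#' selected greedily one-to-one.
#'
#' @param tracks_a,tracks_b Linked spot tables (same time base) with `frame`,
#'   `track_id`, `y_px`, `x_px`.
#' @param d_max_px Per-frame colocalization distance, pixels.
#' @param min_fraction Minimum colocalized fraction reported.
#' @return Data frame: `id_a`, `id_b`, `colocalized_fraction`,
#'   `mean_distance_px`, `n_frames` (co-resolved frames).
#' @export
colocalize_tracks <- function(tracks_a, tracks_b, d_max_px = 2,
                              min_fraction = 0.5) {
  stopifnot(d_max_px >= 0, min_fraction >= 0, min_fraction <= 1)
  ta <- split_tracks(tracks_a)
  tb <- split_tracks(tracks_b)
  cand <- list()
  for (a in names(ta)) for (b in names(tb)) {
    fa <- ta[[a]]; fb <- tb[[b]]
    common <- intersect(fa$frame, fb$frame)
    if (!length(common)) next
    ia <- match(common, fa$frame); ib <- match(common, fb$frame)
    d <- sqrt((fa$y_px[ia] - fb$y_px[ib])^2 + (fa$x_px[ia] - fb$x_px[ib])^2)
    frac <- mean(d <= d_max_px)
    if (frac >= min_fraction)
      cand[[length(cand) + 1]] <- data.frame(
        id_a = fa$track_id[1], id_b = fb$track_id[1],
        colocalized_fraction = frac, mean_distance_px = mean(d),
        n_frames = length(common))
  }
  empty <- data.frame(id_a = integer(), id_b = integer(),
                      colocalized_fraction = numeric(),
                      mean_distance_px = numeric(), n_frames = integer())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$colocalized_fraction, cand$mean_distance_px,
                     cand$id_a, cand$id_b), ]
  used_a <- used_b <- integer()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$id_a[i] %in% used_a || cand$id_b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$id_a[i]); used_b <- c(used_b, cand$id_b[i])
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
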