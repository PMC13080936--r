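# Particle tracking: frame-to-frame linking with gap memory, MSD curves,
# and diffusion-coefficient estimation.

# Optimal one-to-one assignment between two point sets with a distance gate.
# Returns a two-column matrix of (i, j) index pairs with d(i, j) <= gate,
# minimizing the total cost among gated pairs (big-M padding on the gated
# pairs, solved with the Hungarian algorithm).
gated_assignment <- function(pa, pb, gate, squared = TRUE) {
  na <- nrow(pa); nb <- nrow(pb)
  if (na == 0 || nb == 0) return(matrix(integer(), ncol = 2))
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  cost <- if (squared) d2 else sqrt(d2)
  gate2 <- gate^2
  big <- sum(cost[d2 <= gate2]) + max(cost) + 1
  cost[d2 > gate2] <- big
  transposed <- FALSE
  if (na > nb) {
    cost <- t(cost); d2 <- t(d2); transposed <- TRUE
  }
  sol <- clue::solve_LSAP(cost)
  i <- seq_len(nrow(cost)); j <- as.integer(sol)
  ok <- d2[cbind(i, j)] <= gate2
  pairs <- cbind(i[ok], j[ok])
  if (transposed) pairs <- pairs[, 2:1, drop = FALSE]
  pairs
}

# Greedy nearest-neighbour alternative: repeatedly link the globally closest
# remaining pair within the gate.
greedy_assignment <- function(pa, pb, gate) {
  na <- nrow(pa); nb <- nrow(pb)
  if (na == 0 || nb == 0) return(matrix(integer(), ncol = 2))
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  d2[d2 > gate^2] <- Inf
  pairs <- matrix(integer(), ncol = 2)
  while (any(is.finite(d2))) {
    k <- which.min(d2)
    i <- (k - 1) %% na + 1; j <- (k - 1) %/% na + 1
    pairs <- rbind(pairs, c(i, j))
    d2[i, ] <- Inf; d2[, j] <- Inf
  }
  pairs
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame linking by optimal one-to-one assignment (minimum total
#' squared displacement among pairs within `max_disp_px`, the deterministic
#' member of the nearest-neighbour family; `method = "greedy"` gives plain
#' globally-greedy nearest neighbour). A track head that finds no match stays
#' alive for up to `memory` frames with its search radius growing as
#' `max_disp_px * (gap + 1)`; spots bridged this way are recorded as gap
#' frames. Tracks with fewer than `min_track_len` detections are discarded
#' (their spots keep `track_id = NA`).
#'
#' @param spots Spot table with columns `frame`, `y_px`, `x_px` (one channel).
#' @param max_disp_px Maximum displacement per frame, pixels.
#' @param memory Maximum number of consecutive undetected frames bridged.
#' @param min_track_len Minimum number of detections per retained track.
#' @param method `"assignment"` (optimal, default) or `"greedy"`.
#' @return `spots` with a `track_id` column (`NA` for unlinked spots), sorted
#'   by frame. Each spot belongs to at most one track.
#' @export
link_spots <- function(spots, max_disp_px, memory = 0, min_track_len = 1,
                       method = c("assignment", "greedy")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(spots), max_disp_px >= 0, memory >= 0,
            min_track_len >= 1)
  spots <- spots[order(spots$frame), , drop = FALSE]
  n <- nrow(spots)
  spots$track_id <- rep(NA_integer_, n)
  if (n == 0) return(spots)
  next_id <- 1L
  # active track heads: track id, last position, last frame
  heads <- data.frame(id = integer(), y = numeric(), x = numeric(),
                      frame = integer())
  frames <- sort(unique(spots$frame))
  for (f in frames) {
    sel <- which(spots$frame == f)
    pb <- cbind(spots$y_px[sel], spots$x_px[sel])
    heads <- heads[f - heads$frame <= memory + 1, , drop = FALSE]
    assigned <- rep(FALSE, length(sel))
    if (nrow(heads) > 0) {
      # link heads with the smallest gap first, so fresh tracks take
      # precedence over memory-bridged candidates
      for (g in sort(unique(f - heads$frame))) {
        hs <- which(f - heads$frame == g & !is.na(heads$id))
        js <- which(!assigned)
        if (!length(hs) || !length(js)) next
        pa <- cbind(heads$y[hs], heads$x[hs])
        gate <- max_disp_px * g
        pairs <- if (method == "assignment")
          gated_assignment(pa, pb[js, , drop = FALSE], gate)
        else greedy_assignment(pa, pb[js, , drop = FALSE], gate)
        if (nrow(pairs)) {
          for (k in seq_len(nrow(pairs))) {
            h <- hs[pairs[k, 1]]; j <- js[pairs[k, 2]]
            spots$track_id[sel[j]] <- heads$id[h]
            heads$y[h] <- pb[j, 1]; heads$x[h] <- pb[j, 2]
            heads$frame[h] <- f
            assigned[j] <- TRUE
          }
        }
      }
    }
    for (j in which(!assigned)) {
      spots$track_id[sel[j]] <- next_id
      heads <- rbind(heads, data.frame(id = next_id, y = pb[j, 1],
                                       x = pb[j, 2], frame = f))
      next_id <- next_id + 1L
    }
  }
  if (min_track_len > 1) {
    len <- table(spots$track_id)
    short <- as.integer(names(len)[len < min_track_len])
    spots$track_id[spots$track_id %in% short] <- NA_integer_
  }
  rownames(spots) <- NULL
  spots
}

#' Link detections independently per channel
#'
#' Runs [link_spots()] on each channel with channel-specific parameters;
#' track ids are unique across channels.
#'
#' @param spots Spot table with a `channel` column.
#' @param params Named list, one entry per channel (names are channel
#'   indices), each a list of arguments for [link_spots()]; a single unnamed
#'   list applies to all channels.
#' @return `spots` with `track_id` filled, ids disjoint across channels.
#' @export
link_multichannel <- function(spots, params = list()) {
  stopifnot(is.data.frame(spots), "channel" %in% names(spots))
  chans <- sort(unique(spots$channel))
  arg_names <- setdiff(names(formals(link_spots)), "spots")
  per_channel <- length(params) && !is.null(names(params)) &&
    all(nzchar(names(params))) && !any(names(params) %in% arg_names)
  out <- vector("list", length(chans))
  offset <- 0L
  for (i in seq_along(chans)) {
    ch <- chans[i]
    p <- if (per_channel) params[[as.character(ch)]] else params
    linked <- do.call(link_spots,
                      c(list(spots = spots[spots$channel == ch, , drop = FALSE]),
                        p))
    linked$track_id <- linked$track_id + offset
    if (any(!is.na(linked$track_id)))
      offset <- max(linked$track_id, na.rm = TRUE)
    out[[i]] <- linked
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Time-averaged mean squared displacement of one track
#'
#' `msd(tau)` is the mean squared displacement over all pairs of detections
#' separated by lag `tau` within the track; frames missing at gaps are simply
#' excluded pairwise. Lag 0 (msd 0) is included.
#'
#' @param track Data frame with `frame`, `y_px`, `x_px` for a single track.
#' @param frame_interval_s Seconds per frame.
#' @param max_lag_frames Largest lag evaluated (default: track span - 1).
#' @return Object of class `msd_curve`: data frame `lag_s`, `msd_px2`,
#'   `n_pairs`.
#' @export
compute_msd <- function(track, frame_interval_s, max_lag_frames = NULL) {
  stopifnot(is.data.frame(track), nrow(track) >= 2)
  track <- track[order(track$frame), ]
  f <- track$frame
  span <- max(f) - min(f)
  max_lag <- min(max_lag_frames %||% span, span)
  lags <- 0:max_lag
  msd <- numeric(length(lags)); np <- integer(length(lags))
  np[1] <- nrow(track)
  idx <- setNames(seq_along(f), f)
  for (li in seq_along(lags)[-1]) {
    L <- lags[li]
    j <- idx[as.character(f + L)]
    ok <- !is.na(j)
    np[li] <- sum(ok)
    if (np[li] > 0) {
      i <- which(ok); j <- j[ok]
      msd[li] <- mean((track$y_px[j] - track$y_px[i])^2 +
                        (track$x_px[j] - track$x_px[i])^2)
    }
  }
  keep <- np > 0
  structure(data.frame(lag_s = lags[keep] * frame_interval_s,
                       msd_px2 = msd[keep], n_pairs = np[keep]),
            class = c("msd_curve", "data.frame"))
}

#' Estimate a diffusion coefficient from MSD curves
#'
#' Fits `msd = 4 * D * tau + b` by weighted least squares (weights =
#' `n_pairs`) over the first `n_fit_lags` positive lags of the pooled
#' ensemble, with a percentile bootstrap over tracks for the confidence
#' interval. `D` is clamped at 0.
#'
#' @param curves A `msd_curve` or list of them.
#' @param n_fit_lags Number of positive lags used in the fit.
#' @param n_boot Bootstrap replicates (0 to skip).
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `D_px2s`, `intercept`, `r2`, `ci` (length-2 vector or
#'   `NULL`), `n_tracks`.
#' @export
estimate_diffusion <- function(curves, n_fit_lags = 4, n_boot = 200,
                               conf = 0.95, seed = 1L) {
  if (inherits(curves, "msd_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1, n_fit_lags >= 2)
  pool <- do.call(rbind, lapply(curves, as.data.frame))
  pool <- pool[pool$lag_s > 0, ]
  lags <- sort(unique(pool$lag_s))
  if (length(lags) < n_fit_lags) stop("not enough lags for the requested fit")
  fit_d <- function(df) {
    df <- df[df$lag_s <= lags[n_fit_lags], ]
    f <- lm(msd_px2 ~ lag_s, data = df, weights = df$n_pairs)
    c(D = max(coef(f)[[2]] / 4, 0), b = coef(f)[[1]],
      r2 = summary(f)$r.squared)
  }
  est <- fit_d(pool)
  ci <- NULL
  if (n_boot > 0 && length(curves) > 1) {
    set.seed(derive_seed(seed, "msdboot"))
    boots <- vapply(seq_len(n_boot), function(i) {
      take <- sample(length(curves), replace = TRUE)
      fit_d(do.call(rbind, lapply(curves[take], as.data.frame)))[["D"]]
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(a, 1 - a)))
  }
  list(D_px2s = unname(est["D"]), intercept = unname(est["b"]),
       r2 = unname(est["r2"]), ci = ci, n_tracks = length(curves))
}

#' Split a linked spot table into per-track data frames
#'
#' @param spots Output of [link_spots()]; rows with `NA` ids are dropped.
#' @return Named list of data frames, one per track.
#' @export
split_tracks <- function(spots) {
  spots <- spots[!is.na(spots$track_id), , drop = FALSE]
  split(spots, spots$track_id)
}
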