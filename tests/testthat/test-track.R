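# Linking, gap memory, MSD, and diffusion estimation.

test_that("a stationary spot yields one full-length gapless track", {
  spots <- data.frame(frame = 1:20, y_px = 10, x_px = 12)
  linked <- link_spots(spots, max_disp_px = 3)
  expect_equal(length(unique(linked$track_id)), 1)
  expect_equal(nrow(linked), 20)
})

test_that("linking matches the exhaustive minimum-displacement oracle", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(2:4, 1)
    start <- cbind(runif(n, 10, 90), runif(n, 10, 90))
    # ensure generous inter-particle spacing relative to step size
    while (n > 1 && min(dist(start)) < 25)
      start <- cbind(runif(n, 10, 90), runif(n, 10, 90))
    pos <- list(start)
    for (f in 2:5) pos[[f]] <- pos[[f - 1]] + matrix(rnorm(2 * n, 0, 1), n)
    spots <- do.call(rbind, lapply(seq_along(pos), function(f)
      data.frame(frame = f, y_px = pos[[f]][, 1], x_px = pos[[f]][, 2])))
    linked <- link_spots(spots, max_disp_px = 8)
    oracle <- exhaustive_link(pos)
    # same partition of detections into tracks
    key <- function(ids) {
      groups <- split(seq_along(ids), ids)
      sort(vapply(groups, paste, character(1), collapse = ","))
    }
    got <- linked$track_id
    want <- unlist(oracle)   # ordered as frame-major rows, same as spots
    expect_identical(unname(key(got)), unname(key(want)))
  }
})

test_that("memory bridges single-frame dropouts; memory 0 splits tracks", {
  spots <- data.frame(frame = c(1, 2, 4, 5), y_px = 5, x_px = 5)
  with_mem <- link_spots(spots, max_disp_px = 2, memory = 1)
  expect_equal(length(unique(with_mem$track_id)), 1)
  without <- link_spots(spots, max_disp_px = 2, memory = 0)
  expect_equal(length(unique(without$track_id)), 2)
})

test_that("short tracks are discarded and no spot sits in two tracks", {
  set.seed(15)
  spots <- rbind(
    data.frame(frame = 1:12, y_px = 20 + rnorm(12, 0, 0.2), x_px = 20),
    data.frame(frame = 1:3, y_px = 60 + rnorm(3, 0, 0.2), x_px = 60))
  linked <- link_spots(spots, max_disp_px = 3, min_track_len = 5)
  kept <- linked[!is.na(linked$track_id), ]
  expect_equal(length(unique(kept$track_id)), 1)
  expect_equal(nrow(kept), 12)
  expect_false(any(duplicated(
    kept[, c("track_id", "frame")])))   # one spot per track per frame
})

test_that("linking is invariant under global translation", {
  set.seed(16)
  spots <- do.call(rbind, lapply(1:6, function(f)
    data.frame(frame = f, y_px = c(10, 40, 70) + rnorm(3, 0, 0.5),
               x_px = c(15, 45, 75) + rnorm(3, 0, 0.5))))
  a <- link_spots(spots, max_disp_px = 5)
  b <- spots; b$y_px <- b$y_px + 123.4; b$x_px <- b$x_px - 67.8
  b <- link_spots(b, max_disp_px = 5)
  expect_identical(a$track_id, b$track_id)
})

test_that("optimal assignment beats greedy on crossing trajectories", {
  # two particles pass close by; greedy nearest-neighbour swaps them
  spots <- rbind(
    data.frame(frame = 1, y_px = c(10, 12), x_px = c(10, 10)),
    data.frame(frame = 2, y_px = c(11.1, 13.5), x_px = c(10, 10)))
  total_disp <- function(linked) {
    sum(vapply(split(linked, linked$track_id), function(tr)
      if (nrow(tr) == 2) sum((diff(tr$y_px))^2 + (diff(tr$x_px))^2) else 0,
      numeric(1)))
  }
  opt <- link_spots(spots, max_disp_px = 5, method = "assignment")
  gre <- link_spots(spots, max_disp_px = 5, method = "greedy")
  expect_lte(total_disp(opt), total_disp(gre))
})

test_that("multichannel linking is independent per channel with disjoint ids", {
  base <- do.call(rbind, lapply(1:8, function(f)
    data.frame(frame = f, y_px = c(10, 30), x_px = c(10, 30))))
  spots <- rbind(cbind(base, channel = 1L), cbind(base, channel = 2L))
  linked <- link_multichannel(spots, list(max_disp_px = 3))
  ids1 <- unique(linked$track_id[linked$channel == 1])
  ids2 <- unique(linked$track_id[linked$channel == 2])
  expect_length(intersect(ids1, ids2), 0)
  # geometry identical to single-channel runs
  solo <- link_spots(base, max_disp_px = 3)
  expect_equal(table(linked$track_id[linked$channel == 2]),
               table(solo$track_id), ignore_attr = TRUE)
  # empty channel produces no tracks
  linked2 <- link_multichannel(spots[spots$channel == 1, ],
                               list(max_disp_px = 3))
  expect_true(all(linked2$channel == 1))
})

test_that("MSD is exact for stationary and ballistic tracks", {
  still <- data.frame(frame = 1:10, y_px = 4, x_px = 4)
  ms <- compute_msd(still, frame_interval_s = 2)
  expect_true(all(ms$msd_px2 == 0))
  expect_equal(ms$lag_s[1], 0)

  v <- 1  # px/frame along x
  ball <- data.frame(frame = 1:30, y_px = 0, x_px = v * (1:30))
  mb <- compute_msd(ball, frame_interval_s = 1)
  expect_equal(mb$msd_px2, (v * mb$lag_s)^2, tolerance = 1e-12)
})

test_that("gap frames are excluded pairwise from MSD", {
  tr <- data.frame(frame = c(1, 2, 4), y_px = c(0, 1, 5), x_px = 0)
  ms <- compute_msd(tr, frame_interval_s = 1)
  # lag 1: only (1,2); lag 2: only (2,4); lag 3: (1,4)
  expect_equal(ms$n_pairs[-1], c(1, 1, 1))
  expect_equal(ms$msd_px2[-1], c(1, 16, 25))
})

test_that("ensemble MSD slope recovers 4D within 20% and scales with the time base", {
  D <- 0.05; dt <- 1
  p <- simulation_params(diffusion_coeff_px2s = D, frame_interval_s = dt,
                         n_spots = 100, n_frames = 200, fov_yx = c(512, 512),
                         seed = 17, min_separation_px = 4)
  pos <- simulate_positions(p)
  curves <- lapply(1:100, function(s)
    compute_msd(data.frame(frame = 1:200, y_px = pos[, s, 1],
                           x_px = pos[, s, 2]),
                frame_interval_s = dt, max_lag_frames = 10))
  est <- estimate_diffusion(curves, n_fit_lags = 4, n_boot = 100)
  expect_equal(est$D_px2s, D, tolerance = 0.2)
  expect_true(est$ci[1] <= D && D <= est$ci[2])

  # doubling the declared frame interval halves D for the same pixel paths
  curves2 <- lapply(1:100, function(s)
    compute_msd(data.frame(frame = 1:200, y_px = pos[, s, 1],
                           x_px = pos[, s, 2]),
                frame_interval_s = 2 * dt, max_lag_frames = 10))
  est2 <- estimate_diffusion(curves2, n_fit_lags = 4, n_boot = 0)
  expect_equal(est2$D_px2s, est$D_px2s / 2, tolerance = 1e-10)

  still <- lapply(1:5, function(i)
    compute_msd(data.frame(frame = 1:50, y_px = 3, x_px = 7), 1))
  expect_equal(estimate_diffusion(still, n_boot = 0)$D_px2s, 0)
})
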