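# Disk photometry, Gaussian fitting, and intensity-trace extraction.

test_that("a uniform field background-subtracts to zero", {
  img <- matrix(250, 32, 32)
  m <- measure_spot(img, 16, 16, disk_radius_px = 3)
  expect_lt(abs(m$bg_sub), 1e-6 * m$total)
})

test_that("disk photometry of a noiseless Gaussian matches the analytic integral", {
  A <- 200; sigma <- 1.3; offset <- 40
  img <- gauss_image(41, 41, rbind(c(21.4, 20.6, A)), sigma, offset = offset)
  m <- measure_spot(img, 21.4, 20.6, disk_radius_px = 3 * sigma,
                    ring_inner_px = 3 * sigma, ring_outer_px = 3 * sigma + 4)
  expect_equal(m$bg_sub, A * 2 * pi * sigma^2 * 0.9889, tolerance = 0.02)
  expect_gte(m$total, m$bg_sub)
})

test_that("measure_spot equals a naive per-pixel loop oracle on random patches", {
  set.seed(23)
  for (i in 1:10) {
    img <- matrix(runif(31 * 31, 0, 1000), 31)
    y <- runif(1, 12, 20); x <- runif(1, 12, 20)
    m <- measure_spot(img, y, x, 4, 4, 7)
    # oracle: loop every pixel, classify by centre distance
    tot <- 0; disk_n <- 0; ring <- c()
    for (yy in 1:31) for (xx in 1:31) {
      d <- sqrt((yy - y)^2 + (xx - x)^2)
      if (d <= 4) { tot <- tot + img[yy, xx]; disk_n <- disk_n + 1 }
      else if (d > 4 && d <= 7) ring <- c(ring, img[yy, xx])
    }
    expect_equal(m$total, tot, tolerance = 1e-12)
    expect_equal(m$bg_sub, tot - median(ring) * disk_n, tolerance = 1e-12)
  }
})

test_that("photometry is additive for two disjoint far-apart spots", {
  A <- 150; sigma <- 1.2
  one <- gauss_image(61, 61, rbind(c(20, 30, A)), sigma)
  two <- gauss_image(61, 61, rbind(c(45, 30, A)), sigma)
  both <- one + two
  m1 <- measure_spot(one, 20, 30, 4)
  m2 <- measure_spot(two, 45, 30, 4)
  mb1 <- measure_spot(both, 20, 30, 4)
  mb2 <- measure_spot(both, 45, 30, 4)
  expect_equal(mb1$total + mb2$total, m1$total + m2$total, tolerance = 1e-6)
})

test_that("Gaussian fit recovers noiseless parameters within 1%", {
  A <- 200; sigma <- 1.5; c0 <- 10
  img <- gauss_image(15, 15, rbind(c(8.3, 7.6, A)), sigma, offset = c0)
  f <- fit_gaussian2d(img)
  expect_true(f$converged)
  expect_equal(f$amplitude, A, tolerance = 0.01)
  expect_equal(f$sigma_px, sigma, tolerance = 0.01)
  expect_equal(f$offset, c0, tolerance = 0.01)
  expect_equal(f$center, c(8.3, 7.6), tolerance = 1e-3)
  # fitted integrated intensity agrees with disk photometry within 5%
  big <- gauss_image(41, 41, rbind(c(21, 21, A)), sigma, offset = c0)
  m <- measure_spot(big, 21, 21, disk_radius_px = 4 * sigma,
                    ring_inner_px = 4 * sigma, ring_outer_px = 4 * sigma + 4)
  expect_equal(f$integrated, m$bg_sub, tolerance = 0.05)
})

test_that("a flat patch does not produce a spurious converged spot", {
  f <- fit_gaussian2d(matrix(55, 9, 9))
  expect_true(!f$converged || f$amplitude < 1e-3 * 55)
})

test_that("the median fitted sigma under Poisson noise is within 10% of truth", {
  A <- 200; sigma <- 1.5; c0 <- 20
  clean <- gauss_image(15, 15, rbind(c(8, 8, A)), sigma, offset = c0)
  set.seed(29)
  sigmas <- vapply(1:100, function(i) {
    noisy <- matrix(rpois(length(clean), as.vector(clean)), nrow(clean))
    fit_gaussian2d(noisy)$sigma_px
  }, numeric(1))
  expect_equal(median(sigmas, na.rm = TRUE), sigma, tolerance = 0.1)
})

test_that("traces are constant for constant spots and gaps follow the policy", {
  p <- simulation_params(n_spots = 2, n_frames = 10, fov_yx = c(48, 48),
                         background_level = 0, read_noise_sd = 0,
                         bleach_rate = 0, diffusion_coeff_px2s = 0,
                         fraction_translating = 0, seed = 31,
                         min_separation_px = 14)
  sim <- simulate_movie(p)
  spots <- detect_movie(sim$movie, 1, sigma_px = 1.3, threshold = 20)
  linked <- link_spots(spots, max_disp_px = 2)
  tr <- extract_traces(sim$movie, linked, method = "bg_sub", sigma_px = 1.3)
  for (id in unique(tr$track_id)) {
    v <- tr$intensity[tr$track_id == id]
    expect_lt(diff(range(v)) / mean(v), 0.02)
  }

  # drop one detection -> gap accounting under both policies
  gap_spots <- linked[!(linked$frame == 5 &
                          linked$track_id == linked$track_id[1]), ]
  relinked <- link_spots(gap_spots[, c("frame", "channel", "y_px", "x_px")],
                         max_disp_px = 2, memory = 1)
  tr_skip <- extract_traces(sim$movie, relinked, method = "bg_sub",
                            gap_policy = "skip", sigma_px = 1.3)
  expect_equal(sum(is.na(tr_skip$intensity)), 1)
  tr_int <- extract_traces(sim$movie, relinked, method = "bg_sub",
                           gap_policy = "interp", sigma_px = 1.3)
  expect_equal(sum(is.na(tr_int$intensity)), 0)
})

test_that("total, bg_sub and gauss trace methods agree on clean spots", {
  p <- simulation_params(n_spots = 1, n_frames = 6, fov_yx = c(32, 32),
                         spot_amplitude = 300, background_level = 0,
                         read_noise_sd = 0, bleach_rate = 0,
                         diffusion_coeff_px2s = 0, fraction_translating = 0,
                         seed = 37)
  sim <- simulate_movie(p)
  spots <- detect_movie(sim$movie, 1, sigma_px = 1.3, threshold = 20)
  linked <- link_spots(spots, max_disp_px = 2)
  v_bg <- extract_traces(sim$movie, linked, "bg_sub", sigma_px = 1.3)$intensity
  v_gs <- extract_traces(sim$movie, linked, "gauss", sigma_px = 1.3)$intensity
  expect_equal(mean(v_gs) / mean(v_bg), 1, tolerance = 0.06)
})
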