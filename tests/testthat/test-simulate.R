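# Translation-trace, motion, and rendering behaviour of the simulator.

test_that("no initiations yield identically zero traces", {
  p <- simulation_params(ki = 0, n_spots = 5, n_frames = 20,
                         fov_yx = c(32, 32), min_separation_px = 2)
  tr <- simulate_translation_traces(p)
  expect_true(all(tr$intensity == 0))
  expect_true(all(tr$ribosomes == 0))
})

test_that("steady-state ribosome occupancy matches the Little's-law expectation", {
  # ki * L / ke = 0.01 * 1000 / 10 = 1 ribosome on average; >= 200 spot hours
  p <- simulation_params(ki = 0.01, ke = 10, L_total = 1000,
                         probe_positions = c(10, 20, 30),
                         n_spots = 250, n_frames = 720, frame_interval_s = 5,
                         fov_yx = c(64, 64), min_separation_px = 1, seed = 5)
  tr <- simulate_translation_traces(p)
  spot_means <- colMeans(tr$ribosomes)
  se <- sd(spot_means) / sqrt(length(spot_means))
  expect_lt(abs(mean(spot_means) - 1), 3 * se + 1e-9)
})

test_that("trace steady state agrees with a slow ribosome-stepping oracle", {
  # independent oracle: explicit small-step simulation, one ribosome at a time
  ki <- 0.05; ke <- 5; L <- 60; probes <- c(5, 10, 20)
  oracle_mean <- local({
    set.seed(101)
    dt <- 0.02; burn <- L / ke; t_end <- 2000
    steps <- seq(-burn, t_end, by = dt)
    vals <- c()
    ribs <- list()  # initiation times
    for (i in seq_along(steps)) {
      if (runif(1) < ki * dt) ribs[[length(ribs) + 1]] <- steps[i]
      if (steps[i] >= 0 && i %% 250 == 0) {   # sample every 5 s
        pos <- ke * (steps[i] - unlist(ribs))
        pos <- pos[pos >= 0 & pos < L]
        vals <- c(vals, sum(findInterval(pos, probes)) / length(probes))
      }
    }
    mean(vals)
  })
  p <- simulation_params(ki = ki, ke = ke, L_total = L,
                         probe_positions = probes, n_spots = 60,
                         n_frames = 400, frame_interval_s = 5,
                         fov_yx = c(64, 64), min_separation_px = 1, seed = 9)
  tr <- simulate_translation_traces(p)
  # both should approximate ki * L_eff / ke (here 0.05 * (60 - 35/3) / 5)
  expect_equal(mean(tr$intensity), oracle_mean, tolerance = 0.12)
  expect_equal(mean(tr$intensity), ki * p$L_eff / ke, tolerance = 0.1)
})

test_that("tethered spots are static and Brownian steps have the right moments", {
  p0 <- simulation_params(diffusion_coeff_px2s = 0, n_spots = 4,
                          n_frames = 30, fov_yx = c(64, 64))
  pos0 <- simulate_positions(p0)
  expect_true(all(apply(pos0, 2:3, function(v) diff(range(v))) == 0))

  D <- 0.05; dt <- 1
  p <- simulation_params(diffusion_coeff_px2s = D, frame_interval_s = dt,
                         n_spots = 50, n_frames = 201, fov_yx = c(256, 256),
                         seed = 21)
  pos <- simulate_positions(p)
  inc <- apply(pos, c(2, 3), diff)        # (frames-1, spots, yx)
  inc <- as.vector(inc)                   # n = 50 * 200 * 2 = 2e4 increments
  expect_gt(length(inc), 1e4)
  expect_lt(abs(mean(inc)), 3 * sd(inc) / sqrt(length(inc)))
  expect_equal(var(inc), 2 * D * dt, tolerance = 0.1)
})

test_that("a noiseless rendered spot has the analytic Gaussian integral", {
  amp <- 1000; sigma <- 1.3
  p <- simulation_params(n_spots = 1, n_frames = 1, fov_yx = c(41, 41),
                         psf_sigma_px = sigma, spot_amplitude = amp,
                         background_level = 0, read_noise_sd = 0,
                         bleach_rate = 0, diffusion_coeff_px2s = 0,
                         fraction_translating = 0, seed = 2)
  out <- render_movie(simulate_translation_traces(p), simulate_positions(p), p)
  img <- get_plane(out$movie, 1, 1)
  tru <- out$truth[1, ]
  pk <- arrayInd(which.max(img), dim(img))
  expect_equal(as.vector(pk), round(c(tru$y_px, tru$x_px)))
  yy <- row(img); xx <- col(img)
  disk <- sqrt((yy - tru$y_px)^2 + (xx - tru$x_px)^2) <= 3 * sigma
  expect_equal(sum(img[disk]), amp * 2 * pi * sigma^2 * 0.9889,
               tolerance = 0.01)
})

test_that("noiseless static movies without bleaching are time-invariant", {
  p <- simulation_params(n_spots = 3, n_frames = 12, fov_yx = c(48, 48),
                         background_level = 0, read_noise_sd = 0,
                         bleach_rate = 0, diffusion_coeff_px2s = 0,
                         fraction_translating = 0, seed = 4,
                         min_separation_px = 8)
  out <- simulate_movie(p)
  expect_identical(get_plane(out$movie, 1, 1), get_plane(out$movie, 12, 1))
})

test_that("rendering is deterministic given the seed and truth bookkeeping is complete", {
  p <- simulation_params(n_spots = 6, n_frames = 8, fov_yx = c(64, 64),
                         seed = 33, min_separation_px = 8)
  a <- simulate_movie(p); b <- simulate_movie(p)
  expect_identical(a$movie$data, b$movie$data)
  expect_equal(nrow(a$truth), 8 * 6)
  expect_true(all(a$truth$intensity_norm >= 0))
})

test_that("the mean of many noisy renders converges to the noiseless render", {
  base <- simulation_params(n_spots = 2, n_frames = 1, fov_yx = c(32, 32),
                            spot_amplitude = 200, background_level = 50,
                            read_noise_sd = 1, bleach_rate = 0,
                            diffusion_coeff_px2s = 0,
                            fraction_translating = 0, seed = 6,
                            min_separation_px = 10)
  tr <- simulate_translation_traces(base)
  pos <- simulate_positions(base)
  clean_p <- simulation_params(n_spots = 2, n_frames = 1, fov_yx = c(32, 32),
                               spot_amplitude = 200, background_level = 0,
                               read_noise_sd = 0, bleach_rate = 0,
                               diffusion_coeff_px2s = 0,
                               fraction_translating = 0, seed = 6,
                               min_separation_px = 10)
  clean <- matrix(as.numeric(get_plane(render_movie(tr, pos, clean_p)$movie,
                                       1, 1)), 32) + 50
  acc <- matrix(0, 32, 32)
  reps <- 200
  for (i in seq_len(reps)) {
    pi_ <- base; pi_$seed <- 1000L + i
    acc <- acc + get_plane(render_movie(tr, pos, pi_)$movie, 1, 1)
  }
  err <- abs(acc / reps - clean)
  expect_lt(mean(err), 0.2 * sqrt(50))   # well under one noise sd
})

test_that("simulator rejects fields too small for the requested spot count", {
  expect_error(simulate_positions(
    simulation_params(n_spots = 50, fov_yx = c(32, 32),
                      min_separation_px = 12)), "too small")
})
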