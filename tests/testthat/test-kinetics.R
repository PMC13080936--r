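# Fluctuation correlation analysis and kinetic-rate extraction.

mat_traces <- function(m, dt) { attr(m, "time_s") <- (seq_len(nrow(m)) - 1) * dt; m }

test_that("constant traces are excluded and an all-constant set errors", {
  m <- mat_traces(matrix(5, 100, 4), 1)
  expect_error(autocorrelate(m), "no usable traces")
})

test_that("white-noise traces have G(0) = v / mu^2 and no lag correlation", {
  set.seed(61)
  mu <- 50; v <- 16
  m <- mat_traces(matrix(rnorm(400 * 60, mu, sqrt(v)), 400, 60), 1)
  res <- autocorrelate(m, max_lag_s = 20)
  expect_equal(res$g0_raw, v / mu^2, tolerance = 0.1)
  beyond <- abs(res$G[-1]) <= 3.5 * res$sem[-1] + 1e-12
  expect_gt(mean(beyond), 0.9)
})

test_that("scaling all traces leaves G unchanged", {
  set.seed(67)
  m <- matrix(rnorm(200 * 20, 30, 4), 200, 20)
  a <- autocorrelate(mat_traces(m, 2), max_lag_s = 30)
  b <- autocorrelate(mat_traces(7.5 * m, 2), max_lag_s = 30)
  expect_equal(a$G, b$G, tolerance = 1e-12)
})

test_that("OU traces recover their correlation time within 15%", {
  set.seed(71)
  theta <- 100; dt <- 1; n <- 360; ntr <- 200
  phi <- exp(-dt / theta); sd_eq <- 3; mu <- 30
  m <- matrix(0, n, ntr)
  for (j in seq_len(ntr)) {
    x <- numeric(n); x[1] <- rnorm(1, 0, sd_eq)
    for (i in 2:n) x[i] <- x[i - 1] * phi + rnorm(1, 0, sd_eq * sqrt(1 - phi^2))
    m[, j] <- mu + x
  }
  # all traces share one true mean, so ensemble normalization is unbiased
  res <- autocorrelate(mat_traces(m, dt), max_lag_s = 250,
                       normalization = "ensemble")
  pos <- res$G > 0 & res$lags_s <= 200
  fit <- lm(log(res$G[pos]) ~ res$lags_s[pos])
  theta_hat <- -1 / coef(fit)[[2]]
  expect_equal(theta_hat, theta, tolerance = 0.15)
})

test_that("a linear ramp G reaches zero exactly where expected under both conventions", {
  res <- structure(list(lags_s = 0:150, G = 1 - (0:150) / 100,
                        sem = rep(0, 151), n_pairs = rep(10, 151),
                        n_traces = 10, n_excluded = 0, g0_raw = 1,
                        g0_extrap = 1, dt_s = 1, baseline = 0,
                        two_sided = FALSE),
                   class = "correlation_result")
  expect_equal(decorrelation_time(res, method = "crossing"), 100)
  expect_equal(decorrelation_time(res, method = "intercept"), 100,
               tolerance = 1e-9)
  # interpolated crossing agrees with a fine-grid oracle
  g <- function(tau) cos(tau / 40)          # crosses at 40 * pi / 2
  lags <- seq(0, 100, by = 5)
  res2 <- res; res2$lags_s <- lags; res2$G <- g(lags)
  tau <- decorrelation_time(res2, method = "crossing")
  fine <- seq(0, 100, by = 0.05)
  oracle <- fine[which(g(fine) <= 0)[1]]
  expect_lt(abs(tau - oracle), 0.05 + 5 / 100)
  # no crossing -> error
  res3 <- res; res3$G <- rep(1, 151)
  expect_error(decorrelation_time(res3, method = "crossing"), "cross zero")
  expect_error(decorrelation_time(res3, method = "intercept"), "decay")
})

test_that("baseline correction removes a flat offset and leaves decaying tails alone", {
  lags <- 0:200
  ramp <- pmax(1 - lags / 80, 0)            # flat at 0 beyond tau_c
  res <- structure(list(lags_s = lags, G = ramp - 0.07, sem = rep(0, 201),
                        n_pairs = rep(10, 201), n_traces = 10,
                        n_excluded = 0, g0_raw = ramp[1] - 0.07,
                        g0_extrap = NA, dt_s = 1, baseline = 0,
                        two_sided = FALSE),
                   class = "correlation_result")
  corr <- correct_baseline(res)
  expect_equal(corr$baseline, -0.07, tolerance = 1e-9)
  expect_equal(corr$G, ramp, tolerance = 1e-9)
  expect_equal(decorrelation_time(corr), 80, tolerance = 0.01)
  # a still-decaying curve has no identifiable baseline: untouched
  res2 <- res; res2$G <- 1 - lags / 400
  expect_equal(correct_baseline(res2)$baseline, 0)
})

test_that("rate estimation reproduces the Poisson-occupancy relation", {
  est <- estimate_rates(g0 = 1, tau_c_s = 1)
  expect_equal(est$ki, 1)
  est2 <- estimate_rates(g0 = 0.08, tau_c_s = 380, L_eff = 1900)
  expect_equal(est2$ki, 1 / (0.08 * 380))
  expect_equal(est2$ke, 5.0)
  expect_error(estimate_rates(g0 = 0, tau_c_s = 10), "positive")
  expect_error(estimate_rates(g0 = -0.1, tau_c_s = 10), "positive")
})

test_that("simulated translation traces obey g0 ~ 1/(ki tau_c)", {
  p <- simulation_params(seed = 73, fov_yx = c(64, 64),
                         min_separation_px = 1)
  tr <- simulate_translation_traces(p)
  kin <- translation_kinetics(mat_traces(tr$intensity, 5), L_eff = p$L_eff,
                              max_lag_s = 1200)
  # g0 = 1/(ki tau_c) under Poisson loading, i.e. recovered ki ~ true ki
  expect_equal(kin$estimates$ki, p$ki, tolerance = 0.25)
})

test_that("kinetic parameter recovery holds across a ki/ke sweep", {
  # L_eff fixed at 1900 codons; 80 traces x 360 frames per condition
  for (cond in list(c(ki = 0.02, ke = 5), c(ki = 0.08, ke = 5),
                    c(ki = 0.04, ke = 10))) {
    p <- simulation_params(ki = cond[["ki"]], ke = cond[["ke"]],
                           L_total = 2000,
                           probe_positions = round(seq(10, 190, length.out = 10)),
                           n_spots = 240, seed = 79, fov_yx = c(64, 64),
                           min_separation_px = 1)
    tr <- simulate_translation_traces(p)
    kin <- translation_kinetics(mat_traces(tr$intensity, 5), L_eff = p$L_eff,
                                max_lag_s = 1200)
    expect_equal(kin$estimates$ke, cond[["ke"]], tolerance = 0.2)
    expect_equal(kin$estimates$ki, cond[["ki"]], tolerance = 0.2)
  }
})

test_that("cross-correlation peaks at the imposed delay and is antisymmetric in its arguments", {
  set.seed(83)
  n <- 300; ntr <- 30; shift <- 4; dt <- 2
  a <- matrix(rnorm(n * ntr, 20, 3), n, ntr)
  # smooth to create autocorrelation so the shifted peak is well defined
  for (j in 1:ntr) a[, j] <- stats::filter(a[, j], rep(1 / 5, 5),
                                           circular = TRUE)
  b <- rbind(a[(n - shift + 1):n, ], a[1:(n - shift), ])  # b(t) = a(t - shift)
  cc <- crosscorrelate(mat_traces(a, dt), mat_traces(b, dt), max_lag_s = 40)
  expect_equal(cc$peak_lag_s, shift * dt)
  # identical pairs peak at zero
  cc0 <- crosscorrelate(mat_traces(a, dt), mat_traces(a, dt), max_lag_s = 40)
  expect_equal(cc0$peak_lag_s, 0)
  # CC_AB(tau) = CC_BA(-tau)
  ab <- crosscorrelate(mat_traces(a, dt), mat_traces(b, dt), max_lag_s = 20)
  ba <- crosscorrelate(mat_traces(b, dt), mat_traces(a, dt), max_lag_s = 20)
  expect_equal(ab$G, rev(ba$G), tolerance = 1e-10)
})
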