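# Ground-truth simulator: stochastic translation traces, Brownian spot
# motion, and two-channel movie rendering with photobleaching and noise.

#' Simulation parameters for synthetic translation movies
#'
#' Defines a two-channel (mRNA + nascent protein) synthetic movie. Defaults
#' reproduce the benchmark configuration used to validate the pipeline:
#' 360 frames at a 5-s interval, 512 x 512 pixels, 80 membrane-tethered mRNA
#' spots translating with initiation rate `ki = 0.04`/s and elongation rate
#' `ke = 5` codons/s, photobleaching at `kb = 0.001`/s in both channels.
#'
#' The epitope layout places `10` probes uniformly over the first 10% of the
#' open reading frame (an N-terminal tag array), so with `L_total = 2000`
#' codons the mean probe position is codon 100 and the effective
#' probe-to-termination length is `L_eff = L_total - mean(probe_positions)
#' = 1900` codons.
#'
#' @param ki Translation initiation rate, events/s (>= 0).
#' @param ke Elongation rate, codons/s (> 0).
#' @param L_total Construct length in codons (> 0).
#' @param probe_positions Ascending codon indices of the fluorescent epitopes.
#' @param n_spots Number of mRNA spots in the field.
#' @param n_frames Number of frames.
#' @param frame_interval_s Frame interval, seconds.
#' @param fov_yx Field of view `(rows, cols)` in pixels.
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels.
#' @param spot_amplitude Peak counts of a unit-intensity spot above background.
#' @param background_level Uniform background, counts.
#' @param read_noise_sd Gaussian camera read noise, counts.
#' @param bleach_rate Photobleaching decay rate(s) `kb` in 1/s; recycled to
#'   one value per channel.
#' @param diffusion_coeff_px2s Spot diffusion coefficient, px^2/s (>= 0);
#'   0 gives perfectly tethered, static spots.
#' @param fraction_translating Fraction of spots carrying nascent-protein
#'   signal; the remainder are mRNA-only spots.
#' @param min_separation_px Minimum distance between initial spot positions.
#' @param seed Integer seed governing all randomness of the simulation.
#' @return A validated list of class `sim_params` with the derived effective
#'   length in `$L_eff`.
#' @export
simulation_params <- function(ki = 0.04, ke = 5, L_total = 2000,
                              probe_positions = round(seq(10, 190, length.out = 10)),
                              n_spots = 80, n_frames = 360,
                              frame_interval_s = 5, fov_yx = c(512, 512),
                              psf_sigma_px = 1.3, spot_amplitude = 300,
                              background_level = 100, read_noise_sd = 2,
                              bleach_rate = 0.001,
                              diffusion_coeff_px2s = 0.005,
                              fraction_translating = 1,
                              min_separation_px = 12, seed = 1L) {
  stopifnot(ki >= 0, ke > 0, L_total > 0,
            all(probe_positions >= 1), all(probe_positions <= L_total),
            !is.unsorted(probe_positions),
            n_spots >= 1, n_frames >= 1, frame_interval_s > 0,
            length(fov_yx) == 2, all(fov_yx >= 8),
            psf_sigma_px > 0, spot_amplitude > 0, background_level >= 0,
            read_noise_sd >= 0, all(bleach_rate >= 0),
            diffusion_coeff_px2s >= 0,
            fraction_translating >= 0, fraction_translating <= 1)
  L_eff <- L_total - mean(probe_positions)
  if (L_eff <= 0) stop("effective length L_total - mean(probe_positions) must be > 0")
  structure(list(ki = ki, ke = ke, L_total = L_total,
                 probe_positions = probe_positions, n_spots = n_spots,
                 n_frames = n_frames, frame_interval_s = frame_interval_s,
                 fov_yx = fov_yx, psf_sigma_px = psf_sigma_px,
                 spot_amplitude = spot_amplitude,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 bleach_rate = rep(bleach_rate, length.out = 2),
                 diffusion_coeff_px2s = diffusion_coeff_px2s,
                 fraction_translating = fraction_translating,
                 min_separation_px = min_separation_px,
                 seed = as.integer(seed), L_eff = L_eff),
            class = "sim_params")
}

#' Simulate nascent-protein intensity traces
#'
#' Ribosome initiations on each mRNA are a homogeneous Poisson process with
#' rate `ki`; each ribosome advances deterministically at `ke` codons/s and
#' terminates at `L_total`. The normalized nascent intensity of a spot at
#' time `t` is the sum over elongating ribosomes of the fraction of probes
#' already translated, i.e. `#(probe_positions <= position) / n_probes`, so a
#' completed protein contributes 1 "unit of mature protein". The process is
#' initialized in steady state (initiations start one full transit time
#' before frame 1). Ribosomes are points: no exclusion, no pausing.
#'
#' @param params A [simulation_params()] object.
#' @return A list with `intensity` (`n_frames x n_spots` matrix of normalized
#'   intensities), `ribosomes` (matrix of concurrent ribosome counts), and
#'   `translating` (logical per spot).
#' @export
simulate_translation_traces <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  tt <- (seq_len(params$n_frames) - 1) * params$frame_interval_s
  transit <- params$L_total / params$ke
  t_end <- max(tt)
  nprobe <- length(params$probe_positions)
  intensity <- matrix(0, params$n_frames, params$n_spots)
  ribosomes <- matrix(0L, params$n_frames, params$n_spots)
  n_tr <- round(params$fraction_translating * params$n_spots)
  translating <- seq_len(params$n_spots) <= n_tr
  for (s in seq_len(params$n_spots)) {
    if (!translating[s] || params$ki == 0) next
    set.seed(derive_seed(params$seed, paste0("traces", s)))
    span <- t_end + transit
    n_init <- rpois(1, params$ki * span)
    if (n_init == 0) next
    t0 <- sort(runif(n_init, -transit, t_end))
    pos <- params$ke * outer(tt, t0, "-")       # codon position per (frame, ribosome)
    active <- pos >= 0 & pos < params$L_total
    done <- matrix(findInterval(pos, params$probe_positions),
                   nrow = length(tt))           # probes completed
    intensity[, s] <- rowSums(active * done) / nprobe
    ribosomes[, s] <- as.integer(rowSums(active))
  }
  list(intensity = intensity, ribosomes = ribosomes, translating = translating)
}

#' Simulate spot positions (tethered / Brownian motion)
#'
#' Initial positions are drawn uniformly with a margin from the field border
#' and a minimum pairwise separation (rejection sampling). Subsequent frames
#' take independent Gaussian steps with per-axis variance `2 * D * dt`,
#' reflected at the field boundaries. `D = 0` yields static, tethered spots.
#'
#' @param params A [simulation_params()] object.
#' @return Numeric array `(n_frames, n_spots, 2)` of `(y, x)` positions in
#'   1-based pixel-centre coordinates.
#' @export
simulate_positions <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  fov <- params$fov_yx
  margin <- max(4 * params$psf_sigma_px, 6)
  set.seed(derive_seed(params$seed, "positions"))
  init <- matrix(NA_real_, params$n_spots, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 20000L
  while (placed < params$n_spots) {
    cand <- c(runif(1, 1 + margin, fov[1] - margin),
              runif(1, 1 + margin, fov[2] - margin))
    ok <- placed == 0L ||
      min(sqrt(rowSums((init[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2))) >=
        params$min_separation_px
    if (ok) {
      placed <- placed + 1L
      init[placed, ] <- cand
    }
    tries <- tries + 1L
    if (tries > max_tries)
      stop("field too small to place ", params$n_spots,
           " spots at minimum separation ", params$min_separation_px, " px")
  }
  pos <- array(0, c(params$n_frames, params$n_spots, 2))
  pos[1, , ] <- init
  if (params$n_frames > 1) {
    step_sd <- sqrt(2 * params$diffusion_coeff_px2s * params$frame_interval_s)
    for (s in seq_len(params$n_spots)) {
      set.seed(derive_seed(params$seed, paste0("motion", s)))
      steps <- matrix(rnorm(2 * (params$n_frames - 1), 0, step_sd),
                      ncol = 2)
      cum <- apply(steps, 2, cumsum)
      if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1)
      traj <- rbind(init[s, ], sweep(cum, 2, init[s, ], "+"))
      traj[, 1] <- reflect_into(traj[, 1], 1, fov[1])
      traj[, 2] <- reflect_into(traj[, 2], 1, fov[2])
      pos[, s, ] <- traj
    }
  }
  pos
}

# Reflect coordinates into [lo, hi] (folded / billiard boundary).
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

# Add a Gaussian spot of given peak amplitude to `frame` in place (window
# limited to +/- 4 sigma); returns the modified frame.
add_gaussian_spot <- function(frame, y, x, amplitude, sigma) {
  r <- ceiling(4 * sigma)
  ys <- max(1, floor(y - r)):min(nrow(frame), ceiling(y + r))
  xs <- max(1, floor(x - r)):min(ncol(frame), ceiling(x + r))
  if (!length(ys) || !length(xs)) return(frame)
  g <- amplitude * exp(-(outer((ys - y)^2, (xs - x)^2, "+")) / (2 * sigma^2))
  frame[ys, xs] <- frame[ys, xs] + g
  frame
}

#' Render a two-channel synthetic movie
#'
#' Channel 1 (mRNA) renders every spot as a 2D Gaussian of unit intensity;
#' channel 2 (nascent protein) scales the Gaussian by the spot's normalized
#' trace value. Per frame, the spot signal is multiplied by
#' `exp(-kb * t)` (photobleaching; the background does not bleach), the
#' uniform background is added, Poisson shot noise is applied, Gaussian read
#' noise is added, and the result is rounded and clipped to 16 bits.
#' Deterministic given `params$seed`.
#'
#' @param traces Output of [simulate_translation_traces()].
#' @param positions Output of [simulate_positions()].
#' @param params A [simulation_params()] object.
#' @return A list with `movie` (a [movie_stack()], channels `"mRNA"` and
#'   `"nascent"`) and `truth` (data frame: `frame`, `spot_id`, `y_px`,
#'   `x_px`, `intensity_norm`, `translating`).
#' @export
render_movie <- function(traces, positions, params) {
  stopifnot(inherits(params, "sim_params"))
  nT <- params$n_frames; fov <- params$fov_yx
  stopifnot(nrow(traces$intensity) == nT, dim(positions)[1] == nT,
            ncol(traces$intensity) == dim(positions)[2])
  nS <- ncol(traces$intensity)
  tt <- (seq_len(nT) - 1) * params$frame_interval_s
  data <- array(0L, c(nT, 2, fov[1], fov[2]))
  noisy <- params$background_level > 0 || params$read_noise_sd > 0
  for (t in seq_len(nT)) {
    for (ch in 1:2) {
      frame <- matrix(0, fov[1], fov[2])
      vals <- if (ch == 1) rep(1, nS) else traces$intensity[t, ]
      bleach <- exp(-params$bleach_rate[ch] * tt[t])
      for (s in seq_len(nS)) {
        v <- vals[s]
        if (v <= 0) next
        frame <- add_gaussian_spot(frame, positions[t, s, 1],
                                   positions[t, s, 2],
                                   params$spot_amplitude * v * bleach,
                                   params$psf_sigma_px)
      }
      frame <- frame + params$background_level
      if (noisy) {
        set.seed(derive_seed(params$seed, paste0("noise", t, "_", ch)))
        n <- length(frame)
        frame <- rpois(n, pmax(frame, 0)) +
          rnorm(n, 0, params$read_noise_sd)
      }
      data[t, ch, , ] <- as.integer(pmin(pmax(round(frame), 0), 65535))
    }
  }
  movie <- movie_stack(data, frame_interval_s = params$frame_interval_s,
                       channel_names = c("mRNA", "nascent"))
  truth <- data.frame(
    frame = rep(seq_len(nT), nS),
    spot_id = rep(seq_len(nS), each = nT),
    y_px = as.vector(positions[, , 1]),
    x_px = as.vector(positions[, , 2]),
    intensity_norm = as.vector(traces$intensity),
    translating = rep(traces$translating, each = nT))
  list(movie = movie, truth = truth)
}

#' Simulate a complete synthetic translation movie
#'
#' Convenience wrapper chaining [simulate_translation_traces()],
#' [simulate_positions()] and [render_movie()].
#'
#' @param params A [simulation_params()] object.
#' @return As [render_movie()], plus `params` and the raw `traces`.
#' @export
simulate_movie <- function(params = simulation_params()) {
  traces <- simulate_translation_traces(params)
  positions <- simulate_positions(params)
  out <- render_movie(traces, positions, params)
  out$params <- params
  out$traces <- traces
  out
}

#' The packaged benchmark movie
#'
#' Generates the standard validation configuration: 360 frames at a 5-s
#' interval, two channels, 512 x 512 pixels, 80 mRNA spots, `ki = 0.04`/s,
#' `ke = 5` codons/s, `L_eff = 1900` codons, photobleaching `kb = 0.001`/s.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [simulation_params()].
#' @return As [simulate_movie()].
#' @export
benchmark_fixture <- function(seed = 1L, ...) {
  simulate_movie(simulation_params(seed = seed, ...))
}
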