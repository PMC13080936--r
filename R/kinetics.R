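# Fluctuation correlation analysis of intensity traces and extraction of
# translation kinetic parameters (de-correlation time, elongation and
# initiation rates).

as_trace_matrix <- function(traces) {
  if (is.matrix(traces)) {
    if (is.null(attr(traces, "time_s")))
      stop("trace matrix needs a 'time_s' attribute (or use intensity_traces)")
    return(traces)
  }
  if (is.data.frame(traces)) return(traces_matrix(traces))
  stop("traces must be an intensity_traces data frame or a frames x tracks matrix")
}

#' Fluctuation autocorrelation of intensity traces
#'
#' For each trace, `G_i(tau) = <dI(t) dI(t + tau)> / mu^2` with
#' `dI = I - mu`; missing points are excluded pairwise. `G` is the
#' across-trace mean with its standard error. By default `mu` is each
#' trace's own mean (`normalization = "trace"`), which cancels
#' spot-to-spot brightness variation; `normalization = "ensemble"` uses the
#' grand mean over all usable traces instead.
#'
#' Subtracting an estimated mean biases the estimated `G` by an additive
#' offset of order `-2 tau_c / T` (trace normalization, downward) or
#' `+Var(trace means) / mu^2` (ensemble normalization, upward) when the
#' de-correlation time is a sizeable fraction of the trace length, as it is
#' for translation-site data. Because the offset is flat in the lag, it is
#' removed by [correct_baseline()] before kinetic quantities are extracted;
#' [translation_kinetics()] does this automatically.
#'
#' Zero-variance traces are excluded (their count is reported); if all
#' traces are excluded an error is raised. `g0_extrap` extrapolates lags
#' 1..3 linearly back to lag 0, excluding the uncorrelated shot-noise spike
#' that inflates the raw `G(0)`.
#'
#' @param traces An `intensity_traces` data frame (see [extract_traces()]) or
#'   a frames x tracks matrix with a `"time_s"` attribute; sampling must be
#'   uniform.
#' @param max_lag_s Largest lag evaluated, seconds (default: half the trace
#'   length).
#' @param min_points Minimum resolved points required per trace.
#' @param normalization `"trace"` (default) or `"ensemble"`; see Details.
#' @return Object of class `correlation_result`: `lags_s`, `G`, `sem`,
#'   `n_pairs`, `n_traces`, `n_excluded`, `g0_raw`, `g0_extrap`, `dt_s`,
#'   `baseline` (0 until [correct_baseline()] is applied).
#' @export
autocorrelate <- function(traces, max_lag_s = NULL, min_points = 20,
                          normalization = c("trace", "ensemble")) {
  normalization <- match.arg(normalization)
  m <- as_trace_matrix(traces)
  tt <- attr(m, "time_s")
  dt <- diff(tt)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("autocorrelation requires uniform sampling")
  dt <- if (length(dt)) dt[1] else 1
  npts <- colSums(!is.na(m))
  vars <- apply(m, 2, var, na.rm = TRUE)
  usable <- npts >= min_points & !is.na(vars) & vars > 0
  n_excluded <- sum(!usable)
  if (!any(usable))
    stop("no usable traces: all have zero variance or fewer than ",
         min_points, " resolved points")
  m <- m[, usable, drop = FALSE]
  max_lag <- floor((max_lag_s %||% (nrow(m) * dt / 2)) / dt)
  max_lag <- min(max_lag, nrow(m) - 2)
  lags <- 0:max_lag
  grand_mu <- mean(m, na.rm = TRUE)
  gi <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    mu <- if (normalization == "trace") mean(x, na.rm = TRUE) else grand_mu
    d <- x - mu
    vapply(lags, function(L) {
      a <- d[seq_len(length(d) - L)]
      b <- d[seq_len(length(d) - L) + L]
      mean(a * b, na.rm = TRUE) / mu^2
    }, numeric(1))
  }, numeric(length(lags)))
  gi <- matrix(gi, nrow = length(lags))
  G <- rowMeans(gi, na.rm = TRUE)
  sem <- apply(gi, 1, sd, na.rm = TRUE) / sqrt(ncol(gi))
  npairs <- vapply(lags, function(L) {
    sum(vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      sum(!is.na(x[seq_len(length(x) - L)]) &
            !is.na(x[seq_len(length(x) - L) + L]))
    }, numeric(1)))
  }, numeric(1))
  g0_extrap <- if (length(G) >= 4) {
    fit <- lm(g ~ l, data = data.frame(g = G[2:4], l = lags[2:4] * dt))
    unname(coef(fit)[1])
  } else NA_real_
  structure(list(lags_s = lags * dt, G = G, sem = sem, n_pairs = npairs,
                 n_traces = ncol(m), n_excluded = n_excluded,
                 g0_raw = G[1], g0_extrap = g0_extrap, dt_s = dt,
                 baseline = 0, two_sided = FALSE),
            class = "correlation_result")
}

#' Remove the finite-trace baseline offset of an autocorrelation
#'
#' Mean-subtracted fluctuation ACFs computed from traces of finite length `T`
#' carry a lag-independent offset (about `-2 tau_c / T * G(0)` for per-trace
#' normalization). Because a fully de-correlated process is flat at long
#' lags, the offset is estimated as the mean of `G` over the last
#' `tail_fraction` of the lag range and subtracted -- but only when that tail
#' is actually flat (its slope below `flat_ratio` times the initial decay
#' slope), so curves that are still decaying at the longest lag, where no
#' baseline is identifiable, are left untouched. `g0_raw`/`g0_extrap` are
#' recomputed after subtraction.
#'
#' @param result A one-sided `correlation_result` from [autocorrelate()].
#' @param tail_fraction Fraction of the longest lags used as the baseline
#'   window; the window must lie beyond the de-correlation time.
#' @param flat_ratio Tail-to-initial slope ratio under which the tail counts
#'   as flat.
#' @return The corrected `correlation_result`, with the subtracted offset in
#'   `$baseline`.
#' @export
correct_baseline <- function(result, tail_fraction = 0.25, flat_ratio = 0.2) {
  stopifnot(inherits(result, "correlation_result"), !result$two_sided,
            tail_fraction > 0, tail_fraction < 1)
  lags <- result$lags_s; G <- result$G
  tail_i <- which(lags >= (1 - tail_fraction) * max(lags))
  head_i <- 2:min(6, length(G))
  if (length(tail_i) < 3 || length(head_i) < 3) return(result)
  s_tail <- coef(lm(G[tail_i] ~ lags[tail_i]))[[2]]
  s_head <- coef(lm(G[head_i] ~ lags[head_i]))[[2]]
  if (abs(s_tail) >= flat_ratio * abs(s_head)) return(result)
  base <- mean(G[tail_i])
  result$G <- G - base
  result$baseline <- result$baseline + base
  result$g0_raw <- result$G[1]
  if (length(result$G) >= 4) {
    fit <- lm(g ~ l, data = data.frame(g = result$G[2:4], l = lags[2:4]))
    result$g0_extrap <- unname(coef(fit)[1])
  }
  result
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "correlation_result: %d traces, lags %s..%s s (dt = %g s)\n",
    x$n_traces, min(x$lags_s), max(x$lags_s), x$dt_s))
  cat(sprintf("  G(0) raw = %.4g, extrapolated = %.4g\n",
              x$g0_raw, x$g0_extrap))
  invisible(x)
}

#' Convert a correlation result to a data frame
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return Data frame `lag_s`, `G`, `sem`, `n_pairs` (the `correlation.csv`
#'   schema).
#' @export
as.data.frame.correlation_result <- function(x, ...) {
  data.frame(lag_s = x$lags_s, G = x$G, sem = x$sem, n_pairs = x$n_pairs)
}

#' De-correlation time of a mean autocorrelation
#'
#' For nascent-protein traces the de-correlation time equals the mean
#' ribosome transit time from the average probe position to termination. Two
#' conventions are offered:
#'
#' * `method = "intercept"` (default): the zero intercept of a straight line
#'   fitted to the initial decay of `G` (positive lags down to where `G`
#'   first falls below `ramp_cut` times its first-lag value). The ACF of a
#'   translation site decays almost linearly over most of its range and then
#'   bends into a shallow foot; the intercept uses the steep, well-estimated
#'   part and is insensitive to noise in the foot, where a literal crossing
#'   wanders by hundreds of seconds at realistic trace counts. Apply
#'   [correct_baseline()] first so the line is referenced to the true zero.
#' * `method = "crossing"`: the first zero crossing of `G` at positive lag,
#'   located by linear interpolation between the bracketing lags.
#'
#' Both conventions agree exactly when `G` is a linear ramp.
#'
#' @param result A `correlation_result` from [autocorrelate()], baseline
#'   corrected for kinetic use.
#' @param method `"intercept"` or `"crossing"`.
#' @param ramp_cut Fraction of the first-lag `G` at which the initial-decay
#'   fit window ends (intercept method).
#' @return The de-correlation time `tau_c` in seconds.
#' @export
decorrelation_time <- function(result, method = c("intercept", "crossing"),
                               ramp_cut = 0.15) {
  stopifnot(inherits(result, "correlation_result"), !result$two_sided)
  method <- match.arg(method)
  lags <- result$lags_s; G <- result$G
  pos <- which(lags > 0)
  if (method == "crossing") {
    for (k in pos) {
      if (G[k] <= 0) {
        if (k == pos[1]) return(lags[k])
        g1 <- G[k - 1]; g2 <- G[k]
        if (g2 == g1) return(lags[k])
        return(lags[k - 1] + (lags[k] - lags[k - 1]) * g1 / (g1 - g2))
      }
    }
    stop("the autocorrelation does not cross zero within the lag range; ",
         "use longer traces or a larger max_lag_s")
  }
  g1 <- G[pos[1]]
  if (!is.finite(g1) || g1 <= 0)
    stop("the autocorrelation is not positive at the first lag; ",
         "cannot fit the initial decay")
  below <- which(G[pos] < ramp_cut * g1)
  end <- if (length(below)) pos[below[1]] - 1L else pos[length(pos)]
  ramp <- pos[1]:max(end, pos[1] + 2L)
  fit <- lm(g ~ l, data = data.frame(g = G[ramp], l = lags[ramp]))
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope >= 0)
    stop("the autocorrelation does not decay over the fit window; ",
         "use longer traces or a larger max_lag_s")
  tau <- -coef(fit)[[1]] / slope
  if (tau <= 0 || tau > max(lags) * 1.5)
    stop("de-correlation time outside the lag range; increase max_lag_s")
  tau
}

#' Kinetic rates from correlation amplitude and de-correlation time
#'
#' Under steady-state Poisson loading of ribosomes, the zero-lag fluctuation
#' amplitude scales as the inverse of the number of independent emitters, so
#' the initiation rate is `ki = 1 / (G(0) * tau_c)` and the elongation rate
#' is `ke = L_eff / tau_c`, with `L_eff` the effective probe-to-termination
#' length in codons.
#'
#' @param g0 Zero-lag autocorrelation amplitude (> 0), raw or extrapolated.
#' @param tau_c_s De-correlation time, seconds (> 0).
#' @param L_eff Effective construct length in codons (user-supplied; optional
#'   -- without it only `ki` is computed).
#' @return Object of class `kinetic_estimates`: `ki` (1/s), `ke` (codons/s or
#'   `NA`), `tau_c_s`, `g0`, `L_eff`.
#' @export
estimate_rates <- function(g0, tau_c_s, L_eff = NULL) {
  if (!is.numeric(g0) || g0 <= 0)
    stop("g0 must be positive to estimate an initiation rate")
  stopifnot(tau_c_s > 0, is.null(L_eff) || L_eff > 0)
  structure(list(ki = 1 / (g0 * tau_c_s),
                 ke = if (is.null(L_eff)) NA_real_ else L_eff / tau_c_s,
                 tau_c_s = tau_c_s, g0 = g0, L_eff = L_eff %||% NA_real_),
            class = "kinetic_estimates")
}

#' @export
print.kinetic_estimates <- function(x, ...) {
  cat(sprintf(
    "kinetic_estimates: ki = %.4g 1/s, ke = %.4g codons/s (tau_c = %.4g s, G0 = %.4g, L_eff = %.4g)\n",
    x$ki, x$ke, x$tau_c_s, x$g0, x$L_eff))
  invisible(x)
}

#' Full correlation-based kinetic analysis with bootstrap intervals
#'
#' Chains [autocorrelate()], [correct_baseline()], [decorrelation_time()]
#' and [estimate_rates()], and bootstraps the whole chain over traces for
#' confidence intervals.
#'
#' @param traces As [autocorrelate()].
#' @param L_eff Effective length in codons.
#' @param max_lag_s Largest lag, seconds; should be at least about 2.5 times
#'   the expected de-correlation time so the baseline window is flat.
#' @param g0_choice `"extrap"` (shot-noise corrected, default) or `"raw"`.
#' @param normalization Passed to [autocorrelate()].
#' @param tau_method Passed to [decorrelation_time()].
#' @param n_boot Bootstrap replicates over traces (0 to skip).
#' @param conf Confidence level.
#' @param seed Bootstrap seed.
#' @return List: `estimates` (a `kinetic_estimates`), `correlation` (the
#'   baseline-corrected `correlation_result`), `ci` (named list of `ki`,
#'   `ke`, `tau_c_s` intervals or `NULL`).
#' @export
translation_kinetics <- function(traces, L_eff, max_lag_s = NULL,
                                 g0_choice = c("extrap", "raw"),
                                 normalization = c("trace", "ensemble"),
                                 tau_method = c("intercept", "crossing"),
                                 n_boot = 0, conf = 0.95, seed = 1L) {
  g0_choice <- match.arg(g0_choice)
  normalization <- match.arg(normalization)
  tau_method <- match.arg(tau_method)
  m <- as_trace_matrix(traces)
  chain <- function(mm) {
    r <- correct_baseline(autocorrelate(mm, max_lag_s = max_lag_s,
                                        normalization = normalization))
    tau <- decorrelation_time(r, method = tau_method)
    g0 <- if (g0_choice == "raw") r$g0_raw else r$g0_extrap
    list(res = r, tau = tau, est = estimate_rates(g0, tau, L_eff))
  }
  full <- chain(m)
  ci <- NULL
  if (n_boot > 0 && ncol(m) > 1) {
    set.seed(derive_seed(seed, "kinboot"))
    draws <- matrix(NA_real_, n_boot, 3)
    for (i in seq_len(n_boot)) {
      mb <- m[, sample(ncol(m), replace = TRUE), drop = FALSE]
      attr(mb, "time_s") <- attr(m, "time_s")
      ok <- try({
        b <- chain(mb)
        draws[i, ] <- c(b$est$ki, b$est$ke, b$tau)
      }, silent = TRUE)
    }
    a <- (1 - conf) / 2
    qs <- apply(draws, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
    ci <- list(ki = qs[, 1], ke = qs[, 2], tau_c_s = qs[, 3])
  }
  list(estimates = full$est, correlation = full$res, ci = ci)
}

#' Fluctuation cross-correlation between paired trace sets
#'
#' `CC(tau) = <dA(t) dB(t + tau)> / (<A> <B>)` per pair, averaged across
#' pairs, over two-sided lags. The lag of the peak mean correlation is
#' reported; for `B` equal to `A` delayed by `k` frames the peak falls at
#' `+k * dt`. `CC_AB(tau) = CC_BA(-tau)`.
#'
#' @param traces_a,traces_b Paired traces (same dimensions and time base):
#'   `intensity_traces` data frames or matrices; column `j` of `a` is paired
#'   with column `j` of `b`.
#' @param max_lag_s Largest absolute lag, seconds.
#' @param min_points Minimum resolved points per trace.
#' @return A `correlation_result` with two-sided `lags_s` and an extra
#'   `peak_lag_s` field (`g0_*` refer to lag 0).
#' @export
crosscorrelate <- function(traces_a, traces_b, max_lag_s = NULL,
                           min_points = 20) {
  a <- as_trace_matrix(traces_a); b <- as_trace_matrix(traces_b)
  if (!all(dim(a) == dim(b)))
    stop("paired trace sets must have identical dimensions")
  tt <- attr(a, "time_s")
  dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
  usable <- vapply(seq_len(ncol(a)), function(j) {
    xa <- a[, j]; xb <- b[, j]
    sum(!is.na(xa)) >= min_points && sum(!is.na(xb)) >= min_points &&
      var(xa, na.rm = TRUE) > 0 && var(xb, na.rm = TRUE) > 0
  }, logical(1))
  if (!any(usable)) stop("no usable trace pairs")
  a <- a[, usable, drop = FALSE]; b <- b[, usable, drop = FALSE]
  max_lag <- floor((max_lag_s %||% (nrow(a) * dt / 2)) / dt)
  max_lag <- min(max_lag, nrow(a) - 2)
  lags <- (-max_lag):max_lag
  cc <- vapply(seq_len(ncol(a)), function(j) {
    xa <- a[, j]; xb <- b[, j]
    mua <- mean(xa, na.rm = TRUE); mub <- mean(xb, na.rm = TRUE)
    da <- xa - mua; db <- xb - mub
    n <- length(da)
    vapply(lags, function(L) {
      if (L >= 0) {
        u <- da[seq_len(n - L)]; v <- db[seq_len(n - L) + L]
      } else {
        u <- da[seq_len(n + L) - L]; v <- db[seq_len(n + L)]
      }
      mean(u * v, na.rm = TRUE) / (mua * mub)
    }, numeric(1))
  }, numeric(length(lags)))
  cc <- matrix(cc, nrow = length(lags))
  G <- rowMeans(cc, na.rm = TRUE)
  sem <- apply(cc, 1, sd, na.rm = TRUE) / sqrt(ncol(cc))
  i0 <- which(lags == 0)
  structure(list(lags_s = lags * dt, G = G, sem = sem,
                 n_pairs = rep(NA_integer_, length(lags)),
                 n_traces = ncol(a), n_excluded = sum(!usable),
                 g0_raw = G[i0], g0_extrap = NA_real_, dt_s = dt,
                 baseline = 0, two_sided = TRUE,
                 peak_lag_s = lags[which.max(G)] * dt),
            class = "correlation_result")
}
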