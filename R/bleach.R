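# Photobleaching: exponential decay estimation and correction.

#' Fit an exponential photobleaching model
#'
#' Fits `I(t) = A * exp(-kb * t) + offset` to the per-frame mean intensity of
#' one channel (inside `mask` if given, else the whole frame) by nonlinear
#' least squares. The fit is initialized from a log-linear regression of the
#' offset-subtracted means, with the offset initialized at the 1st percentile
#' of the per-frame means; the offset term absorbs non-bleaching background
#' such as camera offset.
#'
#' @param movie A [movie_stack()] (>= 10 frames).
#' @param channel Channel index to fit.
#' @param mask Optional label matrix `(Y, X)`; pixels with label > 0 define
#'   the region whose mean is fitted (e.g. dilated spot regions, so the decay
#'   is measured where there is signal rather than diluted over background).
#' @return An object of class `bleach_model`: `amplitude`, `kb` (1/s, >= 0),
#'   `offset`, `fit_r2`, and `constant` (`TRUE` when the input had zero
#'   variance, in which case `kb = 0`).
#' @export
fit_bleach <- function(movie, channel = 1L, mask = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  nT <- n_frames(movie)
  if (nT < 10) stop("photobleach fitting needs at least 10 frames")
  if (!is.null(mask)) {
    stopifnot(all(dim(mask)[1:2] == dim(movie$data)[3:4]))
    sel <- mask > 0
    if (!any(sel)) stop("mask selects no pixels")
  }
  means <- vapply(seq_len(nT), function(t) {
    pl <- get_plane(movie, t, channel)
    if (is.null(mask)) mean(pl) else mean(pl[sel])
  }, numeric(1))
  tt <- frame_times(movie)
  if (var(means) == 0) {
    return(structure(list(amplitude = 0, kb = 0, offset = means[1],
                          fit_r2 = 1, constant = TRUE),
                     class = "bleach_model"))
  }
  offset0 <- as.numeric(quantile(means, 0.01))
  pos <- pmax(means - offset0, max(means - offset0) * 1e-6)
  ll <- lm(log(pos) ~ tt)
  kb0 <- max(-coef(ll)[[2]], 1e-8)
  a0 <- exp(coef(ll)[[1]])
  fit <- try(minpack.lm::nlsLM(
    means ~ A * exp(-kb * tt) + c0,
    start = list(A = a0, kb = kb0, c0 = max(offset0, 0)),
    lower = c(A = 0, kb = 0, c0 = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # fall back to the log-linear estimate
    pars <- c(A = a0, kb = kb0, c0 = max(offset0, 0))
  } else {
    pars <- coef(fit)
  }
  pred <- pars[["A"]] * exp(-pars[["kb"]] * tt) + pars[["c0"]]
  r2 <- 1 - sum((means - pred)^2) / sum((means - mean(means))^2)
  kb <- max(pars[["kb"]], 0)
  # a decay amplitude indistinguishable from the residual scatter carries no
  # information about kb (e.g. an already-corrected movie): report no decay
  if (pars[["A"]] < 3 * sd(means - pred)) kb <- 0
  structure(list(amplitude = pars[["A"]], kb = kb,
                 offset = pars[["c0"]], fit_r2 = r2, constant = FALSE),
            class = "bleach_model")
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf("bleach_model: I(t) = %.4g * exp(-%.4g t) + %.4g  (R2 = %.4f)\n",
              x$amplitude, x$kb, x$offset, x$fit_r2))
  invisible(x)
}

#' Evaluate a bleach model
#'
#' @param model A `bleach_model`.
#' @param t Times in seconds.
#' @return `amplitude * exp(-kb * t) + offset`.
#' @export
predict_bleach <- function(model, t) {
  model$amplitude * exp(-model$kb * t) + model$offset
}

#' Correct a channel for photobleaching
#'
#' Rescales the signal above the model offset by `exp(+kb * t)` frame by
#' frame: `out = (I - offset) * exp(kb * t) + offset`, rounded and clipped to
#' 16 bits. Only signal above the offset is rescaled because non-bleaching
#' background (camera offset) must not be amplified. Other channels are
#' untouched. The number of pixels clipped at 65535 is returned in the
#' `"clipped_px"` attribute (also recorded by the pipeline metadata).
#'
#' @param movie A [movie_stack()].
#' @param model A `bleach_model` with `kb >= 0`.
#' @param channel Channel index to correct.
#' @return A corrected [movie_stack()].
#' @export
correct_bleach <- function(movie, model, channel = 1L) {
  stopifnot(inherits(movie, "movie_stack"), inherits(model, "bleach_model"),
            model$kb >= 0)
  if (model$kb == 0) {
    attr(movie, "clipped_px") <- 0L
    return(movie)
  }
  tt <- frame_times(movie)
  clipped <- 0L
  for (t in seq_len(n_frames(movie))) {
    pl <- matrix(movie$data[t, channel, , ], dim(movie$data)[3])
    out <- (pl - model$offset) * exp(model$kb * tt[t]) + model$offset
    clipped <- clipped + sum(out > 65535)
    movie$data[t, channel, , ] <- as.integer(pmin(pmax(round(out), 0), 65535))
  }
  attr(movie, "clipped_px") <- clipped
  movie
}
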