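#' Canonical double-gamma hemodynamic response function
#'
#' Samples the standard double-gamma HRF (positive gamma peaking ~5 s after
#' onset, delayed undershoot) on a regular time grid. The kernel is scaled
#' analytically so the full impulse response integrates to 1; a sustained
#' block regressor built from it therefore plateaus near 1 and condition
#' betas read directly as sustained response amplitudes.
#'
#' The two gamma components use shape `peakDelay` and `undershootDelay` with
#' rate 1, so the positive lobe's mode sits at `peakDelay - 1` seconds.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param peakDelay shape of the response gamma (default 6; mode at 5 s).
#' @param undershootDelay shape of the undershoot gamma (default 16).
#' @param undershootRatio weight of the undershoot (default 1/6).
#' @param lengthSeconds kernel support in seconds (default 32).
#' @return numeric kernel sampled at `dt`, with attributes `dt` and `times`.
#' @examples
#' h <- hrfKernel(0.1)
#' attr(h, "times")[which.max(h)]  # ~5 s
#' @export
hrfKernel <- function(dt, peakDelay = 6, undershootDelay = 16,
                      undershootRatio = 1 / 6, lengthSeconds = 32) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive duration in seconds")
  if (undershootRatio < 0 || undershootRatio >= 1)
    stop("undershootRatio must be in [0, 1)")
  t <- seq(0, lengthSeconds, by = dt)
  h <- dgamma(t, shape = peakDelay, rate = 1) -
    undershootRatio * dgamma(t, shape = undershootDelay, rate = 1)
  h <- h / (1 - undershootRatio)  # analytic unit integral, grid-independent
  attr(h, "dt") <- dt
  attr(h, "times") <- t
  h
}
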