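#' Build a single-spike calcium transient template
#'
#' Constructs the fluorescence kernel of one action potential: a linear rise
#' over `riseTime` followed by an exponential decay whose time constant is
#' chosen in closed form so that the continuous kernel's full width at half
#' maximum equals `fwhm` (half-max is crossed at `riseTime/2` on the way up
#' and at `riseTime + tau * log(2)` on the way down, so
#' `tau = (fwhm - riseTime/2) / log(2)`). The kernel is sampled at the frame
#' rate; `riseTime` is snapped to a whole number of frame periods so that a
#' sample lands exactly on the peak.
#'
#' @param peakAmplitude peak \eqn{\Delta F/F} fraction (> 0).
#' @param fwhm full width at half maximum, seconds (> riseTime/2). OGB-1
#'   single-spike transients are about 0.4 s wide.
#' @param frameRate imaging rate, Hz.
#' @param riseTime rise time, seconds; defaults to one frame period.
#' @param cutoff kernel is truncated once it decays below this fraction of
#'   the peak.
#' @return a [TransientTemplate-class].
#' @examples
#' tpl <- makeTemplate(0.05, fwhm = 0.4, frameRate = 10)
#' max(kernel(tpl))
#' @export
makeTemplate <- function(peakAmplitude, fwhm = 0.4, frameRate = 10,
                         riseTime = 1 / frameRate, cutoff = 0.01) {
    if (!is.numeric(peakAmplitude) || peakAmplitude <= 0)
        stop("peakAmplitude must be positive")
    if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be positive")
    if (!is.numeric(frameRate) || frameRate <= 0)
        stop("frameRate must be positive")
    riseFrames <- max(1L, as.integer(round(riseTime * frameRate)))
    riseTime <- riseFrames / frameRate
    if (fwhm <= riseTime / 2)
        stop("fwhm must exceed half the rise time (", riseTime / 2, " s)")
    tau <- (fwhm - riseTime / 2) / log(2)
    decayFrames <- as.integer(ceiling(tau * log(1 / cutoff) * frameRate))
    tt <- (0:(riseFrames + decayFrames)) / frameRate
    k <- ifelse(tt <= riseTime,
                peakAmplitude * tt / riseTime,
                peakAmplitude * exp(-(tt - riseTime) / tau))
    new("TransientTemplate", kernel = k, peakAmplitude = peakAmplitude,
        fwhm = fwhm, riseTime = riseTime, frameRate = frameRate)
}

#' @describeIn makeTemplate kernel samples of a template.
#' @param x a `TransientTemplate`.
#' @export
setMethod("kernel", "TransientTemplate", function(x) x@kernel)

#' @describeIn makeTemplate frame rate of a template.
#' @export
setMethod("frameRate", "TransientTemplate", function(x) x@frameRate)

#' Windowed response of a template insertion
#'
#' The per-trial \eqn{\Delta F/F} response that one inserted k-spike
#' transient contributes when the kernel starts at the first frame of the
#' response window: the mean of the first `windowResponse` seconds of the
#' kernel, times `k`. Useful as the ground-truth per-spike response when
#' validating linearity or amplitude recovery.
#'
#' @param template a [TransientTemplate-class].
#' @param windowResponse response window, seconds (default 0.4).
#' @param k spikes per insertion.
#' @return \eqn{\Delta F/F} fraction.
#' @export
templateResponse <- function(template, windowResponse = 0.4, k = 1) {
    wr <- windowFrames(windowResponse, template@frameRate)
    kk <- kernel(template)
    if (length(kk) < wr) kk <- c(kk, rep(0, wr - length(kk)))
    k * mean(kk[seq_len(wr)])
}

setMethod("show", "TransientTemplate", function(object) {
    cat("TransientTemplate:", length(object@kernel), "frames at",
        object@frameRate, "Hz\n")
    cat("  peak", object@peakAmplitude, "dF/F; FWHM", object@fwhm,
        "s; rise", object@riseTime, "s\n")
})
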