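#' Per-trial stimulus response of one trace
#'
#' The fractional fluorescence change of one trial,
#' \eqn{\Delta F/F = F_s / F_b - 1}, where \eqn{F_s} is the mean
#' fluorescence over `windowResponse` seconds starting right at the pulse
#' offset and \eqn{F_b} the mean over the `windowBaseline` seconds
#' immediately before the pulse onset. Window lengths are converted to whole
#' frames by rounding (minimum one frame); onset/offset times map to the
#' nearest frame at or after the stated time. The ratio form makes the
#' response invariant to rescaling the whole trace, so raw fluorescence and
#' baseline-normalised traces give identical results.
#'
#' @param trace numeric fluorescence trace (positive values).
#' @param frameRate Hz.
#' @param onset,offset pulse times, seconds.
#' @param windowResponse response window, seconds (default 0.4).
#' @param windowBaseline baseline window, seconds (default 0.6).
#' @return \eqn{\Delta F/F} fraction.
#' @examples
#' tr <- rep(1, 100); tr[51:60] <- 1.02
#' trialResponse(tr, 10, onset = 4.5, offset = 5.0)
#' @export
trialResponse <- function(trace, frameRate, onset, offset,
                          windowResponse = 0.4, windowBaseline = 0.6) {
    wr <- windowFrames(windowResponse, frameRate)
    wb <- windowFrames(windowBaseline, frameRate)
    onIdx <- timeToFrame(onset, frameRate)
    offIdx <- timeToFrame(offset, frameRate)
    if (onIdx - wb < 0L || offIdx + wr > length(trace))
        stop("trial at onset ", onset, " s does not fit in the trace ",
             "with full baseline and response windows")
    fb <- mean(trace[(onIdx - wb + 1L):onIdx])
    if (fb <= 0) stop("degenerate baseline (mean <= 0) for trial at onset ",
                      onset, " s")
    fs <- mean(trace[(offIdx + 1L):(offIdx + wr)])
    fs / fb - 1
}

#' Extract the per-trial response distribution R of every cell
#'
#' Applies [trialResponse()] to every cell and trial of a recording. Trials
#' whose windows fall outside the trace are an error (never silently
#' dropped), so the returned matrix always has one column per scheduled
#' trial.
#'
#' @param rec a [FovRecording-class].
#' @param windowResponse,windowBaseline window lengths, seconds.
#' @return a [TrialResponseSet-class].
#' @export
extractResponses <- function(rec, windowResponse = 0.4,
                             windowBaseline = 0.6) {
    fr <- frameRate(rec)
    sched <- stimSchedule(rec)
    tr <- traces(rec)
    .checkScheduleFits(sched, fr, ncol(tr), windowResponse, windowBaseline)
    wr <- windowFrames(windowResponse, fr)
    wb <- windowFrames(windowBaseline, fr)
    onIdx <- timeToFrame(onsets(sched), fr)
    offIdx <- timeToFrame(offsets(sched), fr)
    nt <- nTrials(sched)
    resp <- matrix(NA_real_, nrow(tr), nt, dimnames = list(rownames(tr), NULL))
    for (t in seq_len(nt)) {
        fb <- rowMeans(tr[, (onIdx[t] - wb + 1L):onIdx[t], drop = FALSE])
        if (any(fb <= 0))
            stop("degenerate baseline (mean <= 0) for trial ", t)
        fs <- rowMeans(tr[, (offIdx[t] + 1L):(offIdx[t] + wr), drop = FALSE])
        resp[, t] <- fs / fb - 1
    }
    new("TrialResponseSet", responses = resp, windowResponse = windowResponse,
        windowBaseline = windowBaseline, frameRate = fr)
}

#' @describeIn extractResponses the cells-by-trials response matrix.
#' @param x a `TrialResponseSet`.
#' @export
setMethod("responses", "TrialResponseSet", function(x) x@responses)

#' @describeIn extractResponses trials per cell.
#' @export
setMethod("nTrials", "TrialResponseSet", function(x) ncol(x@responses))

#' @describeIn extractResponses cells in the set.
#' @export
setMethod("nCells", "TrialResponseSet", function(x) nrow(x@responses))

setMethod("show", "TrialResponseSet", function(object) {
    cat("TrialResponseSet:", nrow(object@responses), "cells x",
        ncol(object@responses), "trials\n")
    cat("  windows: response", object@windowResponse, "s, baseline",
        object@windowBaseline, "s at", object@frameRate, "Hz\n")
})

#' Spike-count versus calcium-response curve
#'
#' Bins event-aligned windowed \eqn{\Delta F/F} responses by the number of
#' spikes in each firing event and fits a least-squares line, quantifying
#' how linearly transient amplitude follows spike count. The response of an
#' event is computed exactly like a trial response, with the event time
#' acting as both onset (for the preceding baseline) and offset (for the
#' response window).
#'
#' @param trace fluorescence trace.
#' @param frameRate Hz.
#' @param eventTimes event times, seconds.
#' @param spikeCounts spikes per event (same length).
#' @param windowResponse,windowBaseline seconds.
#' @return list with `bins` (data.frame: spike count, n, mean, sd, sem),
#'   `slope` and `intercept` of the least-squares fit of response on count
#'   (slope `NA` when only one distinct count is represented), and
#'   `responses` (per-event values).
#' @export
spikeAmplitudeCurve <- function(trace, frameRate, eventTimes, spikeCounts,
                                windowResponse = 0.4, windowBaseline = 0.6) {
    if (length(eventTimes) == 0) stop("no events supplied")
    if (length(eventTimes) != length(spikeCounts))
        stop("eventTimes and spikeCounts must have equal length")
    r <- vapply(eventTimes, function(tm)
        trialResponse(trace, frameRate, tm, tm, windowResponse,
                      windowBaseline), numeric(1))
    counts <- as.integer(spikeCounts)
    bins <- do.call(rbind, lapply(sort(unique(counts)), function(k) {
        rk <- r[counts == k]
        data.frame(spikes = k, n = length(rk), mean = mean(rk),
                   sd = if (length(rk) > 1) sd(rk) else NA_real_,
                   sem = sem(rk))
    }))
    if (length(unique(counts)) > 1) {
        fit <- coef(lm(r ~ counts))
        slope <- unname(fit[2]); intercept <- unname(fit[1])
    } else {
        slope <- NA_real_; intercept <- NA_real_
    }
    list(bins = bins, slope = slope, intercept = intercept, responses = r)
}
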