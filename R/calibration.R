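#' Insert mock single-spike responses into a trace
#'
#' Adds `k` stacked transient kernels at the offset frame of a randomly
#' chosen `round(p * nTrials)` mock trials (sampled without replacement).
#' This is the validation device of the whole framework: spontaneous
#' activity plus inserted transients is ground-truth follower data at a
#' known stimulation efficacy. The input trace is not modified.
#'
#' @param trace fluorescence trace.
#' @param schedule a [StimSchedule-class] of mock trials fitting the trace.
#' @param template a [TransientTemplate-class] (frame rate must match).
#' @param p insertion probability (efficacy) in [0, 1].
#' @param k spikes per insertion (>= 1).
#' @param frameRate Hz.
#' @param seed RNG seed for the trial choice.
#' @return the augmented trace.
#' @examples
#' sched <- makeStimSchedule(nTrials = 10)
#' tr <- rep(1, 400)
#' tpl <- makeTemplate(0.05, frameRate = 10)
#' out <- insertMockResponses(tr, sched, tpl, p = 0.4, frameRate = 10, seed = 1)
#' sum(out != tr) > 0
#' @export
insertMockResponses <- function(trace, schedule, template, p, k = 1L,
                                frameRate, seed = 1) {
    if (p < 0 || p > 1) stop("p must lie in [0, 1]")
    if (k < 1) stop("k must be >= 1")
    offIdx <- timeToFrame(offsets(schedule), frameRate) + 1L
    if (max(offIdx) > length(trace))
        stop("schedule does not fit in the trace")
    nt <- nTrials(schedule)
    nIns <- as.integer(round(p * nt))
    if (nIns == 0) return(trace)
    set.seed(seed)
    chosen <- sample(nt, nIns)
    .insertAtFrames(trace, offIdx[chosen], k, kernel(template))
}

#' Sensitivity-calibration curve
#'
#' The validation machinery: for each stimulation efficacy p, insert
#' single-spike (or `k`-spike) transients into `round(p * nTrials)` mock
#' trials of `nCells` spontaneous traces, run the mean-z detector with the
#' supplied thresholds, and record the fraction of cells labelled excited,
#' the mean (+/- sem) mean-z, and the mean \eqn{\Delta F/F} of "relevant"
#' trials (see Details). Comparator criteria can be run on the same
#' augmented data for side-by-side sensitivity curves.
#'
#' Relevant trials of an excited follower are the trials whose response
#' exceeds the median of the cell's pooled null responses (mirror image for
#' inhibited cells) — the trials that pull the rank-sum statistic across
#' the threshold.
#'
#' @param config a [SynthConfig-class] describing the spontaneous traces.
#' @param schedule mock-trial [StimSchedule-class] (defaults to 190 trials).
#' @param efficacyLevels efficacies p to probe, ascending, in [0, 1].
#' @param nCells simulated cells per level.
#' @param k spikes per insertion.
#' @param thresholds detector [Thresholds-class] (sham-calibrated limits for
#'   honest specificity).
#' @param nIter shuffle iterations.
#' @param exclusion shuffle exclusion zone, seconds.
#' @param seed base RNG seed.
#' @param comparators character subset of `c("kwandan", "ttest")` to run on
#'   the same augmented data.
#' @param windowResponse,windowBaseline seconds.
#' @return a [CalibrationCurve-class].
#' @export
sensitivityCurve <- function(config, schedule = makeStimSchedule(190),
                             efficacyLevels = c(0.1, 0.2, 0.3, 0.4, 0.5,
                                                0.6, 0.8, 1.0),
                             nCells = 75, k = 1L,
                             thresholds = defaultThresholds(),
                             nIter = 5000, exclusion = 1, seed = 1,
                             comparators = character(),
                             windowResponse = 0.4, windowBaseline = 0.6) {
    if (is.unsorted(efficacyLevels)) stop("efficacyLevels must be ascending")
    if (any(efficacyLevels < 0 | efficacyLevels > 1))
        stop("efficacyLevels must lie in [0, 1]")
    config@duration <- max(config@duration, max(offsets(schedule)) + 2)
    fr <- config@frameRate
    nt <- nTrials(schedule)
    offIdx <- timeToFrame(offsets(schedule), fr) + 1L
    onIdxT <- timeToFrame(onsets(schedule), fr)
    offIdxT <- timeToFrame(offsets(schedule), fr)
    wr <- windowFrames(windowResponse, fr)
    wb <- windowFrames(windowBaseline, fr)
    kern <- kernel(config@template)

    base <- lapply(seq_len(nCells), function(cell) {
        set.seed(deriveSeed(seed, cell))
        config@baselineF + .spontSignal(config)
    })

    rows <- list()
    for (li in seq_along(efficacyLevels)) {
        p <- efficacyLevels[li]
        nIns <- as.integer(round(p * nt))
        mz <- numeric(nCells)
        labs <- character(nCells)
        relDff <- allDff <- rep(NA_real_, nCells)
        kdFlag <- ttFlag <- logical(nCells)
        for (cell in seq_len(nCells)) {
            tr <- base[[cell]]
            if (nIns > 0) {
                set.seed(deriveSeed(seed, 100000L * li + cell))
                chosen <- sample(nt, nIns)
                tr <- .insertAtFrames(tr, offIdx[chosen], k, kern)
            }
            shifts <- drawShifts(length(tr), windowFrames(exclusion, fr),
                                 nIter, deriveSeed(seed, 200000L * li + cell))
            z <- cpp_shuffle_z(tr, onIdxT, offIdxT, wr, wb, shifts)
            mz[cell] <- mean(z)
            labs[cell] <- classifyMeanZ(mz[cell], thresholds)

            real <- cpp_null_responses(tr, onIdxT, offIdxT, wr, wb, 0L)[1, ]
            needNull <- labs[cell] != "neutral" || "ttest" %in% comparators
            if (needNull)
                nullPool <- cpp_null_responses(tr, onIdxT, offIdxT, wr, wb,
                                               shifts)
            if (labs[cell] != "neutral") {
                med <- median(nullPool)
                rel <- if (labs[cell] == "excited") real > med else real < med
                if (any(rel)) relDff[cell] <- mean(real[rel])
                allDff[cell] <- mean(real)
            }
            if ("kwandan" %in% comparators) {
                s <- sem(real)
                kdFlag[cell] <- mean(real) > 3 * s
            }
            if ("ttest" %in% comparators) {
                tt <- ttestComparator(real, as.numeric(nullPool))
                ttFlag[cell] <- tt$p < 0.05 && tt$t > 0
            }
        }
        det <- labs == "excited"
        row <- data.frame(efficacy = p, n_detected = sum(det),
                          detection_fraction = mean(det),
                          mean_z = mean(mz), sem_z = sem(mz),
                          mean_relevant_dff =
                              if (any(det)) mean(relDff[det], na.rm = TRUE)
                              else NA_real_,
                          sem_relevant_dff =
                              if (sum(det) > 1) sem(relDff[det]) else NA_real_,
                          mean_all_dff =
                              if (any(det)) mean(allDff[det]) else NA_real_,
                          sem_all_dff =
                              if (sum(det) > 1) sem(allDff[det]) else NA_real_)
        if ("kwandan" %in% comparators)
            row$detection_fraction_kwandan <- mean(kdFlag)
        if ("ttest" %in% comparators)
            row$detection_fraction_ttest <- mean(ttFlag)
        rows[[li]] <- row
    }
    new("CalibrationCurve", curve = do.call(rbind, rows),
        nCells = as.integer(nCells), nTrials = as.integer(nt),
        k = as.integer(k), seed = as.integer(seed), thresholds = thresholds)
}

setMethod("show", "CalibrationCurve", function(object) {
    cat("CalibrationCurve:", nrow(object@curve), "efficacy levels,",
        object@nCells, "cells x", object@nTrials, "trials, k =", object@k,
        "\n")
    print(object@curve, digits = 3, row.names = FALSE)
})

#' @describeIn sensitivityCurve mean (+/- sem) mean-z per efficacy level.
#' @param curve a `CalibrationCurve`.
#' @export
meanzVsEfficacy <- function(curve) {
    curve@curve[, c("efficacy", "mean_z", "sem_z")]
}

#' @describeIn sensitivityCurve mean \eqn{\Delta F/F} of detected followers
#'   per efficacy level: over relevant trials only, and over all trials (the
#'   latter scales linearly with p by the insertion-indicator expectation).
#' @export
dffVsEfficacy <- function(curve) {
    curve@curve[, c("efficacy", "mean_relevant_dff", "sem_relevant_dff",
                    "mean_all_dff", "sem_all_dff")]
}

#' Estimate stimulation efficacy from an observed mean z
#'
#' Inverse lookup on the calibrated mean-z-versus-efficacy curve by linear
#' interpolation: the efficacy whose simulated mean z matches the observed
#' value. Observations outside the simulated range are clamped to the
#' nearest endpoint with a warning.
#'
#' @param curve a [CalibrationCurve-class].
#' @param observedMeanZ observed mean-z value(s).
#' @return estimated efficacy (fraction of trials with one extra spike).
#' @export
efficacyEstimate <- function(curve, observedMeanZ) {
    cv <- curve@curve
    xs <- c(0, cv$mean_z)          # p = 0 has mean z 0 by construction
    ys <- c(0, cv$efficacy)
    o <- order(xs)
    xs <- xs[o]; ys <- ys[o]
    rng <- range(xs)
    if (any(observedMeanZ < rng[1] | observedMeanZ > rng[2]))
        warning("observed mean z outside the simulated range [",
                signif(rng[1], 3), ", ", signif(rng[2], 3),
                "]; estimate clamped")
    approx(xs, ys, xout = observedMeanZ, rule = 2, ties = "ordered")$y
}
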