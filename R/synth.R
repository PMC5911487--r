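#' Default synthetic-recording configuration
#'
#' The shipped generator constants emulate in vivo OGB-1 bulk-loaded L2/3
#' recordings at 10 Hz: sparse spontaneous calcium events (Poisson, 0.1
#' events/s per cell) carrying geometric spike counts (mean ~1.4 spikes),
#' linear transient summation, and i.i.d. Gaussian frame noise of 0.113
#' \eqn{\Delta F/F}. The single-spike template peaks at 0.07 \eqn{\Delta F/F}
#' with a 0.4 s FWHM, giving a windowed one-spike response of ~4.4%
#' \eqn{\Delta F/F} against ~7.5% response-level noise. These constants are
#' the package's calibration anchor: over a ~1,000-cell sham study the mean-z
#' distribution spans approximately [-2.3, 2.1], and single-spike insertion
#' in 40% of 190 trials (at the reference thresholds) is detected in roughly
#' half the cells (see the methods vignette for the calibration derivation).
#'
#' @param schedule optional [StimSchedule-class]; when given, `duration` is
#'   extended to fit it with a 2 s margin.
#' @param nCells cells per field of view.
#' @param frameRate Hz (5-15 supported by typical hardware).
#' @param duration seconds.
#' @param spontEventRate spontaneous events/s per cell.
#' @param spikeProb geometric spike-count success probability
#'   (mean spikes/event = 1/spikeProb).
#' @param noiseSd per-frame Gaussian noise sd, \eqn{\Delta F/F} fraction.
#' @param baselineF baseline fluorescence level (traces = baseline + signal).
#' @param driftAmplitude amplitude of optional slow sinusoidal drift (0 = off).
#' @param template a [TransientTemplate-class]; default built from
#'   `peakAmplitude` at `frameRate`.
#' @param peakAmplitude single-spike peak \eqn{\Delta F/F} for the default
#'   template.
#' @return a [SynthConfig-class].
#' @export
defaultSynthConfig <- function(schedule = NULL, nCells = 56L, frameRate = 10,
                               duration = 600, spontEventRate = 0.1,
                               spikeProb = 0.7, noiseSd = 0.113,
                               baselineF = 1.0, driftAmplitude = 0,
                               peakAmplitude = 0.07,
                               template = makeTemplate(peakAmplitude,
                                                       fwhm = 0.4,
                                                       frameRate = frameRate)) {
    if (!is.null(schedule))
        duration <- max(duration, max(offsets(schedule)) + 2)
    new("SynthConfig", nCells = as.integer(nCells), frameRate = frameRate,
        duration = duration, spontEventRate = spontEventRate,
        spikeProb = spikeProb, noiseSd = noiseSd, baselineF = baselineF,
        driftAmplitude = driftAmplitude, template = template)
}

setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig:", object@nCells, "cells,", object@duration, "s at",
        object@frameRate, "Hz\n")
    cat("  spont", object@spontEventRate, "events/s; spikeProb",
        object@spikeProb, "; noise sd", object@noiseSd, "; baseline",
        object@baselineF, "\n")
})

# Spontaneous trace in dF/F units (no baseline offset); assumes the RNG
# stream is already positioned (set.seed done by the caller).
.spontSignal <- function(config) {
    nF <- as.integer(round(config@duration * config@frameRate))
    sig <- rnorm(nF, 0, config@noiseSd)
    if (config@driftAmplitude > 0) {
        ph <- runif(1, 0, 2 * pi)
        sig <- sig + config@driftAmplitude *
            sin(2 * pi * (seq_len(nF) / config@frameRate) / 60 + ph)
    }
    nEv <- rpois(1, config@spontEventRate * config@duration)
    if (nEv > 0) {
        times <- sort(runif(nEv, 0, config@duration))
        counts <- rgeom(nEv, config@spikeProb) + 1L
        kk <- kernel(config@template)
        for (e in seq_len(nEv)) {
            i0 <- timeToFrame(times[e], config@frameRate) + 1L
            if (i0 > nF) next
            idx <- i0:min(nF, i0 + length(kk) - 1L)
            sig[idx] <- sig[idx] + counts[e] * kk[seq_along(idx)]
        }
    }
    sig
}

#' Simulate one spontaneous-activity fluorescence trace
#'
#' Sum of Poisson-timed spontaneous calcium events (each a geometric number
#' of spikes times the transient kernel, superposed linearly), i.i.d.
#' Gaussian frame noise, and the constant baseline. Fully reproducible from
#' the seed.
#'
#' @param config a [SynthConfig-class].
#' @param seed integer RNG seed for this trace.
#' @return numeric trace of `round(duration * frameRate)` frames, in
#'   baseline-plus-\eqn{\Delta F/F} units.
#' @examples
#' cfg <- defaultSynthConfig(duration = 60)
#' tr <- simulateSpontTrace(cfg, seed = 1)
#' @export
simulateSpontTrace <- function(config, seed) {
    validObject(config)
    set.seed(seed)
    config@baselineF + .spontSignal(config)
}

# Add k stacked kernels starting at each given 1-based frame index.
.insertAtFrames <- function(trace, frameIdx, k, kern) {
    nF <- length(trace)
    for (i0 in frameIdx) {
        if (i0 > nF) next
        idx <- i0:min(nF, i0 + length(kern) - 1L)
        trace[idx] <- trace[idx] + k * kern[seq_along(idx)]
    }
    trace
}

#' Simulate a field of view with known followers
#'
#' Generates one synthetic session: every cell gets an independent
#' spontaneous trace; cells with ground-truth efficacy `p > 0` additionally
#' receive `k` stacked single-spike kernels inserted at the stimulus offset
#' frame (the first frame at or after the pulse offset) in `round(p *
#' nTrials)` trials chosen without replacement. Cell positions are drawn
#' uniformly in a disk around the patched cell, which sits at the origin.
#'
#' @param config a [SynthConfig-class].
#' @param schedule a [StimSchedule-class]; must fit within the configured
#'   duration.
#' @param efficacy per-cell insertion probability p in [0, 1]; scalar or
#'   vector of length `nCells`. All zero (default) gives a recording
#'   statistically identical to spontaneous activity.
#' @param spikes per-cell spikes per insertion (k >= 1 wherever p > 0).
#' @param conditionLabel session label; `"sham"` requires all-zero efficacy.
#' @param fovRadius radius of the simulated field, micrometres.
#' @param interneuronFraction probability a cell is flagged interneuron.
#' @param seed integer RNG seed; per-cell substreams are derived from it.
#' @return a [FovRecording-class] with ground truth in `rowData`.
#' @examples
#' sched <- makeStimSchedule(nTrials = 20)
#' cfg <- defaultSynthConfig(sched, nCells = 4)
#' fov <- simulateFov(cfg, sched, efficacy = c(1, 0.5, 0, 0), seed = 7)
#' @export
simulateFov <- function(config, schedule, efficacy = 0, spikes = 1L,
                        conditionLabel = "L2/3-anesthetized",
                        fovRadius = 150, interneuronFraction = 0.1,
                        seed = 1) {
    validObject(config)
    nc <- config@nCells
    efficacy <- rep_len(efficacy, nc)
    spikes <- rep_len(as.integer(spikes), nc)
    if (any(efficacy < 0 | efficacy > 1))
        stop("efficacy must lie in [0, 1]")
    if (any(efficacy > 0 & spikes < 1L))
        stop("spikes must be >= 1 for any cell with efficacy > 0")
    nF <- as.integer(round(config@duration * config@frameRate))
    if (max(offsets(schedule)) + 2 > config@duration)
        stop("schedule does not fit in the configured duration")
    nt <- nTrials(schedule)
    offIdx <- timeToFrame(offsets(schedule), config@frameRate) + 1L
    kern <- kernel(config@template)

    tr <- matrix(0, nc, nF)
    for (cell in seq_len(nc)) {
        set.seed(deriveSeed(seed, cell))
        x <- config@baselineF + .spontSignal(config)
        if (efficacy[cell] > 0) {
            nIns <- as.integer(round(efficacy[cell] * nt))
            if (nIns > 0) {
                chosen <- sample(nt, nIns)
                x <- .insertAtFrames(x, offIdx[chosen], spikes[cell], kern)
            }
        }
        tr[cell, ] <- x
    }

    set.seed(deriveSeed(seed, 0L))
    rr <- fovRadius * sqrt(runif(nc))
    th <- runif(nc, 0, 2 * pi)
    pos <- cbind(rr * cos(th), rr * sin(th))
    pos[1, ] <- c(0, 0)
    inter <- as.logical(rbinom(nc, 1, interneuronFraction))
    inter[1] <- FALSE

    FovRecording(tr, frameRate = config@frameRate, schedule = schedule,
                 patchedCell = 1L, cellPositions = pos, interneuron = inter,
                 conditionLabel = conditionLabel, efficacy = efficacy,
                 spikesPerTrial = ifelse(efficacy > 0, spikes, 0L))
}

#' Simulate a multi-FOV study
#'
#' A reproducible collection of sham and stimulation sessions. Sham FOVs
#' carry no inserted responses; in stimulation FOVs a fraction
#' `stimFraction` of cells (chosen at random per FOV) receives
#' `stimSpikes`-spike insertions in `stimEfficacy` of the trials — a weak,
#' distributed population effect rather than a few strong followers.
#'
#' @param nShamFovs,nStimFovs session counts (either may be 0, not both).
#' @param config a [SynthConfig-class] (per-FOV cell count comes from it).
#' @param schedule a [StimSchedule-class] shared by all sessions.
#' @param stimEfficacy insertion probability for affected cells in
#'   stimulation FOVs.
#' @param stimFraction fraction of cells affected in stimulation FOVs.
#' @param stimSpikes spikes per insertion.
#' @param conditionLabel label for the stimulation FOVs.
#' @param seed integer seed; each FOV gets a derived substream, so the whole
#'   study is bit-reproducible.
#' @return list with elements `sham` and `stim`, each a list of
#'   [FovRecording-class].
#' @export
simulateStudy <- function(nShamFovs, nStimFovs, config, schedule,
                          stimEfficacy = 0.2, stimFraction = 0.5,
                          stimSpikes = 1L,
                          conditionLabel = "L2/3-anesthetized", seed = 1) {
    if (nShamFovs < 0 || nStimFovs < 0 || nShamFovs + nStimFovs < 1)
        stop("need at least one FOV")
    sham <- lapply(seq_len(nShamFovs), function(i)
        simulateFov(config, schedule, efficacy = 0, conditionLabel = "sham",
                    seed = deriveSeed(seed, 131L * i)))
    stim <- lapply(seq_len(nStimFovs), function(i) {
        fovSeed <- deriveSeed(seed, 131L * (nShamFovs + i))
        nc <- config@nCells
        set.seed(deriveSeed(fovSeed, 999983L))
        affected <- sample(nc, round(stimFraction * nc))
        eff <- rep(0, nc)
        eff[affected] <- stimEfficacy
        simulateFov(config, schedule, efficacy = eff, spikes = stimSpikes,
                    conditionLabel = conditionLabel, seed = fovSeed)
    })
    list(sham = sham, stim = stim)
}
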