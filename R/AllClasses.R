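#' Single action-potential calcium transient template
#'
#' The fluorescence kernel evoked by one spike: a linear rise followed by an
#' exponential decay, sampled at the imaging frame rate. OGB-1 single-spike
#' transients have a full width at half maximum of roughly 400 ms, and
#' transients of multi-spike events sum approximately linearly, which is what
#' makes spike-insertion simulation meaningful.
#'
#' @slot kernel numeric, \eqn{\Delta F/F} fraction per frame, starting at the
#'   spike frame.
#' @slot peakAmplitude peak \eqn{\Delta F/F} fraction of the kernel.
#' @slot fwhm full width at half maximum, seconds.
#' @slot riseTime rise time to peak, seconds.
#' @slot frameRate sampling rate, Hz.
#' @seealso [makeTemplate()]
#' @export
setClass("TransientTemplate",
    representation(kernel = "numeric", peakAmplitude = "numeric",
                   fwhm = "numeric", riseTime = "numeric",
                   frameRate = "numeric"),
    validity = function(object) {
        msg <- character()
        if (any(object@kernel < 0)) msg <- c(msg, "kernel must be nonnegative")
        if (abs(max(object@kernel) - object@peakAmplitude) >
                1e-6 * object@peakAmplitude)
            msg <- c(msg, "max(kernel) must equal peakAmplitude")
        fw <- measuredFwhm(object@kernel, object@frameRate)
        if (is.na(fw) || abs(fw - object@fwhm) > 1 / object@frameRate)
            msg <- c(msg, "measured kernel FWHM deviates from fwhm by more than one frame")
        if (length(msg)) msg else TRUE
    })

#' Stimulation schedule
#'
#' Onset and offset times (seconds) of the electrical stimulation pulses of
#' one session. Pulses must be separated by gaps of at least 2.5 s so that
#' the calcium transient of one trial has decayed before the next baseline
#' window opens; schedules violating this are flagged with a warning at
#' construction and at file load.
#'
#' @slot onsets pulse onset times, seconds, strictly increasing.
#' @slot offsets pulse offset times, seconds; `offsets > onsets`.
#' @seealso [makeStimSchedule()], [StimSchedule()]
#' @export
setClass("StimSchedule",
    representation(onsets = "numeric", offsets = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@onsets) != length(object@offsets))
            msg <- c(msg, "onsets and offsets must have equal length")
        if (length(object@onsets) == 0)
            msg <- c(msg, "schedule must contain at least one trial")
        else {
            if (any(object@offsets <= object@onsets))
                msg <- c(msg, "offsets must lie strictly after onsets")
            if (is.unsorted(object@onsets, strictly = TRUE))
                msg <- c(msg, "onsets must be strictly increasing")
            n <- length(object@onsets)
            if (n > 1 && any(object@onsets[-1] < object@offsets[-n]))
                msg <- c(msg, "stimulation pulses must not overlap")
        }
        if (length(msg)) msg else TRUE
    })

#' Synthetic recording configuration
#'
#' Generative parameters of the synthetic OGB-like trace simulator:
#' spontaneous calcium events occur as a Poisson process, each carrying a
#' geometric number of spikes whose transients sum linearly on top of a
#' constant fluorescence baseline with i.i.d. Gaussian frame noise.
#'
#' @slot nCells cells per simulated field of view.
#' @slot frameRate imaging rate, Hz.
#' @slot duration trace length, seconds.
#' @slot spontEventRate spontaneous event rate, events/s per cell.
#' @slot spikeProb success probability of the geometric spike-count
#'   distribution (mean spikes per event = 1/spikeProb).
#' @slot noiseSd Gaussian noise sd per frame, \eqn{\Delta F/F} fraction.
#' @slot baselineF baseline fluorescence level the traces ride on (traces are
#'   stored as baseline + \eqn{\Delta F/F} signal, i.e. `1 + dF/F` by default).
#' @slot driftAmplitude amplitude of an optional slow sinusoidal drift
#'   (\eqn{\Delta F/F} fraction; 0 = none).
#' @slot template a [TransientTemplate-class].
#' @seealso [defaultSynthConfig()]
#' @export
setClass("SynthConfig",
    representation(nCells = "integer", frameRate = "numeric",
                   duration = "numeric", spontEventRate = "numeric",
                   spikeProb = "numeric", noiseSd = "numeric",
                   baselineF = "numeric", driftAmplitude = "numeric",
                   template = "TransientTemplate"),
    validity = function(object) {
        msg <- character()
        if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
        if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
        if (object@duration <= 0) msg <- c(msg, "duration must be positive")
        if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
        if (object@spontEventRate < 0) msg <- c(msg, "spontEventRate must be >= 0")
        if (object@spikeProb <= 0 || object@spikeProb > 1)
            msg <- c(msg, "spikeProb must be in (0, 1]")
        if (object@baselineF <= 0) msg <- c(msg, "baselineF must be positive")
        if (length(msg)) msg else TRUE
    })

#' One imaging session (field of view)
#'
#' A `SummarizedExperiment` holding the cells-by-frames fluorescence matrix
#' (assay `"traces"`, stored as baseline + \eqn{\Delta F/F}), per-cell
#' metadata in `rowData` (positions in micrometres, interneuron flags, and
#' for synthetic data the ground-truth stimulation efficacy and spikes per
#' trial), and the stimulation schedule, frame rate, patched-cell index and
#' condition label in `metadata`.
#'
#' @seealso [FovRecording()] for construction, [simulateFov()] for synthesis.
#' @export
setClass("FovRecording", contains = "SummarizedExperiment")

#' Per-trial response distributions
#'
#' The matrix of per-trial \eqn{\Delta F/F} responses r(t) for every cell of
#' a session (cells in rows, trials in columns): the real response
#' distribution R that the shuffle statistic tests.
#'
#' @slot responses cells-by-trials matrix of \eqn{\Delta F/F} fractions.
#' @slot windowResponse response window, seconds.
#' @slot windowBaseline baseline window, seconds.
#' @slot frameRate Hz.
#' @seealso [extractResponses()], [trialResponse()]
#' @export
setClass("TrialResponseSet",
    representation(responses = "matrix", windowResponse = "numeric",
                   windowBaseline = "numeric", frameRate = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!is.numeric(object@responses)) msg <- c(msg, "responses must be numeric")
        if (object@windowResponse <= 0 || object@windowBaseline <= 0)
            msg <- c(msg, "windows must be positive")
        if (length(msg)) msg else TRUE
    })

#' Circular-shuffle null ensemble for one cell
#'
#' The null response distributions R_N built by circularly rotating one
#' cell's trace by random admissible frame shifts and re-reading all trial
#' windows at the original stimulus times. Shifts within `exclusion` seconds
#' of zero (or of the trace length) are inadmissible, so null windows never
#' overlap the cell's own post-stimulus transient of the same trial.
#'
#' @slot cell cell index.
#' @slot shifts integer frame shifts, one per iteration.
#' @slot nullResponses iterations-by-trials matrix of null responses.
#' @slot exclusion exclusion zone, seconds.
#' @slot seed RNG seed used to draw the shifts.
#' @seealso [circularNull()]
#' @export
setClass("NullEnsemble",
    representation(cell = "integer", shifts = "integer",
                   nullResponses = "matrix", exclusion = "numeric",
                   seed = "integer"),
    validity = function(object) {
        if (length(object@shifts) < 1) "at least one iteration required"
        else if (nrow(object@nullResponses) != length(object@shifts))
            "nullResponses must have one row per shift" else TRUE
    })

#' Follower-classification thresholds
#'
#' Limits on the mean shuffle z-value above/below which a cell is classified
#' as an excited/inhibited follower. The reference defaults (2.1 and -2.3)
#' were derived from 1,069 sham-stimulated cells; [calibrateThresholds()]
#' re-derives them from any sham study as the extreme sham mean-z values,
#' which guarantees zero followers on the calibration set by construction.
#'
#' @slot upper excited-follower threshold (> 0).
#' @slot lower inhibited-follower threshold (< 0).
#' @slot provenance `"default"` or `"recalibrated"`.
#' @seealso [defaultThresholds()], [calibrateThresholds()]
#' @export
setClass("Thresholds",
    representation(upper = "numeric", lower = "numeric",
                   provenance = "character"),
    validity = function(object) {
        msg <- character()
        if (!(object@upper > 0 && object@lower < 0))
            msg <- c(msg, "thresholds must satisfy upper > 0 > lower")
        if (!object@provenance %in% c("default", "recalibrated"))
            msg <- c(msg, "provenance must be 'default' or 'recalibrated'")
        if (length(msg)) msg else TRUE
    })

#' Mean shuffle-z statistic of one cell
#'
#' The 5,000 (by default) rank-sum z-values of the real response
#' distribution against each shuffle null, their mean, and the resulting
#' classification.
#'
#' @slot cell cell index.
#' @slot zValues one rank-sum z per shuffle iteration.
#' @slot meanZ arithmetic mean of `zValues`.
#' @slot label `"excited"`, `"inhibited"` or `"neutral"`.
#' @slot thresholds the [Thresholds-class] used for the label.
#' @seealso [meanZStatistic()]
#' @export
setClass("MeanZResult",
    representation(cell = "integer", zValues = "numeric", meanZ = "numeric",
                   label = "character", thresholds = "Thresholds"),
    validity = function(object) {
        msg <- character()
        if (abs(object@meanZ - mean(object@zValues)) > 1e-8)
            msg <- c(msg, "meanZ must equal mean(zValues)")
        expected <- classifyMeanZ(object@meanZ, object@thresholds)
        if (!identical(object@label, expected))
            msg <- c(msg, "label inconsistent with thresholds")
        if (length(msg)) msg else TRUE
    })

#' Follower-detection results for one field of view
#'
#' Per-cell mean-z values (or comparator statistics) and follower labels,
#' with the thresholds, iteration count and seed that produced them.
#'
#' @slot table data.frame with at least columns `cell`, `mean_z`, `label`.
#' @slot thresholds [Thresholds-class] used.
#' @slot method `"meanz"`, `"kwandan"` or `"ttest"`.
#' @slot nIter shuffle iterations per cell (mean-z and t-test methods).
#' @slot seed base RNG seed.
#' @slot conditionLabel condition of the analysed recording.
#' @seealso [detectFollowers()]
#' @export
setClass("FollowerResults",
    representation(table = "data.frame", thresholds = "Thresholds",
                   method = "character", nIter = "integer", seed = "integer",
                   conditionLabel = "character"),
    validity = function(object) {
        need <- c("cell", "mean_z", "label")
        if (!all(need %in% names(object@table)))
            "table must contain columns cell, mean_z, label" else TRUE
    })

#' Sensitivity / response-magnitude calibration curve
#'
#' Detection fraction, mean z and mean relevant-trial \eqn{\Delta F/F} of
#' simulated follower cells as a function of stimulation efficacy p (the
#' fraction of trials that receive an inserted spike transient).
#'
#' @slot curve data.frame with one row per efficacy level.
#' @slot nCells simulated cells per level.
#' @slot nTrials mock trials per cell.
#' @slot k inserted spikes per effective trial.
#' @slot seed base RNG seed.
#' @slot thresholds [Thresholds-class] used by the detector.
#' @seealso [sensitivityCurve()]
#' @export
setClass("CalibrationCurve",
    representation(curve = "data.frame", nCells = "integer",
                   nTrials = "integer", k = "integer", seed = "integer",
                   thresholds = "Thresholds"),
    validity = function(object) {
        msg <- character()
        cv <- object@curve
        if (!all(c("efficacy", "detection_fraction", "mean_z") %in% names(cv)))
            msg <- c(msg, "curve must contain efficacy, detection_fraction, mean_z")
        else {
            if (is.unsorted(cv$efficacy))
                msg <- c(msg, "efficacy levels must be sorted ascending")
            df <- cv$detection_fraction
            if (any(df < 0 | df > 1, na.rm = TRUE))
                msg <- c(msg, "detection_fraction must lie in [0, 1]")
        }
        if (length(msg)) msg else TRUE
    })
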