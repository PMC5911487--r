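#' Stimulation schedules
#'
#' `StimSchedule()` wraps explicit onset/offset times; `makeStimSchedule()`
#' builds a regular schedule of `nTrials` pulses of `pulseDuration` seconds
#' separated by `gap` seconds. Gaps below 2.5 s are allowed but trigger a
#' loud warning: the single-spike calcium transient takes that long to decay
#' and shorter gaps contaminate the next trial's baseline window.
#'
#' @param onsets,offsets pulse times in seconds.
#' @param checkGap warn when any inter-trial gap (next onset minus previous
#'   offset) is below 2.5 s.
#' @return a [StimSchedule-class].
#' @examples
#' sched <- makeStimSchedule(nTrials = 190)
#' nTrials(sched)
#' @export
StimSchedule <- function(onsets, offsets, checkGap = TRUE) {
    obj <- new("StimSchedule", onsets = as.numeric(onsets),
               offsets = as.numeric(offsets))
    if (checkGap && length(onsets) > 1) {
        gaps <- obj@onsets[-1] - obj@offsets[-length(obj@offsets)]
        if (any(gaps < 2.5))
            warning("schedule has ", sum(gaps < 2.5), " inter-trial gap(s) ",
                    "below the recommended 2.5 s minimum (smallest: ",
                    signif(min(gaps), 3), " s)")
    }
    obj
}

#' @rdname StimSchedule
#' @param nTrials number of stimulation pulses (typical session: 190;
#'   supported range roughly 100-400).
#' @param pulseDuration pulse length, seconds (default 0.505, a typical
#'   stimulation-pulse duration).
#' @param gap pause between a pulse offset and the next onset, seconds.
#' @param firstOnset time of the first pulse onset, seconds.
#' @export
makeStimSchedule <- function(nTrials = 190, pulseDuration = 0.505, gap = 2.6,
                             firstOnset = 5) {
    if (nTrials < 1) stop("nTrials must be >= 1")
    period <- pulseDuration + gap
    onsets <- firstOnset + (seq_len(nTrials) - 1) * period
    StimSchedule(onsets, onsets + pulseDuration)
}

#' @rdname StimSchedule
#' @param x a `StimSchedule`.
#' @export
setMethod("nTrials", "StimSchedule", function(x) length(x@onsets))

#' @rdname StimSchedule
#' @export
setMethod("onsets", "StimSchedule", function(x) x@onsets)

#' @rdname StimSchedule
#' @export
setMethod("offsets", "StimSchedule", function(x) x@offsets)

setMethod("show", "StimSchedule", function(object) {
    n <- length(object@onsets)
    cat("StimSchedule:", n, "trials,",
        signif(object@onsets[1], 4), "-", signif(object@offsets[n], 4), "s\n")
})
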