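.conditionLevels <- c("L2/3-anesthetized", "L2/3-awake", "L4-awake", "sham")

#' Construct a field-of-view recording
#'
#' Bundles a cells-by-frames fluorescence matrix with its stimulation
#' schedule and session metadata into a [FovRecording-class] (a
#' `SummarizedExperiment`). Traces are stored as positive fluorescence in
#' baseline units — for synthetic data `1 + dF/F` — so that the ratio form
#' of the per-trial response is well defined; raw-fluorescence inputs work
#' unchanged because the response is scale invariant.
#'
#' Construction fails if any trial's baseline window (0.6 s before onset) or
#' response window (0.4 s after offset) falls outside the trace extent.
#'
#' @param traces numeric matrix, cells in rows, frames in columns.
#' @param frameRate imaging rate, Hz.
#' @param schedule a [StimSchedule-class].
#' @param patchedCell row index of the stimulated cell, or `NA`.
#' @param cellPositions optional 2-column matrix (x, y in micrometres).
#' @param interneuron optional logical vector, one flag per cell.
#' @param conditionLabel one of `"L2/3-anesthetized"`, `"L2/3-awake"`,
#'   `"L4-awake"`, `"sham"`.
#' @param efficacy,spikesPerTrial optional per-cell ground truth for
#'   synthetic recordings: the fraction of trials with an inserted transient
#'   and the number of stacked spikes per insertion.
#' @return a [FovRecording-class].
#' @seealso [simulateFov()] to generate one synthetically.
#' @export
FovRecording <- function(traces, frameRate, schedule,
                         patchedCell = NA_integer_, cellPositions = NULL,
                         interneuron = NULL,
                         conditionLabel = "L2/3-anesthetized",
                         efficacy = NULL, spikesPerTrial = NULL) {
    traces <- as.matrix(traces)
    if (!is.numeric(traces) || anyNA(traces))
        stop("traces must be a numeric matrix without missing frames")
    if (frameRate <= 0) stop("frameRate must be positive")
    conditionLabel <- match.arg(conditionLabel, .conditionLevels)
    nc <- nrow(traces)
    if (is.null(rownames(traces)))
        rownames(traces) <- sprintf("cell%03d", seq_len(nc))

    .checkScheduleFits(schedule, frameRate, ncol(traces))

    if (is.null(efficacy)) efficacy <- rep(0, nc)
    if (is.null(spikesPerTrial)) spikesPerTrial <- rep(0L, nc)
    if (conditionLabel == "sham" && any(efficacy != 0))
        stop("sham recordings must have ground-truth efficacy 0 for all cells")
    rd <- DataFrame(efficacy = efficacy,
                    spikes_per_trial = as.integer(spikesPerTrial),
                    row.names = rownames(traces))
    if (!is.null(cellPositions)) {
        cellPositions <- as.matrix(cellPositions)
        stopifnot(nrow(cellPositions) == nc, ncol(cellPositions) == 2)
        rd$x_um <- cellPositions[, 1]
        rd$y_um <- cellPositions[, 2]
    }
    if (!is.null(interneuron)) {
        stopifnot(length(interneuron) == nc)
        rd$interneuron <- as.logical(interneuron)
    }
    se <- SummarizedExperiment(assays = list(traces = traces), rowData = rd)
    metadata(se) <- list(frame_rate = frameRate, schedule = schedule,
                         patched_cell = as.integer(patchedCell),
                         condition_label = conditionLabel)
    new("FovRecording", se)
}

.checkScheduleFits <- function(schedule, frameRate, nFrames,
                               windowResponse = 0.4, windowBaseline = 0.6) {
    wb <- windowFrames(windowBaseline, frameRate)
    wr <- windowFrames(windowResponse, frameRate)
    onIdx <- timeToFrame(onsets(schedule), frameRate)
    offIdx <- timeToFrame(offsets(schedule), frameRate)
    bad <- which(onIdx - wb < 0L | offIdx + wr > nFrames)
    if (length(bad))
        stop("trial(s) ", paste(head(bad, 5), collapse = ", "),
             if (length(bad) > 5) ", ..." else "",
             " do not fit in the trace with full baseline and response windows")
    invisible(TRUE)
}

#' @describeIn FovRecording fluorescence matrix (cells x frames).
#' @param x a `FovRecording`.
#' @export
setMethod("traces", "FovRecording", function(x) assay(x, "traces"))

#' @describeIn FovRecording imaging rate, Hz.
#' @export
setMethod("frameRate", "FovRecording", function(x) metadata(x)$frame_rate)

#' @describeIn FovRecording the stimulation schedule.
#' @export
setMethod("stimSchedule", "FovRecording", function(x) metadata(x)$schedule)

#' @describeIn FovRecording index of the patched (stimulated) cell.
#' @export
setMethod("patchedCell", "FovRecording", function(x) metadata(x)$patched_cell)

#' @describeIn FovRecording condition label of the session.
#' @export
setMethod("conditionLabel", "FovRecording",
          function(x) metadata(x)$condition_label)

#' @describeIn FovRecording per-cell ground-truth efficacy / spikes
#'   (synthetic recordings; all zero for real or sham data).
#' @export
setMethod("groundTruth", "FovRecording", function(x)
    rowData(x)[, c("efficacy", "spikes_per_trial")])

#' @describeIn FovRecording per-cell x/y positions in micrometres (or NULL).
#' @export
setMethod("cellPositions", "FovRecording", function(x) {
    rd <- rowData(x)
    if (!all(c("x_um", "y_um") %in% names(rd))) return(NULL)
    cbind(x_um = rd$x_um, y_um = rd$y_um)
})

#' @describeIn FovRecording number of cells (rows).
#' @export
setMethod("nCells", "FovRecording", function(x) nrow(x))

#' @describeIn FovRecording number of stimulation trials.
#' @export
setMethod("nTrials", "FovRecording",
          function(x) nTrials(stimSchedule(x)))

setMethod("show", "FovRecording", function(object) {
    cat("FovRecording (", conditionLabel(object), "): ",
        nrow(object), " cells x ", ncol(object), " frames at ",
        frameRate(object), " Hz\n", sep = "")
    cat("  ", nTrials(object), " trials; patched cell: ",
        patchedCell(object), "\n", sep = "")
    gt <- groundTruth(object)
    if (any(gt$efficacy > 0))
        cat("  synthetic followers:", sum(gt$efficacy > 0), "cells with",
            "efficacy", paste(unique(gt$efficacy[gt$efficacy > 0]),
                              collapse = ", "), "\n")
})
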