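classifyMeanZ <- function(meanZ, thr) {
    if (meanZ > thr@upper) "excited"
    else if (meanZ < thr@lower) "inhibited"
    else "neutral"
}

#' Follower-classification thresholds
#'
#' `defaultThresholds()` returns the reference limits (2.1 / -2.3) derived
#' from 1,069 sham-stimulated cells; `Thresholds()` builds custom limits.
#'
#' @param upper excited-follower threshold (> 0).
#' @param lower inhibited-follower threshold (< 0).
#' @param provenance `"default"` or `"recalibrated"`.
#' @return a [Thresholds-class].
#' @seealso [calibrateThresholds()]
#' @export
Thresholds <- function(upper, lower, provenance = "default") {
    new("Thresholds", upper = upper, lower = lower, provenance = provenance)
}

#' @rdname Thresholds
#' @export
defaultThresholds <- function() Thresholds(2.1, -2.3, "default")

setMethod("show", "Thresholds", function(object) {
    cat("Thresholds (", object@provenance, "): excited > ", object@upper,
        ", inhibited < ", object@lower, "\n", sep = "")
})

# Uniform draw of admissible circular shifts: at least exclFrames away from
# both 0 and the trace length, so a shifted response window can never land
# on the same trial's true post-stimulus transient.
drawShifts <- function(nFrames, exclFrames, nIter, seed) {
    lo <- exclFrames
    hi <- nFrames - exclFrames
    if (hi < lo)
        stop("no admissible circular shifts: trace of ", nFrames,
             " frames is too short for an exclusion zone of ", exclFrames,
             " frames on each side")
    set.seed(seed)
    as.integer(sample(lo:hi, nIter, replace = TRUE))
}

#' Circular-shuffle null ensemble for one cell
#'
#' Rotates the cell's trace `nIter` times by uniformly drawn admissible
#' frame shifts and recomputes all per-trial responses on the rotated trace
#' at the original stimulus times. Because rotation preserves the trace's
#' autocorrelation and noise structure, the resulting null distributions
#' R_N reflect each cell's own spontaneous variability. Shifts closer than
#' `exclusion` seconds to zero (or to the trace length) are never drawn.
#'
#' @param rec a [FovRecording-class].
#' @param cell cell (row) index.
#' @param nIter shuffle iterations (default 5000).
#' @param exclusion exclusion zone around the identity shift, seconds.
#' @param seed integer RNG seed.
#' @param windowResponse,windowBaseline window lengths, seconds.
#' @return a [NullEnsemble-class].
#' @export
circularNull <- function(rec, cell, nIter = 5000, exclusion = 1, seed = 1,
                         windowResponse = 0.4, windowBaseline = 0.6) {
    fr <- frameRate(rec)
    tr <- traces(rec)[cell, ]
    sched <- stimSchedule(rec)
    shifts <- drawShifts(length(tr), windowFrames(exclusion, fr), nIter, seed)
    nullResp <- cpp_null_responses(tr, timeToFrame(onsets(sched), fr),
                                   timeToFrame(offsets(sched), fr),
                                   windowFrames(windowResponse, fr),
                                   windowFrames(windowBaseline, fr), shifts)
    new("NullEnsemble", cell = as.integer(cell), shifts = shifts,
        nullResponses = nullResp, exclusion = exclusion,
        seed = as.integer(seed))
}

setMethod("show", "NullEnsemble", function(object) {
    cat("NullEnsemble: cell", object@cell, "-", length(object@shifts),
        "shifts,", ncol(object@nullResponses), "trials each; exclusion",
        object@exclusion, "s\n")
})

#' Mean shuffle-z statistic of one cell
#'
#' The core follower statistic, in three steps: (1) extract the real
#' per-trial response distribution R; (2) build `nIter` circular-shuffle
#' null distributions R_N; (3) compute one rank-sum z per iteration
#' (R versus R_N) and average them. The mean z is compared against the
#' thresholds to label the cell excited, inhibited or neutral.
#'
#' @inheritParams circularNull
#' @param thresholds a [Thresholds-class].
#' @return a [MeanZResult-class].
#' @examples
#' sched <- makeStimSchedule(nTrials = 15)
#' cfg <- defaultSynthConfig(sched, nCells = 1, duration = 60)
#' fov <- simulateFov(cfg, sched, seed = 3)
#' meanZStatistic(fov, 1, nIter = 100, seed = 5)
#' @export
meanZStatistic <- function(rec, cell, nIter = 5000, exclusion = 1, seed = 1,
                           thresholds = defaultThresholds(),
                           windowResponse = 0.4, windowBaseline = 0.6) {
    fr <- frameRate(rec)
    tr <- traces(rec)[cell, ]
    sched <- stimSchedule(rec)
    .checkScheduleFits(sched, fr, length(tr), windowResponse, windowBaseline)
    shifts <- drawShifts(length(tr), windowFrames(exclusion, fr), nIter, seed)
    z <- cpp_shuffle_z(tr, timeToFrame(onsets(sched), fr),
                       timeToFrame(offsets(sched), fr),
                       windowFrames(windowResponse, fr),
                       windowFrames(windowBaseline, fr), shifts)
    mz <- mean(z)
    new("MeanZResult", cell = as.integer(cell), zValues = as.numeric(z),
        meanZ = mz, label = classifyMeanZ(mz, thresholds),
        thresholds = thresholds)
}

#' @describeIn meanZStatistic the mean z value.
#' @param x a `MeanZResult`.
#' @export
setMethod("meanZ", "MeanZResult", function(x) x@meanZ)

#' @describeIn meanZStatistic the classification label.
#' @export
setMethod("followerLabels", "MeanZResult", function(x) x@label)

setMethod("show", "MeanZResult", function(object) {
    cat("MeanZResult: cell", object@cell, "- mean z",
        signif(object@meanZ, 4), "->", object@label, "\n")
})

#' Detect followers in a field of view
#'
#' Runs a detection method on every cell of a recording. `"meanz"` is the
#' shuffle statistic ([meanZStatistic()]); `"kwandan"` and `"ttest"` are the
#' comparator criteria provided for benchmarking (see [kwanDanFollowers()]
#' and [ttestComparator()]). Each cell uses a substream seed derived from
#' `seed`, so results are reproducible and independent of cell order.
#'
#' @inheritParams meanZStatistic
#' @param method detection method.
#' @return a [FollowerResults-class]. For `"kwandan"` the `mean_z` column
#'   holds the mean pre/post difference and the table gains a `criterion`
#'   column (3 sem); for `"ttest"` it holds the Welch t statistic and the
#'   table gains `p_value`.
#' @export
detectFollowers <- function(rec, thresholds = defaultThresholds(),
                            nIter = 5000, exclusion = 1, seed = 1,
                            method = c("meanz", "kwandan", "ttest"),
                            windowResponse = 0.4, windowBaseline = 0.6) {
    method <- match.arg(method)
    nc <- nCells(rec)
    if (method == "meanz") {
        rows <- lapply(seq_len(nc), function(cell) {
            res <- meanZStatistic(rec, cell, nIter, exclusion,
                                  deriveSeed(seed, cell), thresholds,
                                  windowResponse, windowBaseline)
            data.frame(cell = cell, mean_z = meanZ(res),
                       label = followerLabels(res))
        })
        tab <- do.call(rbind, rows)
    } else if (method == "kwandan") {
        rs <- extractResponses(rec, windowResponse, windowBaseline)
        kd <- kwanDanFollowers(rs, details = TRUE)
        tab <- data.frame(cell = seq_len(nc), mean_z = kd$mean_diff,
                          criterion = kd$criterion,
                          label = ifelse(kd$follower, "excited", "neutral"))
    } else {
        rs <- extractResponses(rec, windowResponse, windowBaseline)
        rows <- lapply(seq_len(nc), function(cell) {
            ne <- circularNull(rec, cell, nIter, exclusion,
                               deriveSeed(seed, cell), windowResponse,
                               windowBaseline)
            tt <- ttestComparator(responses(rs)[cell, ],
                                  as.numeric(ne@nullResponses))
            lab <- if (tt$p < 0.05) {
                if (tt$t > 0) "excited" else "inhibited"
            } else "neutral"
            data.frame(cell = cell, mean_z = tt$t, p_value = tt$p,
                       label = lab)
        })
        tab <- do.call(rbind, rows)
    }
    rownames(tab) <- NULL
    new("FollowerResults", table = tab, thresholds = thresholds,
        method = method, nIter = as.integer(nIter), seed = as.integer(seed),
        conditionLabel = conditionLabel(rec))
}

#' @describeIn detectFollowers per-cell mean-z (or comparator statistic)
#'   vector.
#' @param x a `FollowerResults`.
#' @export
setMethod("meanZ", "FollowerResults",
          function(x) setNames(x@table$mean_z, x@table$cell))

#' @describeIn detectFollowers per-cell labels.
#' @export
setMethod("followerLabels", "FollowerResults",
          function(x) setNames(x@table$label, x@table$cell))

#' @describeIn detectFollowers thresholds used.
#' @export
setMethod("thresholds", "FollowerResults", function(x) x@thresholds)

#' @describeIn detectFollowers number of cells analysed.
#' @export
setMethod("nCells", "FollowerResults", function(x) nrow(x@table))

#' @describeIn detectFollowers percentage of cells labelled excited or
#'   inhibited.
#' @export
setMethod("percentFollowers", "FollowerResults", function(x, ...)
    100 * sum(x@table$label != "neutral") / nrow(x@table))

setMethod("show", "FollowerResults", function(object) {
    tb <- table(factor(object@table$label,
                       levels = c("excited", "inhibited", "neutral")))
    cat("FollowerResults (", object@method, ", ", object@conditionLabel,
        "): ", nrow(object@table), " cells\n", sep = "")
    cat("  excited ", tb["excited"], ", inhibited ", tb["inhibited"],
        ", neutral ", tb["neutral"], "\n", sep = "")
    cat("  thresholds: ", object@thresholds@upper, " / ",
        object@thresholds@lower, " (", object@thresholds@provenance, ")\n",
        sep = "")
})

#' Recalibrate thresholds from sham sessions
#'
#' Sets the excited/inhibited limits to the extreme mean-z values observed
#' across all sham-stimulated cells, which by construction yields zero
#' followers when the calibration set is re-classified with its own
#' thresholds — the specificity guarantee the detector is built around.
#'
#' @param shamResults a numeric vector of sham mean-z values, a
#'   [FollowerResults-class], or a list of `FollowerResults`.
#' @return a [Thresholds-class] with provenance `"recalibrated"`.
#' @export
calibrateThresholds <- function(shamResults) {
    if (is(shamResults, "FollowerResults")) shamResults <- list(shamResults)
    if (is.list(shamResults))
        shamResults <- unlist(lapply(shamResults, meanZ))
    shamResults <- as.numeric(shamResults)
    if (length(shamResults) == 0 || all(is.na(shamResults)))
        stop("no sham mean-z values supplied")
    up <- max(shamResults); lo <- min(shamResults)
    if (!(up > 0 && lo < 0))
        stop("sham mean-z values must straddle zero to define thresholds ",
             "(observed range [", signif(lo, 3), ", ", signif(up, 3), "])")
    Thresholds(up, lo, "recalibrated")
}
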