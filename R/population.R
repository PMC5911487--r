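#' Field-of-view z-median
#'
#' The median of all cells' mean-z values in one FOV: a population-level
#' measure of how much the whole neighbourhood's activity moves with
#' stimulation. Unlike the follower count it is insensitive to a handful of
#' strong cells and instead reflects weak, distributed influence.
#'
#' @param x a [FollowerResults-class] or a numeric vector of mean-z values.
#' @return the z-median.
#' @export
fovZmedian <- function(x) {
    if (is(x, "FollowerResults")) x <- meanZ(x)
    x <- as.numeric(x)
    if (length(x) == 0) stop("no mean-z values supplied")
    median(x)
}

#' Compare sham and stimulation z-medians
#'
#' Two-sided Wilcoxon rank-sum test between the per-FOV z-medians of a sham
#' group and a stimulation group. A positive shift of the stimulation group
#' indicates distributed excitatory influence of the stimulated cell even
#' when few (or no) individual cells cross the follower thresholds.
#'
#' @param shamMedians,stimMedians numeric vectors of per-FOV z-medians.
#' @return list with `statistic` (rank-sum W), `p` (two-sided), and the two
#'   group medians.
#' @export
compareZmedians <- function(shamMedians, stimMedians) {
    if (length(shamMedians) == 0 || length(stimMedians) == 0)
        stop("both groups must be non-empty")
    wt <- suppressWarnings(wilcox.test(stimMedians, shamMedians))
    list(statistic = unname(wt$statistic), p = unname(wt$p.value),
         sham_median = median(shamMedians), stim_median = median(stimMedians))
}

#' Pearson chi-square test for two proportions
#'
#' Uncorrected (no Yates continuity correction) chi-square on the 2x2 table
#' of successes and failures in two groups, 1 degree of freedom — e.g.
#' comparing effective-stimulator counts between conditions.
#'
#' @param successes1,n1 successes and total in group 1.
#' @param successes2,n2 successes and total in group 2.
#' @return list with `chi2` and `p`.
#' @examples
#' chi2Test2x2(4, 19, 5, 14)  # p ~ 0.35
#' @export
chi2Test2x2 <- function(successes1, n1, successes2, n2) {
    if (any(c(successes1, successes2) < 0) || successes1 > n1 ||
        successes2 > n2)
        stop("need 0 <= successes <= n in both groups")
    tab <- matrix(c(successes1, n1 - successes1,
                    successes2, n2 - successes2), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("degenerate table: a row or column margin is zero")
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Summarise one analysed FOV
#'
#' One row of study bookkeeping for a detection result: cell and follower
#' counts, polarity breakdown, percent followers, the FOV z-median, and the
#' effective-stimulator flag (at least one follower present).
#'
#' @param results a [FollowerResults-class].
#' @return one-row data.frame.
#' @seealso [tallyStudy()]
#' @export
summarizeFov <- function(results) {
    lab <- followerLabels(results)
    nFollow <- sum(lab != "neutral")
    data.frame(condition = results@conditionLabel,
               n_cells = length(lab),
               n_followers = nFollow,
               n_excited = sum(lab == "excited"),
               n_inhibited = sum(lab == "inhibited"),
               percent_followers = 100 * nFollow / length(lab),
               z_median = fovZmedian(results),
               effective_stimulator = nFollow > 0)
}

#' Study-level tally of followers and effective stimulators
#'
#' Pools per-FOV summaries by condition: total cells, followers, polarity
#' counts, pooled percent followers (full precision plus a display value
#' rounded to two significant figures, e.g. 4/796 -> "0.5", 8/832 ->
#' "0.96"), and the effective-stimulator fraction.
#'
#' @param summaries data.frame of [summarizeFov()] rows (rbind of FOVs).
#' @return data.frame with one row per condition plus a pooled `"all"` row.
#' @export
tallyStudy <- function(summaries) {
    if (nrow(summaries) == 0) stop("no FOV summaries supplied")
    tallyOne <- function(s, label) {
        cells <- sum(s$n_cells); fol <- sum(s$n_followers)
        pct <- 100 * fol / cells
        data.frame(condition = label,
                   n_fovs = nrow(s),
                   n_cells = cells,
                   n_followers = fol,
                   n_excited = sum(s$n_excited),
                   n_inhibited = sum(s$n_inhibited),
                   percent_followers = pct,
                   percent_display = formatC(signif(pct, 2), format = "fg"),
                   effective_stimulators = sum(s$effective_stimulator),
                   effective_fraction =
                       sum(s$effective_stimulator) / nrow(s))
    }
    parts <- lapply(split(summaries, summaries$condition),
                    function(s) tallyOne(s, s$condition[1]))
    out <- do.call(rbind, c(parts, list(tallyOne(summaries, "all"))))
    rownames(out) <- NULL
    out
}

#' Restrict a FOV to cells near the patched cell
#'
#' Drops cells farther than `maxDistance` micrometres from the patched
#' cell, and flags FOVs whose own radius (the farthest imaged cell) is
#' below `maxDistance` — the standardisation step that makes differently
#' sized fields comparable. The flag is stored in
#' `metadata(rec)$undersized_fov`.
#'
#' @param rec a [FovRecording-class] with cell positions and a patched cell.
#' @param maxDistance cutoff, micrometres (default 150).
#' @return the filtered [FovRecording-class].
#' @export
radiusFilter <- function(rec, maxDistance = 150) {
    pos <- cellPositions(rec)
    pc <- patchedCell(rec)
    if (is.null(pos)) stop("cell positions are required for radius filtering")
    if (is.na(pc)) stop("a patched cell is required for radius filtering")
    d <- sqrt((pos[, 1] - pos[pc, 1])^2 + (pos[, 2] - pos[pc, 2])^2)
    fovRadius <- max(d)
    keep <- d <= maxDistance
    keep[pc] <- TRUE
    out <- rec[keep, ]
    metadata(out)$patched_cell <- as.integer(match(pc, which(keep)))
    metadata(out)$undersized_fov <- fovRadius < maxDistance
    out
}

#' Linear correlation between a covariate and responses
#'
#' Pearson correlation with a two-sided p-value, used for checks such as
#' membrane potential before each stimulus versus the follower's responses,
#' baseline activity versus response, or response amplitude versus distance
#' from the patched cell.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list with `r` and `p`.
#' @export
covariateCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("need at least 3 observations")
    if (sd(x) == 0 || sd(y) == 0)
        stop("undefined correlation: zero variance in x or y")
    ct <- cor.test(x, y)
    list(r = unname(ct$estimate), p = unname(ct$p.value))
}
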