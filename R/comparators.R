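#' Kwan-Dan comparator criterion
#'
#' The benchmark follower rule: a cell is a follower when its mean stimulus
#' response exceeds the mean by more than 3 standard errors of the per-trial
#' \eqn{\Delta F/F} differences between the pre-stimulus epoch (the 0.6 s
#' baseline window) and the post-stimulus epoch (the 0.4 s response
#' window). With differences d(t) = post(t) - pre(t) this reads
#' `mean(d) > 3 * sem(d)`, i.e. the mean response must clear three standard
#' errors above the null expectation of zero. Compared with the shuffle
#' statistic this criterion is less sensitive and less specific (it admits
#' false positives on sham data).
#'
#' @param responseSet a [TrialResponseSet-class]. Because the stored
#'   responses are already the post/pre ratio minus one, they are exactly
#'   the per-trial pre/post differences in baseline units.
#' @param details return per-cell statistics instead of the plain flags.
#' @return logical vector (one flag per cell), or when `details = TRUE` a
#'   data.frame with `mean_diff`, `sem_diff`, `criterion` (3 sem) and
#'   `follower`.
#' @export
kwanDanFollowers <- function(responseSet, details = FALSE) {
    r <- responses(responseSet)
    if (ncol(r) < 2) stop("at least 2 trials required")
    m <- rowMeans(r)
    s <- apply(r, 1, sem)
    follower <- m > 3 * s
    if (!details) return(setNames(follower, rownames(r)))
    data.frame(cell = seq_len(nrow(r)), mean_diff = m, sem_diff = s,
               criterion = 3 * s, follower = follower)
}

#' Welch t-test comparator
#'
#' Direct comparison of real responses against (pooled) null responses with
#' a Welch two-sample t-test — the conventional approach the shuffle
#' statistic is benchmarked against, and generally weaker in conferring
#' significance. Degenerate inputs (both samples with zero variance, or
#' identical samples) return p = 1 by convention.
#'
#' @param real numeric vector of real per-trial responses.
#' @param null numeric vector of (pooled) null responses.
#' @return list with `t` (Welch statistic, 0 for degenerate input) and `p`
#'   (two-sided).
#' @export
ttestComparator <- function(real, null) {
    if (length(real) < 2 || length(null) < 2)
        stop("both samples need at least 2 values")
    if (sd(real) == 0 && sd(null) == 0)
        return(list(t = 0, p = 1))
    tt <- t.test(real, null)
    list(t = unname(tt$statistic), p = unname(tt$p.value))
}
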