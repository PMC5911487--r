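#' Wilcoxon rank-sum z statistic
#'
#' Two-sample rank-sum z under the normal approximation with tie-corrected
#' variance and no continuity correction. Positive z means `x` is
#' stochastically larger than `y`; swapping the arguments negates z. When
#' every value is tied across both samples the variance is zero and z is
#' defined as 0. With ~190 trials per sample the normal approximation is
#' excellent, which is why z-values (rather than exact p-values) are used
#' throughout the shuffle statistic.
#'
#' @param x,y non-empty numeric vectors (real and null responses).
#' @return the z value.
#' @examples
#' ranksumZ(c(1, 2, 3), c(4, 5, 6))  # -4.5 / sqrt(5.25)
#' @export
ranksumZ <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
    n <- n1 + n2
    W <- sum(rank(c(x, y))[seq_len(n1)])
    tieSizes <- rle(sort(c(x, y)))$lengths
    tiesum <- sum(tieSizes^3 - tieSizes)
    v <- n1 * n2 / 12 * ((n + 1) - tiesum / (n * (n - 1)))
    if (v <= 0) return(0)
    (W - n1 * (n + 1) / 2) / sqrt(v)
}
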