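# Internal conversions between times (seconds) and frames. Frames are
# 0-based sample indices at times i / frameRate; a stated time maps to the
# nearest frame at or after it. R matrix columns are frame + 1.

timeToFrame <- function(t, frameRate) {
    as.integer(ceiling(t * frameRate - 1e-9))
}

windowFrames <- function(window, frameRate) {
    max(1L, as.integer(round(window * frameRate)))
}

# Deterministic 32-bit substream seeds so every cell / FOV / insertion draw
# has its own reproducible stream derived from one user-facing seed.
deriveSeed <- function(seed, i) {
    as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(i) * 1009 + 1) %%
                   2147483647)
}

sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
}

# Linear-interpolation full width at half maximum of a sampled kernel,
# in seconds. Kernel samples are at times (seq_along(k) - 1) / frameRate.
measuredFwhm <- function(k, frameRate) {
    pk <- max(k)
    if (pk <= 0) return(NA_real_)
    half <- pk / 2
    tt <- (seq_along(k) - 1) / frameRate
    above <- k >= half
    if (!any(above)) return(NA_real_)
    i1 <- which(above)[1]
    i2 <- tail(which(above), 1)
    # upward crossing between i1 - 1 and i1
    t.up <- if (i1 == 1) tt[1] else
        tt[i1 - 1] + (half - k[i1 - 1]) / (k[i1] - k[i1 - 1]) / frameRate
    # downward crossing between i2 and i2 + 1 (or trace end)
    t.dn <- if (i2 == length(k)) tt[i2] else
        tt[i2] + (k[i2] - half) / (k[i2] - k[i2 + 1]) / frameRate
    t.dn - t.up
}
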