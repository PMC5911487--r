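# Independent oracle: exact permutation mean and variance of the rank sum W
# over all C(n, n1) assignments of the observed (possibly tied) ranks.
enumRanksumZ <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    picks <- utils::combn(n, n1)
    Wall <- apply(picks, 2, function(ix) sum(r[ix]))
    v <- mean((Wall - mean(Wall))^2)   # population variance over assignments
    if (v == 0) return(0)
    (W - mean(Wall)) / sqrt(v)
}
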