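# Small fixtures shared across unit tests. Kept deliberately tiny; the
# full-scale study conditions live in the acceptance tests.

tinySchedule <- function(n = 12, gap = 2.6) makeStimSchedule(n, gap = gap)

tinyConfig <- function(sched, nCells = 3, ...) {
    defaultSynthConfig(sched, nCells = nCells,
                       duration = max(offsets(sched)) + 2, ...)
}

# Noiseless, event-free configuration: traces are exactly the baseline plus
# any inserted transients, so windowed arithmetic is exact.
quietConfig <- function(sched, nCells = 2) {
    tinyConfig(sched, nCells = nCells, spontEventRate = 0, noiseSd = 0)
}

constantFov <- function(nCells = 2, sched = tinySchedule()) {
    nF <- as.integer((max(offsets(sched)) + 2) * 10)
    FovRecording(matrix(1, nCells, nF), frameRate = 10, schedule = sched,
                 conditionLabel = "sham")
}
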