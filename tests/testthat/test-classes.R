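test_that("recording construction enforces its invariants", {
    sched <- tinySchedule()
    nF <- as.integer((max(offsets(sched)) + 2) * 10)
    tr <- matrix(1, 2, nF)
    trNA <- tr; trNA[1, 5] <- NA
    expect_error(FovRecording(trNA, 10, sched), "missing")
    expect_error(FovRecording(tr[, 1:60, drop = FALSE], 10, sched), "fit")
    expect_error(FovRecording(tr, 10, sched, conditionLabel = "cortex"),
                 "arg")
    expect_error(FovRecording(tr, 0, sched), "frameRate")
    fov <- FovRecording(tr, 10, sched)
    expect_s4_class(fov, "FovRecording")
    expect_equal(nCells(fov), 2L)
    expect_equal(nTrials(fov), 12L)
})

test_that("schedule validity catches structural faults", {
    expect_error(StimSchedule(c(1, 2), c(1.5)), "equal length")
    expect_error(StimSchedule(c(1, 2), c(0.5, 2.5)), "strictly after")
    expect_error(StimSchedule(c(2, 1), c(2.5, 1.5)), "increasing")
    expect_error(StimSchedule(c(1, 1.4), c(1.5, 1.9), checkGap = FALSE),
                 "overlap")
    expect_warning(StimSchedule(c(1, 3), c(1.5, 3.5)), "2.5 s")
    expect_error(makeStimSchedule(0), "nTrials")
})

test_that("synthetic configuration validity catches bad parameters", {
    expect_error(defaultSynthConfig(nCells = 0), "nCells")
    expect_error(defaultSynthConfig(noiseSd = -0.1), "noiseSd")
    expect_error(defaultSynthConfig(spikeProb = 0), "spikeProb")
    expect_error(defaultSynthConfig(duration = -5), "duration")
})

test_that("show methods print a concise summary", {
    sched <- tinySchedule()
    expect_output(show(sched), "StimSchedule: 12 trials")
    expect_output(show(makeTemplate(0.07, 0.4, 10)), "TransientTemplate")
    expect_output(show(defaultSynthConfig()), "SynthConfig")
    fov <- constantFov(2, sched)
    expect_output(show(fov), "FovRecording \\(sham\\): 2 cells")
    expect_output(show(defaultThresholds()), "excited > 2.1")
    res <- detectFollowers(fov, nIter = 20, seed = 1)
    expect_output(show(res), "FollowerResults \\(meanz, sham\\): 2 cells")
    expect_output(show(meanZStatistic(fov, 1, nIter = 20, seed = 1)),
                  "MeanZResult")
    expect_output(show(circularNull(fov, 1, nIter = 20, seed = 1)),
                  "NullEnsemble")
})

test_that("inconsistent mean-z results are rejected by validity", {
    thr <- defaultThresholds()
    expect_error(new("MeanZResult", cell = 1L, zValues = c(1, 2),
                     meanZ = 5, label = "excited", thresholds = thr),
                 "meanZ")
    expect_error(new("MeanZResult", cell = 1L, zValues = c(1, 2),
                     meanZ = 1.5, label = "excited", thresholds = thr),
                 "label")
})
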