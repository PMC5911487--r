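test_that("event-free noiseless traces sit exactly on the baseline", {
    sched <- tinySchedule()
    cfg <- quietConfig(sched)
    tr <- simulateSpontTrace(cfg, seed = 1)
    expect_true(all(tr == cfg@baselineF))
})

test_that("trace simulation is reproducible from the seed", {
    sched <- tinySchedule()
    cfg <- tinyConfig(sched)
    expect_identical(simulateSpontTrace(cfg, seed = 7),
                     simulateSpontTrace(cfg, seed = 7))
    f1 <- simulateFov(cfg, sched, efficacy = c(0, 0.5, 1), seed = 9)
    f2 <- simulateFov(cfg, sched, efficacy = c(0, 0.5, 1), seed = 9)
    expect_identical(traces(f1), traces(f2))
    expect_false(identical(traces(f1),
                           traces(simulateFov(cfg, sched,
                                              efficacy = c(0, 0.5, 1),
                                              seed = 10))))
})

test_that("whole studies are bit-reproducible and honor FOV counts", {
    sched <- tinySchedule()
    cfg <- tinyConfig(sched, nCells = 2)
    s1 <- simulateStudy(2, 1, cfg, sched, seed = 3)
    s2 <- simulateStudy(2, 1, cfg, sched, seed = 3)
    expect_identical(lapply(s1$sham, traces), lapply(s2$sham, traces))
    expect_identical(traces(s1$stim[[1]]), traces(s2$stim[[1]]))
    expect_length(s1$sham, 2)
    expect_length(s1$stim, 1)
    shamOnly <- simulateStudy(2, 0, cfg, sched, seed = 3)
    expect_length(shamOnly$stim, 0)
    expect_true(all(vapply(shamOnly$sham, function(f)
        all(groundTruth(f)$efficacy == 0), logical(1))))
})

test_that("insertion counts equal round(p * nTrials), sampled per trial", {
    sched <- tinySchedule(20)
    cfg <- quietConfig(sched)
    for (p in c(0.4, 1.0)) {
        fov <- simulateFov(cfg, sched, efficacy = c(p, 0), seed = 5)
        r <- responses(extractResponses(fov))
        expect_equal(sum(r[1, ] > 1e-12), round(p * 20))
        expect_true(all(r[2, ] == 0))
    }
})

test_that("k-spike insertions scale responses linearly (noiseless)", {
    sched <- tinySchedule(10, gap = 5)
    cfg <- quietConfig(sched, nCells = 1)
    r1 <- responses(extractResponses(
        simulateFov(cfg, sched, efficacy = 1, spikes = 1L, seed = 4)))
    r3 <- responses(extractResponses(
        simulateFov(cfg, sched, efficacy = 1, spikes = 3L, seed = 4)))
    expect_equal(as.numeric(r3), 3 * as.numeric(r1), tolerance = 1e-9)
})

test_that("invalid follower specifications are rejected", {
    sched <- tinySchedule()
    cfg <- tinyConfig(sched, nCells = 2)
    expect_error(simulateFov(cfg, sched, efficacy = c(1.2, 0)), "efficacy")
    expect_error(simulateFov(cfg, sched, efficacy = 0.5, spikes = 0L),
                 "spikes")
    expect_error(simulateFov(cfg, sched, efficacy = c(0.5, 0),
                             conditionLabel = "sham"), "sham")
    shortCfg <- tinyConfig(sched, nCells = 2)
    shortCfg@duration <- 5
    expect_error(simulateFov(shortCfg, sched, seed = 1), "fit|duration")
})
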