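test_that("trial response implements the windowed ratio exactly", {
    tr <- rep(1, 100)
    expect_equal(trialResponse(tr, 10, onset = 4.5, offset = 5.0), 0)
    # response window frames 51..54 (0-based 50..53) raised by 2%
    tr2 <- tr; tr2[51:54] <- 1.02
    expect_equal(trialResponse(tr2, 10, onset = 4.5, offset = 5.0), 0.02,
                 tolerance = 1e-12)
    # 10 Hz: response = 4 frames, baseline = 6 frames before onset
    tr3 <- tr
    tr3[40:45] <- 2           # 0-based 39..44 = baseline of onset 4.5 s
    expect_equal(trialResponse(tr3, 10, onset = 4.5, offset = 5.0),
                 1 / 2 - 1, tolerance = 1e-12)
})

test_that("trial response is invariant to rescaling the trace", {
    set.seed(11)
    tr <- 1 + abs(rnorm(200, 0, 0.1))
    r1 <- trialResponse(tr, 10, onset = 8, offset = 8.5)
    r2 <- trialResponse(3.7 * tr, 10, onset = 8, offset = 8.5)
    expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("out-of-range and degenerate trials raise errors", {
    tr <- rep(1, 50)
    expect_error(trialResponse(tr, 10, onset = 0.2, offset = 0.7), "fit")
    expect_error(trialResponse(tr, 10, onset = 4, offset = 4.9), "fit")
    expect_error(trialResponse(rep(0, 100), 10, onset = 4, offset = 4.5),
                 "baseline")
})

test_that("every scheduled trial yields one response per cell", {
    sched <- makeStimSchedule(190)
    cfg <- defaultSynthConfig(sched, nCells = 2, spontEventRate = 0,
                              noiseSd = 0)
    fov <- simulateFov(cfg, sched, seed = 1)
    rs <- extractResponses(fov)
    expect_equal(dim(responses(rs)), c(2L, 190L))
    expect_true(all(responses(rs) == 0))
    expect_equal(nTrials(rs), 190L)
})

test_that("full-efficacy noiseless responses equal the template response", {
    sched <- tinySchedule(10, gap = 5)
    cfg <- quietConfig(sched, nCells = 1)
    fov <- simulateFov(cfg, sched, efficacy = 1, seed = 2)
    r <- responses(extractResponses(fov))
    expect_equal(as.numeric(r), rep(templateResponse(cfg@template), 10),
                 tolerance = 1e-9)
})

test_that("spike-amplitude curve is linear on noiseless events", {
    tpl <- makeTemplate(0.07, 0.4, 10)
    tr <- rep(1, 400)
    times <- c(10, 20, 30)
    counts <- 1:3
    for (i in 1:3) {
        i0 <- times[i] * 10 + 1
        idx <- i0:(i0 + length(kernel(tpl)) - 1)
        tr[idx] <- tr[idx] + counts[i] * kernel(tpl)
    }
    sac <- spikeAmplitudeCurve(tr, 10, times, counts)
    expect_equal(sac$bins$mean / sac$bins$mean[1], c(1, 2, 3),
                 tolerance = 1e-9)
    expect_gt(sac$slope, 0)
    one <- spikeAmplitudeCurve(tr, 10, times[1], 1)
    expect_equal(nrow(one$bins), 1L)
    expect_true(is.na(one$slope))
    expect_error(spikeAmplitudeCurve(tr, 10, numeric(0), integer(0)),
                 "no events")
})
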