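test_that("mock insertion is pure and hits exactly round(p * n) trials", {
    sched <- makeStimSchedule(190)
    tpl <- makeTemplate(0.07, 0.4, 10)
    tr <- rep(1, (max(offsets(sched)) + 2) * 10)
    expect_identical(insertMockResponses(tr, sched, tpl, p = 0,
                                         frameRate = 10, seed = 1), tr)
    offIdx <- FollowerScan:::timeToFrame(offsets(sched), 10) + 1L
    for (p in c(0.4, 1.0)) {
        out <- insertMockResponses(tr, sched, tpl, p = p, frameRate = 10,
                                   seed = 2)
        expect_equal(sum(out[offIdx + 1L] != tr[offIdx + 1L]),
                     round(p * 190))  # kernel peak lands one frame after start
        expect_true(all(tr == 1))     # input untouched
    }
    expect_error(insertMockResponses(tr, sched, tpl, p = 1.5,
                                     frameRate = 10), "p must")
    expect_error(insertMockResponses(tr[1:100], sched, tpl, p = 1,
                                     frameRate = 10), "fit")
})

test_that("sensitivity curve rises with efficacy and is clean at p = 0", {
    sched <- tinySchedule(40)
    cfg <- tinyConfig(sched, nCells = 8)
    cv <- sensitivityCurve(cfg, sched, efficacyLevels = c(0, 0.5, 1),
                           nCells = 8, k = 3L, nIter = 200, seed = 31)
    df <- cv@curve$detection_fraction
    expect_equal(df[1], 0)
    expect_true(all(diff(df) >= 0))
    expect_gt(df[3], 0.8)
    expect_true(all(diff(cv@curve$mean_z) > 0))
    expect_error(sensitivityCurve(cfg, sched, efficacyLevels = c(1, 0.5)),
                 "ascending")
})

test_that("efficacy estimation inverts the mean-z curve", {
    curve <- new("CalibrationCurve",
                 curve = data.frame(efficacy = c(0.1, 0.4, 0.6, 1),
                                    n_detected = c(0, 5, 9, 10),
                                    detection_fraction = c(0, 0.5, 0.9, 1),
                                    mean_z = c(0.5, 2.1, 3.4, 5.6),
                                    sem_z = rep(0.1, 4)),
                 nCells = 10L, nTrials = 190L, k = 1L, seed = 1L,
                 thresholds = defaultThresholds())
    expect_equal(efficacyEstimate(curve, 2.1), 0.4)
    expect_equal(efficacyEstimate(curve, 0.5), 0.1)
    expect_lt(efficacyEstimate(curve, 0.01), 0.02)
    expect_warning(est <- efficacyEstimate(curve, 9), "clamped")
    expect_equal(est, 1)
    expect_equal(efficacyEstimate(curve, (2.1 + 3.4) / 2), 0.5,
                 tolerance = 1e-9)
})

test_that("relevant-trial responses on noiseless data equal the template", {
    sched <- tinySchedule(20, gap = 5)
    cfg <- quietConfig(sched)
    cv <- sensitivityCurve(cfg, sched, efficacyLevels = c(0.5, 1),
                           nCells = 2, nIter = 100, seed = 4)
    wr <- templateResponse(cfg@template)
    expect_equal(cv@curve$detection_fraction, c(1, 1))
    # relevant trials are exactly the inserted ones, each worth one template
    expect_equal(cv@curve$mean_relevant_dff, c(wr, wr), tolerance = 1e-9)
    # averaged over *all* trials the response scales with p instead
    expect_equal(cv@curve$mean_all_dff, c(0.5 * wr, wr), tolerance = 1e-9)
})
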