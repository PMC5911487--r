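test_that("circular shifts are reproducible and respect the exclusion zone", {
    fov <- constantFov()
    n1 <- circularNull(fov, 1, nIter = 500, exclusion = 1, seed = 3)
    n2 <- circularNull(fov, 1, nIter = 500, exclusion = 1, seed = 3)
    expect_identical(n1@shifts, n2@shifts)
    nFrames <- ncol(traces(fov))
    excl <- 10L                        # 1 s at 10 Hz
    expect_true(all(n1@shifts >= excl))
    expect_true(all(n1@shifts <= nFrames - excl))
    expect_false(any(n1@shifts == 0L))
})

test_that("too-short traces for the exclusion zone raise an error", {
    sched <- StimSchedule(2, 2.5, checkGap = FALSE)
    fov <- FovRecording(matrix(1, 1, 35), frameRate = 10, schedule = sched)
    expect_error(circularNull(fov, 1, nIter = 10, exclusion = 2, seed = 1),
                 "admissible")
})

test_that("a constant trace yields all-zero z values and a neutral label", {
    fov <- constantFov()
    ne <- circularNull(fov, 1, nIter = 200, seed = 8)
    expect_true(all(ne@nullResponses == 0))
    res <- meanZStatistic(fov, 1, nIter = 200, seed = 8)
    expect_equal(res@zValues, rep(0, 200))
    expect_equal(meanZ(res), 0)
    expect_equal(followerLabels(res), "neutral")
})

test_that("compiled shuffle z equals the R rank-sum on extracted nulls", {
    sched <- tinySchedule(15)
    cfg <- tinyConfig(sched, nCells = 1)
    fov <- simulateFov(cfg, sched, efficacy = 0.5, seed = 21)
    res <- meanZStatistic(fov, 1, nIter = 50, seed = 33)
    ne <- circularNull(fov, 1, nIter = 50, seed = 33)
    # the two response-extraction routes agree numerically ...
    fr <- frameRate(fov)
    onI <- FollowerScan:::timeToFrame(onsets(sched), fr)
    offI <- FollowerScan:::timeToFrame(offsets(sched), fr)
    real <- FollowerScan:::cpp_null_responses(traces(fov)[1, ], onI, offI,
                                              4L, 6L, 0L)[1, ]
    expect_equal(real, unname(responses(extractResponses(fov))[1, ]),
                 tolerance = 1e-9)
    # ... and the compiled merge rank-sum matches the R formula exactly,
    # including iterations where a shift aligns null windows onto another
    # trial's real windows and creates exact real/null ties
    zR <- vapply(seq_len(50), function(i)
        ranksumZ(real, ne@nullResponses[i, ]), numeric(1))
    expect_equal(res@zValues, zR, tolerance = 1e-12)
})

test_that("labels follow the thresholds on either side", {
    thr <- defaultThresholds()
    expect_equal(FollowerScan:::classifyMeanZ(2.2, thr), "excited")
    expect_equal(FollowerScan:::classifyMeanZ(-2.4, thr), "inhibited")
    expect_equal(FollowerScan:::classifyMeanZ(0, thr), "neutral")
    expect_equal(FollowerScan:::classifyMeanZ(2.1, thr), "neutral")
    expect_equal(thr@upper, 2.1)
    expect_equal(thr@lower, -2.3)
    expect_error(Thresholds(-1, -2), "upper > 0 > lower")
})

test_that("threshold recalibration takes the sham extremes", {
    thr <- calibrateThresholds(c(-1.2, 0.3, 1.8))
    expect_equal(thr@upper, 1.8)
    expect_equal(thr@lower, -1.2)
    expect_equal(thr@provenance, "recalibrated")
    expect_error(calibrateThresholds(numeric(0)), "no sham")
    expect_error(calibrateThresholds(c(0.5, 1)), "straddle")
})

test_that("recalibrated thresholds admit no follower from their own set", {
    set.seed(99)
    mz <- rnorm(200, 0, 0.7)
    thr <- calibrateThresholds(mz)
    expect_equal(sum(mz > thr@upper | mz < thr@lower), 0L)
})

test_that("a strong synthetic follower is detected, quiet cells are not", {
    sched <- tinySchedule(30)
    cfg <- tinyConfig(sched, nCells = 2)
    fov <- simulateFov(cfg, sched, efficacy = c(1, 0), spikes = 3L, seed = 12)
    res <- detectFollowers(fov, nIter = 300, seed = 6)
    expect_equal(unname(followerLabels(res)[1]), "excited")
    expect_gt(meanZ(res)[1], 2.1)
    expect_equal(unname(followerLabels(res)[2]), "neutral")
    expect_equal(percentFollowers(res), 50)
})

test_that("Kwan-Dan criterion rejects flat cells and accepts strong ones", {
    flat <- extractResponses(constantFov())
    expect_false(any(kwanDanFollowers(flat)))
    sched <- tinySchedule(30)
    cfg <- tinyConfig(sched, nCells = 2)
    fov <- simulateFov(cfg, sched, efficacy = c(1, 0), spikes = 3L, seed = 12)
    kd <- kwanDanFollowers(extractResponses(fov), details = TRUE)
    expect_true(kd$follower[1])
    expect_equal(kd$criterion, 3 * kd$sem_diff)
    expect_error(kwanDanFollowers(
        new("TrialResponseSet", responses = matrix(1, 2, 1),
            windowResponse = 0.4, windowBaseline = 0.6, frameRate = 10)),
        "2 trials")
})

test_that("t-test comparator handles identical and degenerate input", {
    x <- c(1, 2, 3, 4)
    expect_equal(ttestComparator(x, x)$p, 1, tolerance = 1e-12)
    expect_equal(ttestComparator(rep(1, 5), rep(1, 8))$p, 1)
    sep <- ttestComparator(rnorm(50, 5), rnorm(50, 0))
    expect_lt(sep$p, 1e-6)
    expect_gt(sep$t, 0)
    expect_error(ttestComparator(1, 1:5), "at least 2")
})

test_that("comparator methods run through the detector front end", {
    sched <- tinySchedule(20)
    cfg <- tinyConfig(sched, nCells = 2)
    fov <- simulateFov(cfg, sched, efficacy = c(1, 0), spikes = 3L, seed = 14)
    kd <- detectFollowers(fov, method = "kwandan")
    expect_equal(kd@method, "kwandan")
    expect_equal(unname(followerLabels(kd)[1]), "excited")
    tt <- detectFollowers(fov, method = "ttest", nIter = 100, seed = 2)
    expect_equal(tt@method, "ttest")
    expect_true("p_value" %in% names(tt@table))
    expect_equal(unname(followerLabels(tt)[1]), "excited")
})
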