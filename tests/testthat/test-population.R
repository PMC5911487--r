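test_that("FOV z-median is the median of the cells' mean-z values", {
    expect_equal(fovZmedian(c(0, 0, 0)), 0)
    expect_equal(fovZmedian(c(-0.2, 0.1, 0.3)), 0.1)
    expect_equal(fovZmedian(c(-0.2, 0.1, 0.3, 50)), 0.2)  # outlier-robust
    expect_equal(fovZmedian(sample(c(-0.2, 0.1, 0.3))),
                 fovZmedian(c(-0.2, 0.1, 0.3)))
    expect_error(fovZmedian(numeric(0)), "no mean-z")
})

test_that("z-median group comparison behaves at the extremes", {
    same <- c(-0.3, 0, 0.2, 0.5)
    expect_gt(compareZmedians(same, same)$p, 0.9)
    set.seed(1)
    sham <- rnorm(19); stim <- rnorm(47) + 100
    cmp <- compareZmedians(sham, stim)
    expect_lt(cmp$p, 1e-9)
    expect_gt(cmp$stim_median, cmp$sham_median)
    expect_error(compareZmedians(numeric(0), 1:3), "non-empty")
})

test_that("uncorrected chi-square reproduces the hand-derived 2x2 values", {
    # expected counts 5.182/13.818/3.818/10.182 -> chi2 = 0.8736, p = 0.3499
    res <- chi2Test2x2(4, 19, 5, 14)
    expect_equal(res$chi2, 0.8736, tolerance = 5e-4)
    expect_equal(round(res$p, 2), 0.35)
    eq <- chi2Test2x2(5, 10, 5, 10)
    expect_equal(eq$chi2, 0, tolerance = 1e-12)
    expect_equal(eq$p, 1, tolerance = 1e-12)
    expect_error(chi2Test2x2(0, 5, 0, 7), "margin")
    expect_error(chi2Test2x2(6, 5, 1, 7), "successes")
})

test_that("study tallies pool counts and format display percentages", {
    mkRow <- function(cond, cells, fol) {
        data.frame(condition = cond, n_cells = cells, n_followers = fol,
                   n_excited = fol, n_inhibited = 0,
                   percent_followers = 100 * fol / cells,
                   z_median = 0, effective_stimulator = fol > 0)
    }
    summ <- rbind(mkRow("L2/3-anesthetized", 400, 1),
                  mkRow("L2/3-anesthetized", 396, 3),
                  mkRow("L2/3-awake", 432, 8),
                  mkRow("L2/3-awake", 400, 0))
    tal <- tallyStudy(summ)
    an <- tal[tal$condition == "L2/3-anesthetized", ]
    aw <- tal[tal$condition == "L2/3-awake", ]
    expect_equal(an$n_followers, 4)
    expect_equal(an$n_cells, 796)
    expect_equal(an$percent_display, "0.5")
    expect_equal(aw$percent_display, "0.96")
    expect_equal(an$effective_stimulators, 2)
    expect_equal(aw$effective_fraction, 0.5)
    all <- tal[tal$condition == "all", ]
    expect_equal(all$percent_followers,
                 100 * sum(summ$n_followers) / sum(summ$n_cells))
    zero <- tallyStudy(mkRow("sham", 100, 0))
    expect_equal(zero$percent_followers, c(0, 0))
    expect_equal(zero$effective_stimulators, c(0, 0))
})

test_that("radius filtering keeps near cells and flags undersized FOVs", {
    sched <- tinySchedule()
    nF <- as.integer((max(offsets(sched)) + 2) * 10)
    pos <- rbind(c(0, 0), c(100, 0), c(160, 0))
    fov <- FovRecording(matrix(1, 3, nF), 10, sched, patchedCell = 1L,
                        cellPositions = pos)
    filt <- radiusFilter(fov, 150)
    expect_equal(nCells(filt), 2L)
    expect_equal(patchedCell(filt), 1L)
    expect_false(S4Vectors::metadata(filt)$undersized_fov)
    expect_equal(nCells(radiusFilter(fov, Inf)), 3L)
    near <- FovRecording(matrix(1, 3, nF), 10, sched, patchedCell = 1L,
                         cellPositions = rbind(c(0, 0), c(30, 0), c(0, 40)))
    expect_true(S4Vectors::metadata(radiusFilter(near, 150))$undersized_fov)
    noPos <- FovRecording(matrix(1, 3, nF), 10, sched, patchedCell = 1L)
    expect_error(radiusFilter(noPos, 150), "positions")
})

test_that("covariate correlation handles exact, null and degenerate input", {
    x <- 1:20
    expect_equal(covariateCorrelation(x, 2 * x)$r, 1, tolerance = 1e-12)
    set.seed(2)
    ind <- covariateCorrelation(rnorm(500), rnorm(500))
    expect_lt(abs(ind$r), 0.15)
    expect_error(covariateCorrelation(rep(1, 5), rnorm(5)), "zero variance")
    expect_error(covariateCorrelation(1:4, 1:5), "equal length")
    expect_error(covariateCorrelation(1:2, 1:2), "at least 3")
})
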