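test_that("expression bounds keep boundary cells and log exclusions", {
    ts <- mfiFixture()
    out <- filterExpressionBounds(ts)
    expect_setequal(unique(out@data$cell_id), c("b10", "mid50", "b200"))
    expect_equal(nCells(out), 3L)
    expect_setequal(out@filterLog$cell_id, c("lo5", "hi250"))
    expect_setequal(out@filterLog$reason, c("mfi_low", "mfi_high"))
    ## idempotent, and a fully in-bounds set is untouched
    expect_identical(filterExpressionBounds(out)@data, out@data)
})

test_that("coverage filtering honors both modes", {
    times <- seq(0, 720, by = 15)
    full <- madeTrack("full", times)
    short <- madeTrack("short", seq(0, 300, by = 15))
    eight <- madeTrack("eight", seq(0, 480, by = 15))
    gap <- madeTrack("gap", setdiff(times, 60))
    ts <- trackSet(rbind(full, short, eight, gap))

    m <- filterTrackingCoverage(ts, "min_minutes", 480)
    expect_setequal(unique(m@data$cell_id), c("full", "eight"))

    f <- filterTrackingCoverage(ts, "full_period")
    expect_setequal(unique(f@data$cell_id), "full")
    expect_true("gap" %in% f@filterLog$cell_id)

    empty <- trackSet(madeTrack("x", 0)[0, ])
    expect_equal(nCells(filterTrackingCoverage(empty)), 0L)
    expect_error(filterTrackingCoverage(ts, "whenever"))
})

test_that("filters commute and compose idempotently", {
    times <- seq(0, 720, by = 15)
    set.seed(3)
    ts <- trackSet(do.call(rbind, lapply(1:12, function(i)
        madeTrack(sprintf("c%02d", i),
                  seq(0, sample(c(300, 480, 720), 1), by = 15),
                  mfi = rep(exp(rnorm(1, log(60), 1.2)), 1)))))
    ab <- filterTrackingCoverage(filterExpressionBounds(ts))
    ba <- filterExpressionBounds(filterTrackingCoverage(ts))
    expect_identical(sort(unique(ab@data$cell_id)),
                     sort(unique(ba@data$cell_id)))
    expect_identical(filterTrackingCoverage(filterExpressionBounds(ab))@data,
                     ab@data)
})

test_that("caspase onset is the first strict threshold crossing", {
    times <- seq(0, 720, by = 15)
    low <- madeTrack("a", times, caspase = rep(20, length(times)))
    expect_true(is.na(detectCaspaseOnset(low)))

    cr <- madeTrack("b", times,
                    caspase = ifelse(times >= 360, 51, 20))
    expect_equal(detectCaspaseOnset(cr), 360)

    flat50 <- madeTrack("c", times, caspase = rep(50, length(times)))
    expect_true(is.na(detectCaspaseOnset(flat50)))

    ## the onset lies on the sampling grid
    set.seed(9)
    ramp <- madeTrack("d", times, caspase = cumsum(runif(length(times), 0, 4)))
    expect_true(detectCaspaseOnset(ramp) %in% times)

    ts <- trackSet(rbind(low, cr, flat50))
    ons <- detectCaspaseOnsets(ts)
    expect_equal(ons$onset[ons$cell_id == "b"], 360)
    expect_equal(sum(is.na(ons$onset)), 2L)
})

test_that("peak-window activity respects the window", {
    times <- seq(0, 480, by = 15)
    shape <- exp(-(times - 240)^2 / 5000)
    tr <- madeTrack("a", times, ratio = 0.3 + shape)
    expect_equal(peakWindowActivity(tr, c(0, 480)), max(0.3 + shape))
    expect_equal(peakWindowActivity(tr, c(0, 180)),
                 max((0.3 + shape)[times <= 180]))
    expect_lt(peakWindowActivity(tr, c(0, 180)),
              peakWindowActivity(tr, c(0, 480)))
    const <- madeTrack("b", times, ratio = rep(0.7, length(times)))
    expect_equal(peakWindowActivity(const, c(0, 480)), 0.7)
    expect_error(peakWindowActivity(tr, c(0, 600)), "coverage")
})

test_that("outcome grouping computes separation statistics", {
    peaks <- data.frame(cell_id = c("a", "b", "c", "d"),
                        peak = c(3, 4, 1, 1))
    onsets <- data.frame(cell_id = c("a", "b", "c", "d"),
                         onset = c(480, 600, NA, NA))
    g <- groupByOutcome(peaks, onsets)
    expect_equal(g@fractionAbove, 1)
    expect_equal(sort(g@apoptotic), c(3, 4))

    same <- groupByOutcome(
        data.frame(cell_id = letters[1:6], peak = rep(c(1, 2, 3), 2)),
        data.frame(cell_id = letters[1:6],
                   onset = c(1, 1, 1, NA, NA, NA)))
    expect_equal(same@cohensD, 0)

    oneSided <- groupByOutcome(peaks,
                               data.frame(cell_id = peaks$cell_id,
                                          onset = rep(NA_real_, 4)))
    expect_false(oneSided@defined)
})

test_that("commitment curve recovers a known logistic threshold", {
    set.seed(21)
    peaks <- runif(2000)
    prob <- plogis(20 * (peaks - 0.6))
    outcomes <- runif(2000) < prob
    cc <- commitmentCurve(peaks, outcomes, bins = 10)
    expect_lt(abs(cc$midpoint - 0.6), 0.05)
    frac <- cc$bins$fraction[cc$bins$n > 0]
    expect_true(all(frac >= 0 & frac <= 1))

    allNo <- commitmentCurve(peaks, rep(FALSE, 2000))
    expect_false(allNo$defined)
    expect_true(all(allNo$bins$fraction[allNo$bins$n > 0] == 0))
})

test_that("the linear window selector matches brute force", {
    ## piecewise-linear cumulative curve: flat, steep linear, saturating
    time <- seq(0, 570, by = 30)   # 20 points
    frac <- c(rep(0, 5), seq(0.05, 0.55, length.out = 8),
              0.58 + 0.02 * sqrt(seq_len(7)))
    w <- jnknoise:::.selectLinearWindow(time, frac, minPoints = 4)

    start <- which(frac > 0)[1]
    best <- NULL; bestR2 <- -Inf
    for (a in start:(length(time) - 3)) {
        for (b in (a + 3):length(time)) {
            idx <- a:b
            if (var(frac[idx]) == 0) next
            r2 <- suppressWarnings(
                summary(lm(frac[idx] ~ time[idx]))$r.squared)
            if (r2 > bestR2 + 1e-12) { bestR2 <- r2; best <- idx }
        }
    }
    expect_identical(w, best)
})

test_that("onset-curve regression compares slopes across conditions", {
    time <- seq(0, 570, by = 30)
    lin <- function(s) pmin(pmax(s * (time - 120), 0), 0.9)
    a <- data.frame(time = time, fraction = lin(0.002))
    b <- data.frame(time = time, fraction = lin(0.004))
    res <- onsetCurveRegression(list(slow = a, fast = b))
    ratio <- res$pairwise$ratio[res$pairwise$a == "fast" |
                                res$pairwise$b == "fast"]
    sl <- res$slopes
    expect_equal(sl$slope[sl$condition == "fast"] /
                 sl$slope[sl$condition == "slow"], 2, tolerance = 0.1)

    same <- onsetCurveRegression(list(x = a, y = a))
    expect_equal(same$pairwise$difference, 0)
    expect_equal(same$pairwise$p, 1)

    expect_error(onsetCurveRegression(list(a)), "at least 2")
    expect_error(onsetCurveRegression(list(x = a, y = b), minPoints = 2),
                 "at least 3")
})
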