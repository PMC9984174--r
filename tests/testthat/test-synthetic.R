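test_that("expression tables hit their configured noise targets", {
    cfg <- generatorConfig(nCells = 2000L, seed = 3L,
                           cov = c(zak = 0.4, mkk4 = 0.4, mkk7 = 0.4,
                                   jnk = 0.4, pakt = 0.4))
    tab <- genExpressionTable(cfg)
    for (k in jnknoise:::.COMPONENTS) {
        cv <- coefficientOfVariation(tab@data[[k]]) / 100
        expect_gt(cv, 0.38); expect_lt(cv, 0.42)
        expect_equal(mean(tab@data[[k]]), 1, tolerance = 0.05)
    }
    expect_identical(genExpressionTable(cfg)@data, tab@data)

    tight <- genExpressionTable(generatorConfig(nCells = 10L, seed = 1L,
        cov = c(zak = 1e-4, mkk4 = 1e-4, mkk7 = 1e-4, jnk = 1e-4,
                pakt = 1e-4)))
    expect_equal(unname(unlist(tight@data[1, jnknoise:::.COMPONENTS])),
                 rep(1, 5), tolerance = 1e-3)
    expect_error(generatorConfig(cov = c(zak = -0.1, mkk4 = 0.4,
                                         mkk7 = 0.4, jnk = 0.4,
                                         pakt = 0.4)))
})

test_that("priming shifts means multiplicatively and leaves noise alone", {
    tab <- smallTable(400, seed = 5)
    ones <- c(zak = 1, mkk4 = 1, mkk7 = 1, jnk = 1, pakt = 1)
    expect_identical(applyPrimingShift(tab, ones)@data, tab@data)

    fc <- ones; fc["jnk"] <- 2
    shifted <- applyPrimingShift(tab, fc)
    expect_equal(mean(shifted@data$jnk), 2 * mean(tab@data$jnk))
    expect_equal(coefficientOfVariation(shifted@data$jnk),
                 coefficientOfVariation(tab@data$jnk))
    expect_error(applyPrimingShift(tab, ones * 0), "> 0")
})

test_that("priming up-shift raises the predicted ensemble response", {
    tab <- smallTable(120, seed = 9)
    primed <- applyPrimingShift(tab, c(zak = 1.5, mkk4 = 1.5, mkk7 = 1.5,
                                       jnk = 1.5, pakt = 1.5))
    base <- simulateEnsemble(tab, duration = 90, grid = 3)
    up <- simulateEnsemble(primed, duration = 90, grid = 3)
    expect_gt(mean(up@stimPeak[!up@failed]),
              mean(base@stimPeak[!base@failed]))
})

test_that("synthetic tracks have the configured shape and are pure", {
    cfg <- generatorConfig(nCells = 60L, seed = 4L, sampleInterval = 15,
                           traceDuration = 240, onsetBand = c(120, 240))
    tab <- genExpressionTable(cfg)
    ens <- simulateEnsemble(tab, duration = 90, grid = 3)
    gen <- genCellTracks(ens, cfg)
    counts <- table(gen$tracks@data$cell_id)
    expect_true(all(counts == 17))   # 240/15 + 1 samples

    gen2 <- genCellTracks(ens, cfg)
    expect_identical(gen$tracks@data, gen2$tracks@data)

    ## flat drive with zero noise gives constant ratio traces
    flat <- madeEnsemble(basal = c(5, 20), stim = c(5, 20))
    cfg0 <- generatorConfig(nCells = 2L, seed = 1L, traceNoiseSD = 0,
                            traceDuration = 240, onsetBand = c(120, 240))
    tr0 <- genCellTracks(flat, cfg0)$tracks@data
    spread <- tapply(tr0$ktr_ratio, tr0$cell_id,
                     function(x) diff(range(x)))
    expect_lt(max(spread), 1e-6)
})

test_that("the population-average trace peaks near the configured time", {
    cfg <- generatorConfig(nCells = 150L, seed = 6L, peakTime = 120,
                           traceDuration = 480)
    tab <- genExpressionTable(cfg)
    ens <- simulateEnsemble(tab, duration = 90, grid = 3)
    gen <- genCellTracks(ens, cfg)
    d <- gen$tracks@data
    avg <- tapply(d$ktr_ratio, d$time_min, mean)
    tPeak <- as.numeric(names(avg))[which.max(avg)]
    ## reporter kinetics lag the activity drive by a few minutes
    expect_gte(tPeak, 105); expect_lte(tPeak, 165)
})

test_that("commitment outcomes follow the logistic layer", {
    cfg <- generatorConfig(nCells = 2000L, seed = 12L)
    set.seed(99)
    peaks <- setNames(runif(2000), sprintf("cell_%05d", 1:2000))
    out <- genCaspaseOutcomes(peaks, cfg)
    cc <- commitmentCurve(peaks, out$outcomes$apoptotic, bins = 10)
    expect_lt(abs(cc$midpoint - cfg@theta), 0.05)

    ## onsets lie on the sample grid inside the band, and traces cross 50
    ons <- out$outcomes$onset[out$outcomes$apoptotic]
    grid <- seq(0, cfg@traceDuration, by = cfg@sampleInterval)
    expect_true(all(ons %in% grid))
    expect_true(all(ons >= cfg@onsetBand[1]))
    firstApo <- out$outcomes$cell_id[out$outcomes$apoptotic][1]
    tr <- out$traces[out$traces$cell_id == firstApo, ]
    expect_equal(detectCaspaseOnset(data.frame(time_min = tr$time_min,
                                               caspase_mfi = tr$caspase_mfi)),
                 out$outcomes$onset[out$outcomes$cell_id == firstApo])

    ## raising the threshold modifier lowers the apoptotic fraction
    up <- generatorConfig(nCells = 2000L, seed = 12L,
                          thresholdModifier = 1.4)
    outUp <- genCaspaseOutcomes(peaks, up)
    expect_lt(mean(outUp$outcomes$apoptotic), mean(out$outcomes$apoptotic))

    ## a near-infinite slope becomes a deterministic threshold
    hard <- generatorConfig(nCells = 2000L, seed = 12L, beta = 1e6)
    outH <- genCaspaseOutcomes(peaks, hard)
    expect_identical(outH$outcomes$apoptotic[peaks > 0.601],
                     rep(TRUE, sum(peaks > 0.601)))
    expect_identical(outH$outcomes$apoptotic[peaks < 0.599],
                     rep(FALSE, sum(peaks < 0.599)))
})
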