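test_that("network construction scales pools by the profile", {
    p <- defaultParams()
    net <- nominalNet(p)
    y0 <- jnknoise:::.initialState(net)
    expect_equal(unname(stateSums(t(as.matrix(y0)))[1, ]),
                 unname(p@totals))

    half <- buildNetwork(expressionProfile(mkk7 = 0.5), p)
    y0h <- jnknoise:::.initialState(half)
    expect_equal(unname(y0h["M7"]), unname(p@totals["mkk7"]) * 0.5)

    expect_error(buildNetwork(c(zak = -1, mkk4 = 1, mkk7 = 1, jnk = 1,
                                pakt = 1), p),
                 "finite and >= 0")
    expect_error(expressionProfile(jnk = -0.1), "finite and >= 0")
})

test_that("zeroed substrates and cross-talk behave as structural limits", {
    p <- defaultParams()
    noJnk <- simulateCell(buildNetwork(expressionProfile(jnk = 0), p),
                          1000, duration = 60, grid = 2)
    expect_true(all(abs(noJnk@activeJNK) < 1e-10))

    noAkt <- simulateCell(buildNetwork(expressionProfile(pakt = 0), p),
                          1000, duration = 60, grid = 2, keepState = TRUE)
    expect_true(all(abs(noAkt@state[, c("M4i", "M7i")]) < 1e-10))
})

test_that("basal stimulus holds the pre-stimulus steady state", {
    traj <- simulateCell(nominalNet(), 50, duration = 120, grid = 5,
                         basal = 50)
    expect_lt(max(traj@activeJNK) - min(traj@activeJNK),
              1e-6 * max(traj@activeJNK, 1e-12) + 1e-9)
})

test_that("mass is conserved along stimulated trajectories", {
    p <- defaultParams()
    tab <- smallTable(20, seed = 11)
    for (i in seq_len(nrow(tab@data))) {
        prof <- unlist(tab@data[i, jnknoise:::.COMPONENTS])
        net <- buildNetwork(prof, p)
        traj <- simulateCell(net, 1000, duration = 60, grid = 10,
                             keepState = TRUE)
        tot <- p@totals * prof[names(p@totals)]
        sums <- stateSums(traj@state)
        rel <- abs(sweep(sums, 2, tot) ) / rep(pmax(tot, 1e-12),
                                               each = nrow(sums))
        expect_lt(max(rel), 1e-6)
        expect_gt(min(traj@state), -1e-8)
    }
})

test_that("identical inputs give bit-identical trajectories", {
    net <- nominalNet()
    a <- simulateCell(net, 1000, duration = 90, grid = 1)
    b <- simulateCell(net, 1000, duration = 90, grid = 1)
    expect_identical(a@activeJNK, b@activeJNK)
})

test_that("peakActiveJNK returns the series maximum", {
    expect_equal(peakActiveJNK(rep(2.5, 10)), 2.5)
    expect_equal(peakActiveJNK(c(0, 3, 1)), 3)
    expect_equal(peakActiveJNK(seq(0, 5, by = 0.5)), 5)  # monotone rise
    expect_error(peakActiveJNK(numeric(0)), "empty")
})

test_that("feedback knockout zeroes exactly the feedback parameters", {
    p <- defaultParams()
    off <- disableFeedback(p)
    expect_identical(off, disableFeedback(off))   # idempotent
    expect_equal(unname(off@rates["kfb"]), 0)
    expect_equal(unname(off@rates["gfb"]), 1)
    keep <- setdiff(names(p@rates), c("kfb", "gfb"))
    expect_identical(p@rates[keep], off@rates[keep])
    expect_identical(p@totals, off@totals)
    expect_false(feedbackEnabled(off))
    expect_true(feedbackEnabled(p))
})

test_that("feedback raises the nominal saturated amplitude", {
    p <- defaultParams()
    full <- peakActiveJNK(simulateCell(nominalNet(p), 1000,
                                       duration = 120, grid = 2))
    nofb <- peakActiveJNK(simulateCell(
        buildNetwork(expressionProfile(), disableFeedback(p)), 1000,
        duration = 120, grid = 2))
    expect_gt(full, nofb)
})

test_that("calibration anchors the nominal saturated response", {
    p <- defaultParams()
    traj <- simulateCell(nominalNet(p), 1000, duration = 120, grid = 0.5)
    tPeak <- traj@time[which.max(traj@activeJNK)]
    expect_lt(abs(tPeak - 30), 1)    # peak at 30 min
    basal <- peakActiveJNK(simulateCell(nominalNet(p), 50,
                                        duration = 120, grid = 2))
    expect_lt(basal, peakActiveJNK(traj))    # monotone dose response
    ## normalization anchor: highest simulated value defines 1
    expect_equal(max(traj@activeJNK) / peakActiveJNK(traj), 1)
    expect_error(calibrateNominal(minHill = 50), "Hill")
})

test_that("dose response reports hill estimates and saturation", {
    p <- defaultParams()
    st <- exp(seq(log(50), log(1000), length.out = 12))
    dr <- doseResponse(nominalNet(p), st, duration = 120, grid = 2)
    expect_true(dr$reliable)
    expect_gte(dr$hill, 2)
    drN <- doseResponse(buildNetwork(expressionProfile(),
                                     disableFeedback(p)),
                        st, duration = 120, grid = 2)
    ## the feedback ignition is the steep part of the response
    expect_gt(dr$hillMax, drN$hillMax)

    flat <- doseResponse(nominalNet(p), rep(1000, 4), duration = 60,
                         grid = 5)
    expect_true(is.na(flat$hill))
    expect_false(flat$reliable)

    pk1 <- peakActiveJNK(simulateCell(nominalNet(p), 1000,
                                      duration = 120, grid = 2))
    pk2 <- peakActiveJNK(simulateCell(nominalNet(p), 2000,
                                      duration = 120, grid = 2))
    expect_lt(abs(pk2 - pk1) / pk1, 0.01)   # beyond saturation
})

test_that("adaptive integration matches the fixed-step oracle", {
    net <- nominalNet()
    for (stim in c(50, 1000)) {
        ada <- simulateCell(net, stim, duration = 60, grid = 1)
        rk4 <- simulateFixedStep(net, stim, duration = 60, grid = 1,
                                 dt = 0.01)
        scale <- max(abs(ada@activeJNK), 1e-12)
        expect_lt(max(abs(ada@activeJNK - rk4@activeJNK)) / scale, 1e-3)
    }
})

test_that("parameter sets survive a JSON round trip", {
    p <- defaultParams()
    f <- tempfile(fileext = ".json")
    writeKineticParameters(p, f)
    q <- readKineticParameters(f)
    expect_equal(p@rates, q@rates)
    expect_equal(p@totals, q@totals)
    doc <- jsonlite::read_json(f)
    expect_equal(doc$schema_version, 1L)
})
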