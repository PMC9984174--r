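test_that("normalization to reference means is exact and idempotent", {
    tab <- smallTable(40)
    ref <- colMeans(tab@data[jnknoise:::.COMPONENTS])
    norm <- normalizeToReference(tab, ref)
    expect_equal(unname(colMeans(norm@data[jnknoise:::.COMPONENTS])),
                 rep(1, 5), tolerance = 1e-9)
    again <- normalizeToReference(norm, colMeans(norm@data[jnknoise:::.COMPONENTS]))
    expect_equal(again@data, norm@data, tolerance = 1e-12)

    doubled <- tab
    doubled@data[jnknoise:::.COMPONENTS] <-
        tab@data[jnknoise:::.COMPONENTS] * 2
    normD <- normalizeToReference(doubled, ref)
    expect_equal(normD@data$jnk, norm@data$jnk * 2)  # linearity

    two <- expressionTable(data.frame(cell_id = c("a", "b"), zak = c(2, 4),
                                      mkk4 = 1, mkk7 = 1, jnk = 1,
                                      pakt = 1))
    out <- normalizeToReference(two, c(zak = 2, mkk4 = 1, mkk7 = 1,
                                       jnk = 1, pakt = 1))
    expect_equal(out@data$zak, c(1, 2))

    expect_error(normalizeToReference(tab, c(zak = 0, mkk4 = 1, mkk7 = 1,
                                             jnk = 1, pakt = 1)), "> 0")
})

test_that("ensembles are deterministic and sized like their table", {
    idt <- expressionTable(data.frame(cell_id = sprintf("c%d", 1:4),
                                      zak = 1, mkk4 = 1, mkk7 = 1,
                                      jnk = 1, pakt = 1),
                           provenance = "synthetic", normalized = TRUE)
    ens <- simulateEnsemble(idt, duration = 90, grid = 3)
    expect_equal(nCells(ens), 4L)
    expect_equal(length(unique(round(ens@stimPeak, 10))), 1L)

    tab <- smallTable(12)
    a <- simulateEnsemble(tab, duration = 90, grid = 3)
    b <- simulateEnsemble(tab, duration = 90, grid = 3)
    expect_identical(a@stimPeak, b@stimPeak)
    expect_identical(a@paramHash, b@paramHash)

    empty <- expressionTable(data.frame(cell_id = character(), zak = numeric(),
                                        mkk4 = numeric(), mkk7 = numeric(),
                                        jnk = numeric(), pakt = numeric()))
    e <- simulateEnsemble(empty, duration = 60)
    expect_equal(nCells(e), 0L)
})

test_that("impaired fraction follows the boundary-inclusive definition", {
    expect_equal(impairedFraction(madeEnsemble(basal = c(1, 1, 1, 1),
                                               stim = c(0.5, 0.9, 2, 3))),
                 0.5)
    expect_equal(impairedFraction(madeEnsemble(basal = c(1, 1),
                                               stim = c(2, 3))), 0)
    expect_equal(impairedFraction(madeEnsemble(basal = c(1, 1, 1),
                                               stim = c(1, 1, 1))), 1)
    expect_error(impairedFraction(
        madeEnsemble(basal = 1, stim = 1, failed = TRUE)), "empty")
})

test_that("normalized peaks are scale-consistent and noise-free tables degenerate", {
    tab <- smallTable(30)
    ens <- simulateEnsemble(tab, duration = 90, grid = 3)
    ok <- !ens@failed
    expect_equal(coefficientOfVariation(ens@stimNorm[ok]),
                 coefficientOfVariation(ens@stimPeak[ok]))
    expect_true(all(ens@stimNorm[ok] >= 0 & ens@stimNorm[ok] <= 1))

    flat <- genExpressionTable(generatorConfig(nCells = 5L, seed = 1L,
        cov = c(zak = 1e-5, mkk4 = 1e-5, mkk7 = 1e-5, jnk = 1e-5,
                pakt = 1e-5)))
    ensF <- simulateEnsemble(flat, duration = 90, grid = 3)
    expect_lt(coefficientOfVariation(ensF@stimPeak), 0.1)
    expect_true(impairedFraction(ensF) %in% c(0, 1))
})

test_that("feedback comparison reproduces the knockout contrasts", {
    tab <- smallTable(300, seed = 7)
    cmp <- feedbackComparison(tab, duration = 120, grid = 3)
    expect_gt(cmp$summary$amplitude_ratio, 1)
    expect_gt(cmp$summary$cov_nofb, cmp$summary$cov_full)
    expect_identical(cmp$full@cellId, cmp$nofeedback@cellId)

    again <- feedbackComparison(tab, duration = 120, grid = 3)
    expect_identical(cmp$full@stimPeak, again$full@stimPeak)
})

test_that("bulk-profile predictions are normalized per set", {
    p <- defaultParams()
    one <- predictBulkResponse(list(only = expressionProfile()), p,
                               duration = 90, grid = 3)
    expect_equal(one$predicted, 1)

    twin <- predictBulkResponse(list(a = expressionProfile(),
                                     b = expressionProfile()), p,
                                duration = 90, grid = 3)
    expect_equal(twin$predicted[1], twin$predicted[2])

    pair <- predictBulkResponse(
        list(nominal = expressionProfile(),
             halved = expressionProfile(0.5, 0.5, 0.5, 0.5, 0.5)), p,
        duration = 90, grid = 3)
    expect_lt(pair$predicted[pair$name == "halved"], 1)
    expect_equal(pair$predicted[pair$name == "nominal"], 1)

    bad <- predictBulkResponse(
        list(ok = expressionProfile(),
             broken = c(zak = -1, mkk4 = 1, mkk7 = 1, jnk = 1, pakt = 1)),
        p, duration = 90, grid = 3)
    expect_true(is.na(bad$peak[bad$name == "broken"]))
    expect_match(bad$error[bad$name == "broken"], "finite")
})

test_that("ensemble CSV export carries the per-cell schema and sidecar", {
    ens <- madeEnsemble(basal = c(0.1, 0.2), stim = c(1, 2))
    f <- tempfile(fileext = ".csv")
    writeEnsembleResult(ens, f, extra = list(note = "unit"))
    d <- read.csv(f)
    expect_identical(names(d), c("cell_id", "basal_peak", "stim_peak",
                                 "basal_norm", "stim_norm", "failed"))
    side <- jsonlite::read_json(paste0(f, ".json"))
    expect_equal(side$n_cells, 2L)
    expect_equal(side$note, "unit")
})
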