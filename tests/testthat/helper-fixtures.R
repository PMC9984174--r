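## shared fixtures: everything is built in code at test time

defaultParams <- function() defaultKineticParameters()

nominalNet <- function(params = defaultParams())
    buildNetwork(expressionProfile(), params)

## small synthetic expression table with a fixed seed
smallTable <- function(n = 50, seed = 7)
    genExpressionTable(generatorConfig(nCells = as.integer(n),
                                       seed = as.integer(seed)))

## hand-built ensemble result, for the impaired-fraction arithmetic
madeEnsemble <- function(basal, stim, failed = rep(FALSE, length(basal))) {
    mx <- max(c(basal, stim))
    new("EnsembleResult",
        cellId = sprintf("c%02d", seq_along(basal)),
        basalPeak = basal, stimPeak = stim,
        basalNorm = basal / mx, stimNorm = stim / mx,
        failed = failed, feedback = "full", seed = NA_integer_,
        paramHash = "test")
}

## long-format track built from per-cell series
madeTrack <- function(cell_id, times, ratio = rep(1, length(times)),
                      mfi = rep(50, length(times)),
                      caspase = rep(0, length(times))) {
    data.frame(cell_id = cell_id, time_min = times, ktr_ratio = ratio,
               reporter_mfi = mfi, caspase_mfi = caspase)
}

## the five-track reporter-expression fixture (mean MFIs 5/10/50/200/250)
mfiFixture <- function() {
    times <- seq(0, 480, by = 15)
    trackSet(do.call(rbind, Map(function(id, m)
        madeTrack(id, times, mfi = rep(m, length(times))),
        c("lo5", "b10", "mid50", "b200", "hi250"),
        c(5, 10, 50, 200, 250))))
}

## per-protein sums of a full state matrix
stateSums <- function(state) {
    cbind(zak = rowSums(state[, c("Z", "Za"), drop = FALSE]),
          mkk4 = rowSums(state[, c("M4", "M4p", "M4pp", "M4i"),
                               drop = FALSE]),
          mkk7 = rowSums(state[, c("M7", "M7p", "M7pp", "M7f", "M7fp",
                                   "M7fpp", "M7i"), drop = FALSE]),
          jnk = rowSums(state[, c("J", "Jp", "Jpp"), drop = FALSE]))
}
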