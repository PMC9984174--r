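#' Default kinase translocation reporter parameters
#'
#' Follows the published four-state KTR framework (phosphorylation-gated
#' nuclear import/export of a fluorescent substrate): the unphosphorylated
#' reporter is nucleus-biased, the phosphorylated reporter cytoplasm-biased,
#' with first-order shuttling on the minutes scale so the reporter tracks
#' activity changes much faster than the hours-scale activity dynamics it
#' is used to read out.  Exact constants are configurable; the activity
#' saturation cap defaults to 200 concentration units.
#'
#' @param kPhos phosphorylation rate per unit active kinase (1/min/AU).
#' @param kDephos constitutive dephosphorylation rate (1/min).
#' @param importU,exportU nuclear import/export of the unphosphorylated
#'   form (1/min).
#' @param importP,exportP nuclear import/export of the phosphorylated
#'   form (1/min).
#' @param cap activity saturation point for inversion (AU).
#' @return a [ReporterParameters-class] object.
#' @export
defaultReporterParameters <- function(kPhos = 0.004, kDephos = 0.3,
                                      importU = 0.6, exportU = 0.12,
                                      importP = 0.1, exportP = 0.6,
                                      cap = 200) {
    new("ReporterParameters", kPhos = kPhos, kDephos = kDephos,
        importU = importU, exportU = exportU, importP = importP,
        exportP = exportP, cap = cap)
}

## steady state of the four-state reporter at constant activity; returns
## the (Un, Uc, Pn, Pc) occupancies summing to 1
.reporterSteadyState <- function(activity, rp) {
    ka <- rp@kPhos * activity
    kd <- rp@kDephos
    A <- rbind(
        c(-(rp@exportU + ka), rp@importU, kd, 0),
        c(rp@exportU, -(rp@importU + ka), 0, kd),
        c(ka, 0, -(rp@exportP + kd), rp@importP),
        c(1, 1, 1, 1))
    b <- c(0, 0, 0, 1)
    solve(A, b)
}

#' Steady-state cytoplasmic:nuclear ratio at a given kinase activity
#'
#' The equilibrium C:N ratio of total reporter under the four-state
#' (phospho x compartment) model; strictly increasing in activity from the
#' unphosphorylated compartment balance (activity 0) toward the fully
#' phosphorylated balance (saturating activity).
#'
#' @param activity active-kinase concentration(s), >= 0 (AU).
#' @param rp a [ReporterParameters-class] object.
#' @return numeric C:N ratio(s).
#' @examples
#' rp <- defaultReporterParameters()
#' steadyStateRatio(c(0, 50, 200), rp)
#' @export
steadyStateRatio <- function(activity, rp = defaultReporterParameters()) {
    if (any(!is.finite(activity)) || any(activity < 0))
        stop("activity must be finite and >= 0")
    vapply(activity, function(a) {
        s <- .reporterSteadyState(a, rp)
        (s[2] + s[4]) / (s[1] + s[3])
    }, numeric(1))
}

#' Convert C:N ratios to active-kinase concentration
#'
#' Numerical inverse of [steadyStateRatio()] by bracketed root finding on
#' `[0, cap]` (tolerance 1e-9).  Ratios at or below the zero-activity
#' model minimum map to 0; ratios at or above the ratio corresponding to
#' the cap map to the cap with the `saturated` flag set, so measurement
#' imprecision beyond saturation cannot inflate the activity estimate.
#'
#' @param ratio positive, finite C:N ratio(s).
#' @param rp a [ReporterParameters-class] object.
#' @return data.frame with columns `activity` (clipped to `[0, cap]`),
#'   `normalized` (activity/cap, in `[0, 1]`) and `saturated`.
#' @examples
#' rp <- defaultReporterParameters()
#' ratioToActivity(steadyStateRatio(80, rp), rp)
#' @export
ratioToActivity <- function(ratio, rp = defaultReporterParameters()) {
    if (any(!is.finite(ratio))) stop("ratio must be finite")
    if (any(ratio <= 0)) stop("ratio must be > 0")
    r0 <- steadyStateRatio(0, rp)
    rcap <- steadyStateRatio(rp@cap, rp)
    act <- vapply(ratio, function(r) {
        if (r <= r0) return(0)
        if (r >= rcap) return(rp@cap)
        stats::uniroot(function(a) steadyStateRatio(a, rp) - r,
                       interval = c(0, rp@cap), tol = 1e-9)$root
    }, numeric(1))
    data.frame(activity = act, normalized = act / rp@cap,
               saturated = act >= rp@cap)
}

#' Normalize concentrations to the highest value
#'
#' @param values non-empty numeric vector with a positive maximum.
#' @return `values / max(values)`, in `[0, 1]` for non-negative input.
#' @examples
#' normalizeToMax(c(1, 2, 4))
#' @export
normalizeToMax <- function(values) {
    if (length(values) == 0) stop("empty input")
    if (any(!is.finite(values))) stop("values must be finite")
    mx <- max(values)
    if (mx <= 0) stop("maximum must be > 0")
    values / mx
}

#' Simulate reporter traces under time-varying activity
#'
#' Forward dynamic model of the reporter (used for synthetic trace
#' generation, not for inversion): fixed-step RK4 on the four-state linear
#' system, vectorized across cells, starting each cell at the reporter
#' steady state of its initial activity.
#'
#' @param activity matrix (cells x length(times)) of active-kinase
#'   concentration driving the reporter.
#' @param times strictly increasing sample times (minutes) at which
#'   `activity` is given and the ratio is returned; internally the solver
#'   subdivides to steps of at most `dtMax`.
#' @param rp a [ReporterParameters-class] object.
#' @param dtMax maximum internal step (minutes).
#' @return matrix (cells x length(times)) of C:N ratios.
#' @export
simulateReporterTraces <- function(activity, times,
                                   rp = defaultReporterParameters(),
                                   dtMax = 0.5) {
    stopifnot(is.matrix(activity), ncol(activity) == length(times),
              all(diff(times) > 0))
    n <- nrow(activity)
    ## initial condition: steady state at the first activity value
    st <- matrix(0, n, 4)
    for (i in seq_len(n))
        st[i, ] <- .reporterSteadyState(activity[i, 1], rp)
    Un <- st[, 1]; Uc <- st[, 2]; Pn <- st[, 3]; Pc <- st[, 4]
    iU <- rp@importU; eU <- rp@exportU
    iP <- rp@importP; eP <- rp@exportP; kd <- rp@kDephos
    deriv <- function(Un, Uc, Pn, Pc, ka) {
        list(dUn = iU * Uc - eU * Un - ka * Un + kd * Pn,
             dUc = eU * Un - iU * Uc - ka * Uc + kd * Pc,
             dPn = iP * Pc - eP * Pn + ka * Un - kd * Pn,
             dPc = eP * Pn - iP * Pc + ka * Uc - kd * Pc)
    }
    out <- matrix(NA_real_, n, length(times))
    out[, 1] <- (Uc + Pc) / (Un + Pn)
    for (j in seq_len(length(times) - 1)) {
        span <- times[j + 1] - times[j]
        nSub <- max(1L, ceiling(span / dtMax))
        dt <- span / nSub
        for (s in seq_len(nSub)) {
            ## linear interpolation of the driving activity within the span
            f0 <- (s - 1) / nSub; f1 <- (s - 0.5) / nSub; f2 <- s / nSub
            kaAt <- function(f)
                rp@kPhos * ((1 - f) * activity[, j] + f * activity[, j + 1])
            k1 <- deriv(Un, Uc, Pn, Pc, kaAt(f0))
            k2 <- deriv(Un + dt / 2 * k1$dUn, Uc + dt / 2 * k1$dUc,
                        Pn + dt / 2 * k1$dPn, Pc + dt / 2 * k1$dPc, kaAt(f1))
            k3 <- deriv(Un + dt / 2 * k2$dUn, Uc + dt / 2 * k2$dUc,
                        Pn + dt / 2 * k2$dPn, Pc + dt / 2 * k2$dPc, kaAt(f1))
            k4 <- deriv(Un + dt * k3$dUn, Uc + dt * k3$dUc,
                        Pn + dt * k3$dPn, Pc + dt * k3$dPc, kaAt(f2))
            Un <- Un + dt / 6 * (k1$dUn + 2 * k2$dUn + 2 * k3$dUn + k4$dUn)
            Uc <- Uc + dt / 6 * (k1$dUc + 2 * k2$dUc + 2 * k3$dUc + k4$dUc)
            Pn <- Pn + dt / 6 * (k1$dPn + 2 * k2$dPn + 2 * k3$dPn + k4$dPn)
            Pc <- Pc + dt / 6 * (k1$dPc + 2 * k2$dPc + 2 * k3$dPc + k4$dPc)
        }
        out[, j + 1] <- (Uc + Pc) / (Un + Pn)
    }
    out
}

#' Append activity columns to a ratio table
#'
#' Convenience conversion used on exported imaging tables: reads the
#' `ktr_ratio` column and appends `activity`, `activity_norm` (relative to
#' the set maximum) and `saturated`.
#'
#' @param table data.frame with a `ktr_ratio` column.
#' @param rp a [ReporterParameters-class] object.
#' @return the augmented data.frame.
#' @export
convertRatioColumn <- function(table, rp = defaultReporterParameters()) {
    if (!"ktr_ratio" %in% names(table))
        stop("table must contain a ktr_ratio column")
    est <- ratioToActivity(table$ktr_ratio, rp)
    table$activity <- est$activity
    table$activity_norm <- if (max(est$activity) > 0)
        est$activity / max(est$activity) else est$activity
    table$saturated <- est$saturated
    table
}
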