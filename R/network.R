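#' Create a single-cell expression profile
#'
#' Relative abundances of the five network components, normalized so the
#' reference population mean of each component is 1.  The nominal
#' (population-average) cell is the all-ones profile.
#'
#' @param zak,mkk4,mkk7,jnk,pakt relative abundances (dimensionless,
#'   finite, >= 0).  `pakt` is the phospho-Akt (Ser473) level and scales
#'   the inhibitory cross-talk flux.
#' @return named numeric vector of length 5.
#' @examples
#' expressionProfile()              # nominal cell
#' expressionProfile(jnk = 0.5)     # JNK-low cell
#' @export
expressionProfile <- function(zak = 1, mkk4 = 1, mkk7 = 1, jnk = 1,
                              pakt = 1) {
    p <- c(zak = zak, mkk4 = mkk4, mkk7 = mkk7, jnk = jnk, pakt = pakt)
    if (any(!is.finite(p)) || any(p < 0))
        stop("all relative abundances must be finite and >= 0")
    p
}

#' Construct a kinetic parameter set
#'
#' @param rates named numeric vector of the 19 kinetic constants (see
#'   [KineticParameters-class] for names and meaning).
#' @param totals named numeric vector of reference total concentrations
#'   for zak, mkk4, mkk7 and jnk.
#' @return a [KineticParameters-class] object.
#' @export
kineticParameters <- function(rates, totals) {
    new("KineticParameters", rates = rates[.RATE_NAMES],
        totals = totals[.TOTAL_NAMES])
}

## Hand-set base constants (time unit minutes before calibration; the
## nominal saturated peak time is fixed at 30 min by calibrateNominal(),
## which rescales every first-order/catalytic rate).  The cascade is the
## standard distributive two-site MAPK idiom; the feedback gain and input
## coupling were tuned so the nominal cell sits above the switching
## threshold at saturating stimulus while the weak tail of a 33-43%-CoV
## log-normal ensemble fails to switch (see the methods vignette).
.BASE_RATES <- c(
    kin  = 0.0270,  # stress-input coupling (per stress unit per min)
    kmz  = 10,      # Km of ZAK activation
    kpz  = 0.05,    # ZAK inactivation
    k4   = 0.03,    # MKK4 phosphorylation by active ZAK (per Za unit)
    km4  = 10,      # Km of MKK4 steps
    p4   = 0.05,    # MKK4 phosphatase
    k7   = 0.03,    # MKK7 phosphorylation by active ZAK
    km7  = 10,      # Km of MKK7 steps
    p7   = 0.05,    # MKK7 phosphatase
    k44  = 0.003,   # JNK phosphorylation by active MKK4 (per M4pp unit)
    k77  = 0.003,   # JNK phosphorylation by active MKK7
    kmj  = 30,      # Km of JNK steps
    pj   = 0.05,    # JNK phosphatase
    kfb  = 0.011,   # feedback marking of MKK7 by active JNK
    pfb  = 0.05,    # removal of the feedback mark
    gfb  = 40,      # catalytic gain of feedback-marked active MKK7
    ka4  = 0.01,    # Akt-driven inhibition of MKK4 (per pakt unit)
    ka7  = 0.01,    # Akt-driven inhibition of MKK7
    krec = 0.005    # recovery from the inhibited states
)

.BASE_TOTALS <- c(zak = 100, mkk4 = 100, mkk7 = 100, jnk = 100)

#' Uncalibrated base kinetic constants
#'
#' The shipped hand-set constants before the peak-time calibration applied
#' by [calibrateNominal()].  Exposed mainly so the calibration itself can
#' be inspected and re-run under different constraints.
#'
#' @return a [KineticParameters-class] object.
#' @export
baseKineticParameters <- function() {
    kineticParameters(.BASE_RATES, .BASE_TOTALS)
}

#' Build the ODE network for one cell
#'
#' Scales the reference protein totals by the cell's relative abundances
#' and binds the phospho-Akt level to the cross-talk flux.
#'
#' @param profile a named abundance vector from [expressionProfile()].
#' @param params a [KineticParameters-class] object.
#' @return a [ParameterizedNetwork-class] object.
#' @examples
#' net <- buildNetwork(expressionProfile(), defaultKineticParameters())
#' @export
buildNetwork <- function(profile, params = defaultKineticParameters()) {
    if (is.null(names(profile))) names(profile) <- .COMPONENTS
    profile <- profile[.COMPONENTS]
    if (any(is.na(profile)))
        stop("profile must provide zak, mkk4, mkk7, jnk and pakt")
    if (any(!is.finite(profile)) || any(profile < 0))
        stop("invalid profile: all relative abundances must be finite and >= 0")
    new("ParameterizedNetwork", profile = profile, params = params)
}

## parameter vector handed to the compiled RHS
.parVec <- function(network, stimulus) {
    c(unname(network@params@rates), stimulus,
      unname(network@profile["pakt"]))
}

## all-unphosphorylated state with pools scaled by the profile
.initialState <- function(network) {
    tot <- network@params@totals * network@profile[.TOTAL_NAMES]
    y <- numeric(16)
    names(y) <- .STATE_NAMES
    y["Z"] <- tot["zak"]; y["M4"] <- tot["mkk4"]
    y["M7"] <- tot["mkk7"]; y["J"] <- tot["jnk"]
    y
}

.STATE_NAMES <- c("Z", "Za", "M4", "M4p", "M4pp", "M4i",
                  "M7", "M7p", "M7pp", "M7f", "M7fp", "M7fpp", "M7i",
                  "J", "Jp", "Jpp")

## R mirror of the compiled right-hand side; backs the fixed-step oracle
## and the steady-state convergence check.
.jnkDerivsR <- function(t, y, pv) {
    kin <- pv[1]; kmz <- pv[2]; kpz <- pv[3]
    k4 <- pv[4]; km4 <- pv[5]; p4 <- pv[6]
    k7 <- pv[7]; km7 <- pv[8]; p7 <- pv[9]
    k44 <- pv[10]; k77 <- pv[11]; kmj <- pv[12]; pj <- pv[13]
    kfb <- pv[14]; pfb <- pv[15]; gfb <- pv[16]
    ka4 <- pv[17]; ka7 <- pv[18]; krec <- pv[19]
    stim <- pv[20]; pakt <- pv[21]

    Z <- y[1]; Za <- y[2]
    M4 <- y[3]; M4p <- y[4]; M4pp <- y[5]; M4i <- y[6]
    M7 <- y[7]; M7p <- y[8]; M7pp <- y[9]
    M7f <- y[10]; M7fp <- y[11]; M7fpp <- y[12]; M7i <- y[13]
    J <- y[14]; Jp <- y[15]; Jpp <- y[16]

    vz <- kin * stim * Z / (kmz + Z)
    v41 <- k4 * Za * M4 / (km4 + M4)
    v42 <- k4 * Za * M4p / (km4 + M4p)
    a4p <- ka4 * pakt * M4p
    a4pp <- ka4 * pakt * M4pp
    v71 <- k7 * Za * M7 / (km7 + M7)
    v72 <- k7 * Za * M7p / (km7 + M7p)
    v71f <- k7 * Za * M7f / (km7 + M7f)
    v72f <- k7 * Za * M7fp / (km7 + M7fp)
    a7p <- ka7 * pakt * M7p
    a7pp <- ka7 * pakt * M7pp
    a7fp <- ka7 * pakt * M7fp
    a7fpp <- ka7 * pakt * M7fpp
    f0 <- kfb * Jpp * M7; f1 <- kfb * Jpp * M7p; f2 <- kfb * Jpp * M7pp
    kcatj <- k44 * M4pp + k77 * (M7pp + gfb * M7fpp)
    w1 <- kcatj * J / (kmj + J)
    w2 <- kcatj * Jp / (kmj + Jp)

    c(-vz + kpz * Za,
      vz - kpz * Za,
      -v41 + p4 * M4p + krec * M4i,
      v41 - v42 - p4 * M4p + p4 * M4pp - a4p,
      v42 - p4 * M4pp - a4pp,
      a4p + a4pp - krec * M4i,
      -v71 + p7 * M7p - f0 + pfb * M7f + krec * M7i,
      v71 - v72 - p7 * M7p + p7 * M7pp - f1 + pfb * M7fp - a7p,
      v72 - p7 * M7pp - f2 + pfb * M7fpp - a7pp,
      -v71f + p7 * M7fp + f0 - pfb * M7f,
      v71f - v72f - p7 * M7fp + p7 * M7fpp + f1 - pfb * M7fp - a7fp,
      v72f - p7 * M7fpp + f2 - pfb * M7fpp - a7fpp,
      a7p + a7pp + a7fp + a7fpp - krec * M7i,
      -w1 + pj * Jp,
      w1 - w2 - pj * Jp + pj * Jpp,
      w2 - pj * Jpp)
}

.lsoda <- function(y, times, pv, rtol, atol) {
    out <- deSolve::lsoda(y = y, times = times, func = "jnk_derivs",
                          parms = pv, dllname = "jnknoise",
                          initfunc = "jnk_initmod",
                          rtol = rtol, atol = atol, maxsteps = 100000)
    diagn <- attributes(out)$istate
    if (!is.null(diagn) && diagn[1] < 0)
        stop(sprintf("ODE solver failed (istate = %d)", diagn[1]))
    if (nrow(out) < length(times))
        stop("ODE solver returned a truncated trajectory")
    out
}

## Pre-stimulus steady state at the basal input, by long integration until
## the maximum relative derivative drops below `tol` per minute.
.basalSteadyState <- function(network, basal, rtol = 1e-8, atol = 1e-10,
                              tol = 1e-9, chunk = 2000, maxChunks = 30) {
    pv <- .parVec(network, basal)
    y <- .initialState(network)
    scale <- max(network@params@totals * network@profile[.TOTAL_NAMES], 1)
    for (i in seq_len(maxChunks)) {
        out <- .lsoda(y, c(0, chunk), pv, rtol, atol)
        y <- out[nrow(out), -1]
        if (max(abs(.jnkDerivsR(0, y, pv))) / scale < tol)
            return(pmax(y, 0))
    }
    stop("basal steady state did not converge; integration diagnostics: ",
         sprintf("max relative derivative %.3g after %d min",
                 max(abs(.jnkDerivsR(0, y, pv))) / scale, maxChunks * chunk))
}

#' Simulate a single-cell trajectory
#'
#' Integrates the network from its pre-stimulus steady state (held at the
#' basal input) under a sustained stimulus step applied at t = 0.
#'
#' @param network a [ParameterizedNetwork-class] object.
#' @param stimulus applied stress input (arbitrary stress units; 1000
#'   saturates the nominal calibrated cell).
#' @param duration simulated time in minutes.
#' @param grid output grid spacing in minutes.
#' @param basal pre-stimulus input held before t = 0 (defaults to 1/20th
#'   of the saturating input).
#' @param keepState keep the full 16-species state matrix in the result.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return a [Trajectory-class] object.
#' @examples
#' net <- buildNetwork(expressionProfile(), defaultKineticParameters())
#' traj <- simulateCell(net, stimulus = 1000, duration = 60)
#' peakActiveJNK(traj)
#' @export
simulateCell <- function(network, stimulus, duration = 240, grid = 1,
                         basal = 50, keepState = FALSE,
                         rtol = 1e-8, atol = 1e-10) {
    if (duration <= 0) stop("duration must be > 0")
    if (stimulus < 0) stop("stimulus must be >= 0")
    y0 <- .basalSteadyState(network, basal, rtol, atol)
    times <- seq(0, duration, by = grid)
    out <- .lsoda(y0, times, .parVec(network, stimulus), rtol, atol)
    state <- out[, -1, drop = FALSE]
    colnames(state) <- .STATE_NAMES
    new("Trajectory", time = out[, 1],
        activeJNK = pmax(state[, "Jpp"], 0),
        state = if (keepState) state else matrix(numeric(0), 0, 0),
        stimulus = stimulus)
}

#' Fixed-step 4th-order reference integration
#'
#' Classic Runge-Kutta at a fixed step, computed from an independent R
#' implementation of the right-hand side.  Used as the integration oracle
#' against the adaptive compiled-model path of [simulateCell()].
#'
#' @inheritParams simulateCell
#' @param dt fixed integration step (minutes).
#' @return a [Trajectory-class] object on the same output grid as
#'   [simulateCell()].
#' @export
simulateFixedStep <- function(network, stimulus, duration = 240, grid = 1,
                              basal = 50, dt = 0.01) {
    if (duration <= 0) stop("duration must be > 0")
    y <- .basalSteadyState(network, basal)
    pv <- .parVec(network, stimulus)
    per <- round(grid / dt)
    stopifnot(abs(per * dt - grid) < 1e-9)
    nOut <- floor(duration / grid)
    times <- seq(0, duration, by = grid)
    jpp <- numeric(nOut + 1)
    jpp[1] <- y[16]
    for (i in seq_len(nOut)) {
        for (s in seq_len(per)) {
            k1 <- .jnkDerivsR(0, y, pv)
            k2 <- .jnkDerivsR(0, y + dt / 2 * k1, pv)
            k3 <- .jnkDerivsR(0, y + dt / 2 * k2, pv)
            k4 <- .jnkDerivsR(0, y + dt * k3, pv)
            y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        }
        jpp[i + 1] <- y[16]
    }
    new("Trajectory", time = times, activeJNK = pmax(jpp, 0),
        state = matrix(numeric(0), 0, 0), stimulus = stimulus)
}

#' Peak active JNK of a trajectory
#'
#' @param traj a [Trajectory-class] object (or a bare numeric series).
#' @return maximum of the active-JNK series.
#' @export
peakActiveJNK <- function(traj) {
    x <- if (is(traj, "Trajectory")) traj@activeJNK else traj
    if (length(x) == 0) stop("empty trajectory")
    max(x)
}

#' Knock out the JNK-to-MKK7 positive feedback
#'
#' Returns a copy of the parameter set with every feedback parameter
#' removed from play: the feedback marking rate is set to 0 and the
#' catalytic gain multiplier to 1 (no contribution).  All other parameters
#' are unchanged; the operation is idempotent.
#'
#' @param params a [KineticParameters-class] object.
#' @return a [KineticParameters-class] object without feedback.
#' @export
disableFeedback <- function(params) {
    r <- params@rates
    r["kfb"] <- 0
    r["gfb"] <- 1
    kineticParameters(r, params@totals)
}

#' Is the positive feedback active?
#'
#' @param params a [KineticParameters-class] object.
#' @return logical.
#' @export
feedbackEnabled <- function(params) {
    unname(params@rates["kfb"] > 0 & params@rates["gfb"] != 1)
}

#' Calibrate the nominal cell
#'
#' Rescales the base kinetic constants so the nominal (all-ones) cell
#' satisfies the calibration constraints: the saturated response
#' (default 1000 stress units) peaks at `peakTime` minutes (default 30,
#' the peak time of anisomycin-induced JNK activity), the basal input is
#' `basalFraction` of the saturating input (default 1/20), and the
#' peak-versus-stimulus dose response with feedback enabled has an
#' effective Hill coefficient of at least `minHill` (default 2, encoding
#' the cascade's ultrasensitivity).  Because the constraint is a pure time
#' rescaling, every first-order and catalytic rate is multiplied by one
#' common factor; Michaelis constants, the gain and the totals are
#' untouched, so peak amplitudes and ensemble statistics are invariant.
#'
#' @param peakTime target peak time of the nominal saturated response
#'   (minutes).
#' @param satStimulus saturating input (arbitrary stress units).
#' @param basalFraction basal input as a fraction of `satStimulus`.
#' @param minHill minimum effective Hill coefficient (feedback on).
#' @param base starting [KineticParameters-class] set.
#' @return a calibrated [KineticParameters-class] object.  Deterministic
#'   given the same constraints.
#' @examples
#' \donttest{
#' p <- calibrateNominal()
#' }
#' @export
calibrateNominal <- function(peakTime = 30, satStimulus = 1000,
                             basalFraction = 1 / 20, minHill = 2,
                             base = baseKineticParameters()) {
    basal <- satStimulus * basalFraction
    net <- buildNetwork(expressionProfile(), base)
    traj <- simulateCell(net, satStimulus, duration = 600, grid = 0.25,
                         basal = basal)
    tp <- traj@time[which.max(traj@activeJNK)]
    if (tp <= 0 || tp >= 600)
        stop("infeasible constraints: nominal response has no interior peak")
    fac <- tp / peakTime
    timeRates <- setdiff(.RATE_NAMES, c("kmz", "km4", "km7", "kmj", "gfb"))
    r <- base@rates
    r[timeRates] <- r[timeRates] * fac
    out <- kineticParameters(r, base@totals)
    dr <- doseResponse(buildNetwork(expressionProfile(), out),
                       stimuli = exp(seq(log(basal), log(satStimulus),
                                         length.out = 12)),
                       duration = 8 * peakTime, grid = peakTime / 20,
                       basal = basal)
    if (!is.finite(dr$hill) || dr$hill < minHill)
        stop(sprintf(paste("infeasible constraints: effective Hill",
                           "coefficient %.2f below required %.2f"),
                     dr$hill, minHill))
    out
}

.pkgCache <- new.env(parent = emptyenv())

#' Shipped calibrated kinetic parameters
#'
#' The default parameter set used throughout: [baseKineticParameters()]
#' passed through [calibrateNominal()] with default constraints.  The
#' result is memoized for the session.
#'
#' @return a [KineticParameters-class] object.
#' @export
defaultKineticParameters <- function() {
    if (is.null(.pkgCache$defaultParams))
        .pkgCache$defaultParams <- calibrateNominal()
    .pkgCache$defaultParams
}

#' Peak-activity dose response and effective Hill coefficient
#'
#' Simulates the peak active JNK at each stimulus and estimates the
#' effective Hill coefficient from the log-stimulus slope at the
#' half-maximal response: for y = ymin + A s^n / (K^n + s^n) the slope
#' dy/dln(s) at half maximum equals nA/4, so n = (4/A) dy/dln(s).
#'
#' With the shipped calibrated parameters the full model's dose response
#' contains a near-discontinuous ignition of the positive feedback; the
#' half-maximum then lies on the graded post-ignition branch, so the
#' switch-like steepness shows up in `hillMax` (the maximum local
#' log-slope expressed on the same scale) rather than in `hill`.
#'
#' @param network a [ParameterizedNetwork-class] object.
#' @param stimuli at least 4 non-negative stimuli spanning basal to
#'   saturated.
#' @param duration,grid,basal passed to [simulateCell()].
#' @return list with `stimuli`, `peaks`, `hill` (NA when the curve is
#'   flat), `hillMax` (maximum local log-slope, same normalization), and
#'   `reliable` (FALSE when the curve is non-monotone or flat).
#' @export
doseResponse <- function(network, stimuli, duration = 240, grid = 1,
                         basal = min(stimuli)) {
    if (length(stimuli) < 4) stop("need at least 4 stimuli")
    if (any(stimuli < 0)) stop("stimuli must be >= 0")
    o <- order(stimuli)
    stimuli <- stimuli[o]
    peaks <- vapply(stimuli, function(s)
        peakActiveJNK(simulateCell(network, s, duration = duration,
                                   grid = grid, basal = basal)),
        numeric(1))
    h <- .hillEstimate(stimuli, peaks)
    list(stimuli = stimuli, peaks = peaks, hill = h$hill,
         hillMax = h$hillMax, reliable = h$reliable)
}

.hillEstimate <- function(stimuli, peaks) {
    A <- max(peaks) - min(peaks)
    if (A <= 1e-9 * max(abs(peaks), 1))
        return(list(hill = NA_real_, hillMax = NA_real_, reliable = FALSE))
    monotone <- all(diff(peaks) >= -1e-6 * A)
    slopes <- diff(peaks) / diff(log(stimuli))
    hillMax <- 4 * max(slopes) / A
    ymid <- min(peaks) + A / 2
    i <- which(peaks[-length(peaks)] <= ymid & peaks[-1] >= ymid)
    if (length(i) == 0)
        return(list(hill = NA_real_, hillMax = hillMax, reliable = FALSE))
    i <- i[1]
    list(hill = 4 * slopes[i] / A, hillMax = hillMax,
         reliable = monotone)
}

## stable hash of a parameter set (md5 of its full-precision serialization)
.paramHash <- function(params) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(c(sprintf("%s=%.17g", names(params@rates), params@rates),
                 sprintf("%s=%.17g", names(params@totals), params@totals)),
               f)
    unname(tools::md5sum(f))
}

#' Write or read a parameter set as flat JSON
#'
#' Serialized as a flat key-to-value document with a `schema_version`
#' field; totals are prefixed `total_`.
#'
#' @param params a [KineticParameters-class] object.
#' @param path file path.
#' @return `readKineticParameters` returns a
#'   [KineticParameters-class] object.
#' @export
writeKineticParameters <- function(params, path) {
    doc <- c(list(schema_version = 1L),
             as.list(params@rates),
             as.list(stats::setNames(params@totals,
                                     paste0("total_", names(params@totals)))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeKineticParameters
#' @export
readKineticParameters <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(doc$schema_version) || doc$schema_version != 1L)
        stop("unsupported parameter-file schema version")
    rates <- unlist(doc[.RATE_NAMES])
    totals <- unlist(doc[paste0("total_", .TOTAL_NAMES)])
    names(totals) <- .TOTAL_NAMES
    kineticParameters(rates, totals)
}
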