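#' Construct a track set
#'
#' @param data long-format data.frame (`cell_id`, `time_min`, `ktr_ratio`,
#'   `reporter_mfi`, `caspase_mfi`), one row per cell per sample time.
#' @param filterLog optional pre-existing exclusion log.
#' @return a [TrackSet-class] object.
#' @export
trackSet <- function(data,
                     filterLog = data.frame(cell_id = character(),
                                            reason = character())) {
    data$cell_id <- as.character(data$cell_id)
    new("TrackSet", data = data, filterLog = filterLog)
}

.dropTracks <- function(ts, drop, reason) {
    if (length(drop) == 0) return(ts)
    log <- rbind(ts@filterLog,
                 data.frame(cell_id = drop, reason = reason))
    trackSet(ts@data[!ts@data$cell_id %in% drop, , drop = FALSE],
             filterLog = log)
}

#' Exclude tracks by biosensor expression level
#'
#' Removes cells expressing very low or very high levels of the reporter:
#' a track is excluded when its mean reporter MFI is strictly below `low`
#' (default 10) or strictly above `high` (default 200); boundary values
#' are retained.  Exclusions are appended to the filter log with reasons
#' `mfi_low` / `mfi_high`.  Idempotent.
#'
#' @param tracks a [TrackSet-class] object.
#' @param low,high MFI bounds.
#' @return the filtered [TrackSet-class].
#' @export
filterExpressionBounds <- function(tracks, low = 10, high = 200) {
    m <- tapply(tracks@data$reporter_mfi, tracks@data$cell_id, mean)
    ts <- .dropTracks(tracks, names(m)[m < low], "mfi_low")
    .dropTracks(ts, names(m)[m > high], "mfi_high")
}

#' Exclude tracks by tracking coverage
#'
#' `full_period` keeps only cells tracked continuously over the entire
#' imaging period (the union time range of the set, no internal gaps);
#' `min_minutes` keeps cells continuously imaged for at least the first
#' `minMinutes` minutes (default 480, i.e. the first 8 hours).
#'
#' @param tracks a [TrackSet-class] object.
#' @param mode "full_period" or "min_minutes".
#' @param minMinutes required contiguous coverage from the experiment
#'   start (minutes), used by mode "min_minutes".
#' @return the filtered [TrackSet-class].
#' @export
filterTrackingCoverage <- function(tracks,
                                   mode = c("min_minutes", "full_period"),
                                   minMinutes = 480) {
    mode <- match.arg(mode)
    d <- tracks@data
    if (nrow(d) == 0) return(tracks)
    t0 <- min(d$time_min); t1 <- max(d$time_min)
    byCell <- split(d$time_min, d$cell_id)
    ## a gap is a sampling-interval jump larger than 1.5x the track's own
    ## (constant) interval
    contigUntil <- function(tt) {
        if (length(tt) == 1) return(tt[1])
        dt <- stats::median(diff(tt))
        gaps <- which(diff(tt) > 1.5 * dt)
        if (length(gaps)) tt[gaps[1]] else tt[length(tt)]
    }
    keep <- vapply(byCell, function(tt) {
        if (mode == "full_period")
            tt[1] <= t0 && contigUntil(tt) >= t1
        else
            tt[1] <= t0 && contigUntil(tt) >= t0 + minMinutes
    }, logical(1))
    .dropTracks(tracks, names(byCell)[!keep],
                if (mode == "full_period") "not_full_period"
                else sprintf("coverage_lt_%gmin", minMinutes))
}

#' Detect caspase activation onset in one track
#'
#' The earliest sample time at which the caspase-reporter intensity
#' strictly exceeds the threshold (default 50 MFI); a series that never
#' exceeds the threshold (including one sitting exactly at it) yields no
#' onset.
#'
#' @param track data.frame with `time_min` and `caspase_mfi` columns.
#' @param threshold positive caspase activation cutoff (MFI).
#' @return onset time in minutes, or `NA_real_` when never exceeded.
#' @export
detectCaspaseOnset <- function(track, threshold = 50) {
    i <- which(track$caspase_mfi > threshold)
    if (length(i) == 0) NA_real_ else track$time_min[min(i)]
}

#' Detect caspase onsets for every track in a set
#'
#' @param tracks a [TrackSet-class] object.
#' @param threshold positive caspase activation cutoff (MFI).
#' @return data.frame (`cell_id`, `onset`); `onset` is NA for cells with
#'   no activation event.
#' @export
detectCaspaseOnsets <- function(tracks, threshold = 50) {
    d <- tracks@data
    sp <- split(d[c("time_min", "caspase_mfi")], d$cell_id)
    data.frame(cell_id = names(sp),
               onset = vapply(sp, detectCaspaseOnset, numeric(1),
                              threshold = threshold),
               row.names = NULL)
}

#' Peak activity of one track within a time window
#'
#' Maximum KTR ratio within the window (default the first 4 hours, the
#' early phase of drug-induced JNK activity), optionally converted to
#' active-kinase concentration via the reporter model.
#'
#' @param track data.frame with `time_min` and `ktr_ratio` columns.
#' @param window length-2 interval in minutes; must lie within the
#'   track's coverage.
#' @param rp optional [ReporterParameters-class]; when given, the peak
#'   ratio is converted with [ratioToActivity()] and the capped activity
#'   is returned.
#' @param smooth "none" takes the raw in-window maximum; "median3"
#'   applies a 3-point running median to the ratio series first, the
#'   usual high-content denoising step that stops single-frame noise
#'   spikes from inflating the peak of otherwise flat traces.
#' @return peak ratio (or converted activity).
#' @export
peakWindowActivity <- function(track, window = c(0, 240), rp = NULL,
                               smooth = c("none", "median3")) {
    smooth <- match.arg(smooth)
    if (window[1] < min(track$time_min) - 1e-9 ||
        window[2] > max(track$time_min) + 1e-9)
        stop("window outside track coverage")
    y <- track$ktr_ratio
    if (smooth == "median3" && length(y) >= 3)
        y <- stats::runmed(y, 3, endrule = "keep")
    sel <- track$time_min >= window[1] & track$time_min <= window[2]
    pk <- max(y[sel])
    if (is.null(rp)) pk else ratioToActivity(pk, rp)$activity
}

#' Peak window activity for every track in a set
#'
#' @param tracks a [TrackSet-class] object.
#' @inheritParams peakWindowActivity
#' @return data.frame (`cell_id`, `peak`).
#' @export
peakWindowActivities <- function(tracks, window = c(0, 240), rp = NULL,
                                 smooth = c("none", "median3")) {
    smooth <- match.arg(smooth)
    d <- tracks@data
    sp <- split(d[c("time_min", "ktr_ratio")], d$cell_id)
    data.frame(cell_id = names(sp),
               peak = vapply(sp, peakWindowActivity, numeric(1),
                             window = window, rp = rp, smooth = smooth),
               row.names = NULL)
}

#' Group peak activities by apoptotic outcome
#'
#' Splits per-cell peak activities by caspase-onset status (apoptotic =
#' onset called) and reports Cohen's d between the groups plus the
#' fraction of apoptotic peaks strictly above the nonapoptotic mean.
#' When either group is empty (or too small for a pooled SD) the
#' statistics are flagged undefined rather than raising an error.
#'
#' @param peaks data.frame (`cell_id`, `peak`).
#' @param onsets data.frame (`cell_id`, `onset`), onset NA for
#'   nonapoptotic cells; aligned to `peaks` by `cell_id`.
#' @return an [OutcomeGroups-class] object.
#' @export
groupByOutcome <- function(peaks, onsets) {
    m <- merge(peaks, onsets, by = "cell_id")
    if (nrow(m) != nrow(peaks))
        stop("peaks and onsets must cover the same cells")
    apo <- m$peak[!is.na(m$onset)]
    non <- m$peak[is.na(m$onset)]
    defined <- length(apo) >= 2 && length(non) >= 2
    d <- if (defined) tryCatch(cohensD(apo, non), error = function(e)
        NA_real_) else NA_real_
    new("OutcomeGroups", apoptotic = apo, nonapoptotic = non,
        cohensD = d,
        fractionAbove = if (length(apo) && length(non))
            mean(apo > mean(non)) else NA_real_,
        defined = defined && is.finite(d))
}

#' Binned apoptosis probability along peak activity
#'
#' Bins per-cell peak activities and reports the apoptotic fraction per
#' bin, plus the interpolated peak value at which the fraction first
#' crosses 0.5 (the commitment midpoint).  The analysis makes no
#' assumption about the functional form of the commitment relationship.
#'
#' The midpoint is read off a weighted isotonic (pool-adjacent-violators)
#' regularization of the binned fractions: commitment probability is
#' assumed monotone non-decreasing in peak activity -- nothing stronger --
#' which suppresses the crossing jitter of sparsely populated bins.  The
#' raw per-bin fractions are returned unregularized.
#'
#' @param peaks numeric per-cell peak activities.
#' @param outcomes logical per-cell apoptotic outcomes.
#' @param bins number of equal-width bins over the peak range; at least 2
#'   bins must be populated.
#' @return list with `bins` (data.frame `mid`, `n`, `fraction`,
#'   `fraction_monotone`), `midpoint` (NA when undefined) and `defined`.
#' @export
commitmentCurve <- function(peaks, outcomes, bins = 10) {
    stopifnot(length(peaks) == length(outcomes))
    br <- seq(min(peaks), max(peaks), length.out = bins + 1)
    idx <- findInterval(peaks, br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    mid <- (br[-1] + br[-length(br)]) / 2
    n <- tabulate(idx, nbins = bins)
    frac <- vapply(seq_len(bins), function(b)
        if (n[b] > 0) mean(outcomes[idx == b]) else NA_real_, numeric(1))
    if (sum(n > 0) < 2)
        stop("need at least 2 populated bins")
    ok <- which(n > 0)
    iso <- .pava(frac[ok], n[ok])
    fracMono <- rep(NA_real_, bins)
    fracMono[ok] <- iso
    out <- list(bins = data.frame(mid = mid, n = n, fraction = frac,
                                  fraction_monotone = fracMono))
    if (all(outcomes) || !any(outcomes))
        return(c(out, list(midpoint = NA_real_, defined = FALSE)))
    ## first upward crossing of 0.5 of the monotone curve
    f <- iso; x <- mid[ok]
    midpoint <- NA_real_
    for (j in seq_len(length(ok) - 1)) {
        if (f[j] < 0.5 && f[j + 1] >= 0.5) {
            midpoint <- x[j] + (0.5 - f[j]) / (f[j + 1] - f[j]) *
                (x[j + 1] - x[j])
            break
        }
    }
    if (is.na(midpoint) && f[1] >= 0.5) midpoint <- x[1]
    c(out, list(midpoint = midpoint, defined = is.finite(midpoint)))
}

## weighted pool-adjacent-violators: monotone non-decreasing fit
.pava <- function(y, w) {
    n <- length(y)
    val <- y; wt <- w; size <- rep(1L, n)
    m <- 0L
    for (i in seq_len(n)) {
        m <- m + 1L
        val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
        while (m > 1L && val[m - 1L] > val[m]) {
            val[m - 1L] <- (wt[m - 1L] * val[m - 1L] + wt[m] * val[m]) /
                (wt[m - 1L] + wt[m])
            wt[m - 1L] <- wt[m - 1L] + wt[m]
            size[m - 1L] <- size[m - 1L] + size[m]
            m <- m - 1L
        }
    }
    rep(val[seq_len(m)], times = size[seq_len(m)])
}

## maximal-R^2 contiguous window of >= minPoints samples starting at or
## after the first nonzero fraction
.selectLinearWindow <- function(time, frac, minPoints = 4) {
    start <- which(frac > 0)[1]
    if (is.na(start)) start <- 1
    idx <- start:length(time)
    if (length(idx) < minPoints)
        stop("fewer than the minimum window points after caspase initiation")
    best <- NULL; bestR2 <- -Inf
    for (a in seq_len(length(idx) - minPoints + 1)) {
        for (b in (a + minPoints - 1):length(idx)) {
            w <- idx[a:b]
            if (stats::var(frac[w]) == 0) next
            ## exactly linear sub-curves are expected here
            r2 <- suppressWarnings(
                summary(stats::lm(frac[w] ~ time[w]))$r.squared)
            if (r2 > bestR2 + 1e-12) { bestR2 <- r2; best <- w }
        }
    }
    if (is.null(best)) idx else best
}

#' Compare cumulative caspase-onset curves across conditions
#'
#' For each condition's cumulative caspase-activation fraction curve, fits
#' an ordinary least-squares line within the linear portion immediately
#' following the initiation of caspase activity (selected automatically as
#' the maximal-R^2 contiguous window of at least `minPoints` samples
#' starting at or after the first nonzero fraction), then performs
#' pairwise slope-difference tests (Welch-type t on the slope standard
#' errors).
#'
#' @param curves named list of data.frames (`time`, `fraction`), each a
#'   monotone non-decreasing cumulative fraction curve.
#' @param minPoints minimum window size in samples (>= 3 required, 4 by
#'   default).
#' @return list with `slopes` (data.frame `condition`, `slope`, `se`,
#'   `ci_lo`, `ci_hi`, `window_start`, `window_end`) and `pairwise`
#'   (data.frame `a`, `b`, `difference`, `ratio`, `p`).
#' @export
onsetCurveRegression <- function(curves, minPoints = 4) {
    if (length(curves) < 2) stop("need at least 2 conditions")
    if (minPoints < 3) stop("window must contain at least 3 points")
    if (is.null(names(curves)))
        names(curves) <- paste0("condition_", seq_along(curves))
    fits <- lapply(names(curves), function(nm) {
        cv <- curves[[nm]]
        if (any(diff(cv$fraction) < -1e-9))
            stop(sprintf("curve '%s' is not a cumulative fraction", nm))
        w <- .selectLinearWindow(cv$time, cv$fraction, minPoints)
        fit <- stats::lm(fraction ~ time, data = cv[w, ])
        sm <- suppressWarnings(summary(fit)$coefficients)
        ci <- suppressWarnings(stats::confint(fit)["time", ])
        list(condition = nm, slope = sm["time", "Estimate"],
             se = sm["time", "Std. Error"], ci_lo = ci[1], ci_hi = ci[2],
             df = fit$df.residual,
             window_start = cv$time[w[1]],
             window_end = cv$time[w[length(w)]])
    })
    slopes <- do.call(rbind, lapply(fits, function(f)
        data.frame(f[c("condition", "slope", "se", "ci_lo", "ci_hi",
                       "window_start", "window_end")])))
    pairs <- utils::combn(seq_along(fits), 2)
    pw <- apply(pairs, 2, function(ij) {
        f1 <- fits[[ij[1]]]; f2 <- fits[[ij[2]]]
        diff <- f1$slope - f2$slope
        se <- sqrt(f1$se^2 + f2$se^2)
        if (se == 0) {
            p <- if (abs(diff) < 1e-12) 1 else 0
        } else {
            df <- (f1$se^2 + f2$se^2)^2 /
                (f1$se^4 / f1$df + f2$se^4 / f2$df)
            p <- 2 * stats::pt(-abs(diff / se), df)
        }
        data.frame(a = f1$condition, b = f2$condition, difference = diff,
                   ratio = f1$slope / f2$slope, p = p)
    })
    list(slopes = slopes, pairwise = do.call(rbind, pw))
}
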