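#' Coefficient of variation
#'
#' The single-cell noise metric: 100 x sample SD / mean, in percent.
#'
#' @param values non-empty numeric vector with nonzero mean.
#' @return CoV in percent.
#' @examples
#' coefficientOfVariation(c(0.5, 1.5))  # 70.71
#' @export
coefficientOfVariation <- function(values) {
    if (length(values) == 0) stop("empty input")
    m <- mean(values)
    if (m == 0) stop("mean is zero; CoV undefined")
    100 * stats::sd(values) / m
}

#' Cohen's d effect size
#'
#' Absolute difference between the two sample means divided by the pooled
#' SD (group-size-weighted variances).
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return non-negative d.
#' @examples
#' cohensD(c(1, 2, 3), c(3, 4, 5))  # 2
#' @export
cohensD <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values")
    pooled <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                   (n1 + n2 - 2))
    if (pooled == 0) stop("pooled SD is zero; d undefined")
    abs(mean(a) - mean(b)) / pooled
}

#' Effect-size class of a Cohen's d value
#'
#' The reporting convention used for large single-cell samples:
#' d < 0.2 is inconsequential (even if statistically significant),
#' 0.2 <= d <= 0.5 is a small/modest effect, d > 0.5 a large effect.
#' (The textbook anchors additionally label d = 0.8 a large effect; the
#' 0.2/0.5 boundaries here follow the reporting/coloring convention.)
#'
#' @param d non-negative effect size.
#' @return one of "inconsequential", "small", "large".
#' @examples
#' effectSizeClass(c(0.1, 0.35, 0.9))
#' @export
effectSizeClass <- function(d) {
    if (any(!is.finite(d)) || any(d < 0)) stop("d must be finite and >= 0")
    ifelse(d < 0.2, "inconsequential", ifelse(d <= 0.5, "small", "large"))
}

#' Effect-size-gated two-sample comparison
#'
#' The combined testing approach for large single-cell samples: the
#' p-value of the chosen two-sample test together with Cohen's d and its
#' class.  The gating flag is set when both groups exceed 1000 samples;
#' under gating a statistically significant p with d < 0.2 is still
#' reported as inconsequential.
#'
#' @param a,b numeric samples.
#' @param test "welch" (Welch's t, default) or "student".
#' @return one-row data.frame (`n1`, `n2`, `p`, `d`, `class`, `gated`).
#' @export
gatedComparison <- function(a, b, test = c("welch", "student")) {
    test <- match.arg(test)
    d <- cohensD(a, b)
    p <- stats::t.test(a, b, var.equal = (test == "student"))$p.value
    data.frame(n1 = length(a), n2 = length(b), p = p, d = d,
               class = effectSizeClass(d),
               gated = min(length(a), length(b)) > 1000)
}

#' Cumulative-distribution discrepancy Z score
#'
#' Compares a set of simulated replicate samples to observed replicate
#' samples on the unit scale: the discrepancy D is the mean absolute
#' difference between the pooled simulated and pooled observed empirical
#' CDFs on a fixed quantile grid, and it is standardized against the
#' leave-one-out replicate-vs-rest discrepancies among the observed
#' replicates: Z = (D - mean(Drep)) / SD(Drep).  Lower Z means closer
#' agreement with the observations relative to replicate variability.
#'
#' @param simReplicates list of numeric samples (values in `[0, 1]`).
#' @param obsReplicates list of at least 2 numeric samples (values in
#'   `[0, 1]`) used to estimate replicate variability.
#' @param gridN number of grid points on `[0, 1]`.
#' @return list with `z`, `d`, `dRep` (leave-one-out discrepancies).
#' @export
cdfDiscrepancyZ <- function(simReplicates, obsReplicates, gridN = 101) {
    if (!is.list(simReplicates)) simReplicates <- list(simReplicates)
    if (!is.list(obsReplicates) || length(obsReplicates) < 2)
        stop("need at least 2 observation replicates")
    all <- c(simReplicates, obsReplicates)
    rng <- range(unlist(all))
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        stop("all samples must be normalized to [0, 1]")
    grid <- seq(0, 1, length.out = gridN)
    D <- function(x, y)
        mean(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
    d <- D(unlist(simReplicates), unlist(obsReplicates))
    dRep <- vapply(seq_along(obsReplicates), function(i)
        D(obsReplicates[[i]], unlist(obsReplicates[-i])), numeric(1))
    list(z = (d - mean(dRep)) / stats::sd(dRep), d = d, dRep = dRep)
}

#' Ordinary least-squares fit with R-squared and 95% CI
#'
#' @param x,y numeric samples of equal length n >= 3; `x` must vary.
#' @return list with `r2`, `slope`, `intercept`, `ci` (2x2 matrix of 95%
#'   confidence bounds for intercept and slope), and the `lm` fit.
#' @examples
#' linearR2(c(1, 2, 3), c(1, 2, 4))$r2  # 0.9643
#' @export
linearR2 <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3) stop("need at least 3 points")
    if (stats::var(x) == 0) stop("x is constant; regression undefined")
    fit <- stats::lm(y ~ x)
    ## a constant response explains nothing: define R^2 = 0 rather than 0/0;
    ## exact fits (R^2 = 1) are legitimate inputs, so the perfect-fit
    ## warning from summary.lm is silenced
    r2 <- if (stats::var(y) == 0) 0 else
        suppressWarnings(summary(fit)$r.squared)
    list(r2 = r2,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         ci = suppressWarnings(stats::confint(fit)),
         fit = fit)
}
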