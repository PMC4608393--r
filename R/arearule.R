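## The "Area Rule": in the integrate-and-threshold regime a cell activates
## iff the stimulus integral A = dose x duration exceeds the cell's
## critical area A*, and A* is inversely proportional to the cell's
## receptor count. Lognormal receptor noise therefore induces a lognormal
## critical-area distribution, and the population activation curve is its
## CDF evaluated at the delivered area. The reduction is validated against
## full ODE population simulation, not asserted.

#' Analytic integrate-and-threshold population model
#'
#' Builds the lognormal critical-area model from an extrinsic-noise
#' configuration: the median critical area is found by bisection on the
#' median cell's ODE activation as a function of pulse area, and the
#' log-sd is inherited from the receptor distribution via the monotone map
#' `A*(R) = A*_median / R`.
#'
#' @param params an `nfkbParameters` list.
#' @param config a `populationConfig` (supplies `sigma_tlr4`, `mu_tlr4`).
#' @param refDose reference dose (ng/ml) for the bisection pulses; the
#'   bisection varies duration at this dose.
#' @param threshold classifier settings (defaults to the ligand's
#'   calibrated classifier).
#' @param interval search interval for the critical area (ng s/ml).
#' @param tol relative bisection tolerance.
#' @return list of class `areaResponseModel`: `meanlog`, `sdlog` of the
#'   critical-area distribution, `critical_area_median`, and the inputs.
#' @export
areaResponseModel <- function(params, config, refDose = 500,
                              threshold = NULL,
                              interval = c(50, 5e5), tol = 0.01) {
    ligand <- params$ligand_variant
    if (is.null(threshold)) threshold <- thresholdDefaults(ligand)
    medCell <- cellParameters(exp(config$mu_tlr4), exp(config$mu_nfkb),
                              "median_cell")
    init <- equilibrateCell(params, medCell)
    activeAt <- function(area) {
        prof <- makePulse(refDose, area / refDose, "sealed", ligand)
        sig <- simulateCell(params, medCell, prof,
                            tGrid = seq(0, 240, by = 1), init = init)
        classifyActivation(sig, threshold$theta)
    }
    lo <- interval[1]; hi <- interval[2]
    if (activeAt(lo)) stop("lower interval bound already activates")
    if (!activeAt(hi)) stop("upper interval bound does not activate")
    while (hi / lo > 1 + tol) {
        mid <- sqrt(lo * hi)
        if (activeAt(mid)) hi <- mid else lo <- mid
    }
    aStar <- sqrt(lo * hi)
    structure(list(
        meanlog = log(aStar),
        sdlog = config$sigma_tlr4,
        critical_area_median = aStar,
        ref_dose = refDose,
        ligand = ligand
    ), class = "areaResponseModel")
}

#' Predicted fraction of activating cells at a given stimulus area
#'
#' The cumulative form of the critical-area distribution:
#' `P(A* <= area) = plnorm(area, meanlog, sdlog)`.
#'
#' @param area stimulus area(s) in ng s/ml (>= 0); vectorized.
#' @param model an `areaResponseModel`.
#' @return fraction(s) in `[0, 1]`, non-decreasing in area, 0 at area 0.
#' @export
analyticFraction <- function(area, model) {
    if (any(area < 0)) stop("area must be >= 0")
    plnorm(area, meanlog = model$meanlog, sdlog = model$sdlog)
}

#' @export
print.areaResponseModel <- function(x, ...) {
    cat(sprintf(
        "areaResponseModel (%s): median critical area %.4g ng s/ml, log-sd %.3f\n",
        x$ligand, x$critical_area_median, x$sdlog))
    invisible(x)
}

#' Area-collapse score across dose series
#'
#' Quantifies how tightly fraction-active curves from different dose series
#' collapse onto a single curve when plotted against stimulus area.
#' Conditions are binned by area (log-spaced, 8 bins per decade by
#' default); the score is the maximum within-bin spread of fraction active
#' across series. Residuals against a single Hill-vs-area fit are also
#' returned.
#'
#' @param summary data.frame with columns `dose_ng_ml` (series id),
#'   `area_ng_s_ml`, `fraction_active` (e.g. from [screenSummary()]), or a
#'   list of `conditionResult`.
#' @param binsPerDecade log-spaced bins per decade of area.
#' @return list: `score` (max within-bin spread), `bins` (per-bin
#'   data.frame), `hill_fit` (Hill-vs-area fit, or `NULL` if degenerate),
#'   `hill_residuals`.
#' @export
collapseScore <- function(summary, binsPerDecade = 8) {
    if (!is.data.frame(summary)) summary <- screenSummary(summary)
    if (length(unique(summary$dose_ng_ml)) < 2)
        stop("need >= 2 dose series")
    a <- summary$area_ng_s_ml
    if (any(a <= 0)) stop("areas must be > 0")
    brk <- exp(seq(log(min(a)) - 1e-9, log(max(a)) + 1e-9,
                   by = log(10) / binsPerDecade))
    if (max(brk) < max(a)) brk <- c(brk, max(a) * (1 + 1e-9))
    bin <- cut(a, breaks = brk, include.lowest = TRUE, labels = FALSE)
    spread <- tapply(summary$fraction_active, bin, function(v)
        if (length(v) >= 2) diff(range(v)) else NA_real_)
    bins <- data.frame(
        bin = as.integer(names(spread)),
        n = as.integer(tapply(summary$fraction_active, bin, length)),
        area_mid = as.numeric(tapply(a, bin, function(v)
            exp(mean(log(v))))),
        spread = as.numeric(spread))
    usable <- bins$n >= 2
    if (!any(usable)) stop("no area bin holds conditions from >= 2 series")
    hf <- tryCatch(fitHill(a, summary$fraction_active),
                   error = function(e) NULL)
    list(score = max(bins$spread[usable]),
         bins = bins,
         hill_fit = hf,
         hill_residuals = if (!is.null(hf)) as.numeric(resid(hf$fit))
                          else NULL)
}

#' Minimal duration reaching a target activation fraction
#'
#' Scans an ascending duration grid at a fixed dose and returns the first
#' grid duration whose estimated fraction of activating cells reaches the
#' target, or `NA` when the dose's plateau stays below the target (doses
#' whose ceiling cannot reach the threshold have no minimal duration).
#'
#' @param dose dose in ng/ml.
#' @param targetFraction target fraction in `[0, 1]`.
#' @param durationGrid ascending durations in seconds.
#' @param params,config model and population configuration; alternatively
#'   pass `fractions` directly.
#' @param fractions optional precomputed fractions matching `durationGrid`
#'   (skips simulation).
#' @param ... passed to [runScreen()] (e.g. `sharedCells`, `ligand`).
#' @return duration in seconds, or `NA_real_`.
#' @export
minimalDuration <- function(dose, targetFraction, durationGrid,
                            params = NULL, config = NULL,
                            fractions = NULL, ...) {
    if (is.unsorted(durationGrid))
        stop("durationGrid must be ascending")
    if (is.null(fractions)) {
        res <- runScreen(params, dose, durationGrid, config, ...)
        fractions <- attr(res, "summary")$fraction_active[
            order(attr(res, "summary")$duration_s)]
    }
    hit <- which(fractions >= targetFraction)
    if (!length(hit)) NA_real_ else durationGrid[hit[1]]
}

#' Square-wave / constant-input equivalence screen
#'
#' For each total duration that is a multiple of the square-wave period,
#' simulates a start-high square wave, a start-low square wave, and a
#' constant pulse of equal area over the same shared population, and
#' reports the pairwise discrepancies in fraction active. Under the Area
#' Rule all three agree at period multiples (the two opposing waves have
#' equal area there).
#'
#' @param params an `nfkbParameters` list.
#' @param dose high-level dose (ng/ml).
#' @param period square-wave period (seconds).
#' @param totalDurations total wave durations (seconds); multiples of
#'   `period` are required.
#' @param config a `populationConfig`.
#' @param chamberMode chamber mode for all inputs.
#' @return data.frame per duration: fractions for start-high, start-low,
#'   constant equal-area pulse, pairwise absolute discrepancies, and the
#'   binomial SE; attribute `"max_discrepancy"`.
#' @export
squareWaveEquivalence <- function(params, dose, period, totalDurations,
                                  config, chamberMode = "sealed") {
    if (any(abs(totalDurations / period -
                round(totalDurations / period)) > 1e-9))
        stop("totalDurations must be multiples of the period")
    ligand <- params$ligand_variant
    cells <- samplePopulation(config)
    eq <- equilibratePopulation(params, cells)
    frac <- function(profile) {
        simulateCondition(params, cells, profile,
                          equilibria = eq)$fraction_active
    }
    rows <- lapply(totalDurations, function(dur) {
        hi <- makeSquareWave(dose, period, "start_high", dur,
                             chamberMode = chamberMode, ligand = ligand)
        lo <- makeSquareWave(dose, period, "start_low", dur,
                             chamberMode = chamberMode, ligand = ligand)
        area <- stimulusArea(hi)
        ## constant pulse of equal area at the same dose: duration = area/dose
        const <- makePulse(dose, area / dose, chamberMode, ligand)
        f <- c(high = frac(hi), low = frac(lo), const = frac(const))
        data.frame(total_duration_s = dur, area_ng_s_ml = area,
                   fraction_start_high = f["high"],
                   fraction_start_low = f["low"],
                   fraction_constant = f["const"],
                   d_high_low = abs(f["high"] - f["low"]),
                   d_high_const = abs(f["high"] - f["const"]),
                   d_low_const = abs(f["low"] - f["const"]),
                   se = sqrt(mean(f) * (1 - mean(f)) / config$n_cells),
                   row.names = NULL)
    })
    out <- do.call(rbind, rows)
    attr(out, "max_discrepancy") <-
        max(out$d_high_low, out$d_high_const, out$d_low_const)
    out
}
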