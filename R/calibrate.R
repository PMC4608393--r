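## Calibration of noise / threshold parameters against printed summary
## numbers. The experimental literature reports outcomes (fractions, Hill
## slopes, timings), not the tuning procedure; calibration here is
## weighted least squares
## over a small set of free parameters, with a direct bisection path for
## the common single-target threshold case. The shipped default parameter
## files are the committed output of inst/scripts/calibrate_defaults.R.

#' Bisection calibration of the activation threshold
#'
#' Finds the classifier threshold `theta` at which a fixed simulated
#' population reproduces a target fraction active under one condition.
#' Because raising `theta` never increases the fraction active, the
#' fraction is monotone non-increasing in `theta` and bisection applies.
#'
#' @param params an `nfkbParameters` list.
#' @param config a `populationConfig`.
#' @param profile the calibration condition ([StimulusProfile-class]).
#' @param targetFraction target fraction active.
#' @param interval search interval for `theta` (signal units).
#' @param tol absolute tolerance on `theta`.
#' @return list: `theta`, `achieved_fraction`, `peaks` (the per-cell
#'   baseline-subtracted maxima the bisection ran on).
#' @export
calibrateThreshold <- function(params, config, profile, targetFraction,
                               interval = c(0.01, 0.9), tol = 1e-4) {
    cells <- samplePopulation(config)
    cl <- .cellList(cells)
    tGrid <- seq(0, profile@totalObservation, by = 1)
    peaks <- vapply(cl, function(cell) {
        sig <- simulateCell(params, cell, profile, tGrid)
        max(sig - sig[1])
    }, numeric(1))
    frac <- function(theta) mean(peaks >= theta)
    lo <- interval[1]; hi <- interval[2]
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (frac(mid) > targetFraction) lo <- mid else hi <- mid
    }
    theta <- (lo + hi) / 2
    list(theta = theta, achieved_fraction = frac(theta), peaks = peaks)
}

#' Weighted least-squares calibration against summary targets
#'
#' General calibration: minimizes the weighted squared deviation between
#' simulated condition summaries and target values over a chosen set of
#' free parameters. Free parameters are optimized on a log scale (all are
#' positive). This is the expensive, offline entry point; the shipped
#' defaults were produced with it and committed.
#'
#' @param targets list of targets, each a list with `profile`
#'   ([StimulusProfile-class]), `statistic` (`"fraction_active"` or
#'   `"median_peak_time"`), `value`, and optional `weight`.
#' @param params starting `nfkbParameters`.
#' @param config starting `populationConfig`.
#' @param free character vector of free parameters: any rate-constant name,
#'   `"sigma_tlr4"`, or `"theta"`.
#' @param nCells population size per evaluation (calibration runs may use
#'   fewer cells than the default screens).
#' @param maxit optimizer iterations.
#' @return list: calibrated `params`, `config`, `theta`, `residuals`
#'   (per-target data.frame), `value` (objective), `converged` (flag;
#'   best-found parameters are returned with a warning when the optimizer
#'   hit `maxit`).
#' @export
calibrate <- function(targets, params, config, free, nCells = 100,
                      maxit = 50) {
    if (!length(targets)) stop("empty target list")
    theta0 <- thresholdDefaults(params$ligand_variant)$theta
    getp <- function(nm, prm, cfg, th) {
        if (nm == "sigma_tlr4") cfg$sigma_tlr4
        else if (nm == "theta") th
        else prm[[nm]]
    }
    x0 <- log(vapply(free, getp, numeric(1), prm = params, cfg = config,
                     th = theta0))
    cfgSmall <- config; cfgSmall$n_cells <- as.integer(nCells)
    evalTargets <- function(x) {
        prm <- params; cfg <- cfgSmall; th <- theta0
        for (k in seq_along(free)) {
            v <- exp(x[k])
            if (free[k] == "sigma_tlr4") cfg$sigma_tlr4 <- v
            else if (free[k] == "theta") th <- v
            else prm[[free[k]]] <- v
        }
        thr <- list(theta = th, smooth_window = 3)
        cells <- samplePopulation(cfg)
        eq <- equilibratePopulation(prm, cells)
        vapply(targets, function(tg) {
            r <- simulateCondition(prm, cells, tg$profile, threshold = thr,
                                   equilibria = eq)
            as.numeric(r$summary[[tg$statistic]])
        }, numeric(1))
    }
    wts <- vapply(targets, function(tg) tg$weight %||% 1, numeric(1))
    vals <- vapply(targets, function(tg) tg$value, numeric(1))
    obj <- function(x) {
        sim <- evalTargets(x)
        sum(wts * ((sim - vals) / pmax(abs(vals), 0.05))^2)
    }
    opt <- optim(x0, obj, method = if (length(x0) == 1) "Brent"
                 else "Nelder-Mead",
                 lower = if (length(x0) == 1) x0 - 3 else -Inf,
                 upper = if (length(x0) == 1) x0 + 3 else Inf,
                 control = list(maxit = maxit))
    if (opt$convergence != 0)
        warning("calibration optimizer did not converge; returning best found")
    prm <- params; cfg <- config; th <- theta0
    for (k in seq_along(free)) {
        v <- exp(opt$par[k])
        if (free[k] == "sigma_tlr4") cfg$sigma_tlr4 <- v
        else if (free[k] == "theta") th <- v
        else prm[[free[k]]] <- v
    }
    sim <- evalTargets(opt$par)
    list(params = prm, config = cfg, theta = th,
         residuals = data.frame(
             statistic = vapply(targets, `[[`, "", "statistic"),
             target = vals, achieved = sim, residual = sim - vals),
         value = opt$value, converged = opt$convergence == 0)
}
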