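#' Sample an extrinsic-noise population
#'
#' Draws `n_cells` independent cells: receptor scale `R ~ lognormal(mu_tlr4,
#' sigma_tlr4)` and total NF-kB `Ntot ~ lognormal(mu_nfkb, sigma_nfkb)`.
#' Deterministic under the config's seed (one root seed; draws are made in a
#' fixed vectorized order, so populations are reproducible independent of
#' execution order).
#'
#' @param config a `populationConfig`.
#' @return `DataFrame` with `cell_id`, `tlr4_count`, `nfkb_total`.
#' @export
samplePopulation <- function(config) {
    stopifnot(inherits(config, "populationConfig"))
    set.seed(config$seed)
    n <- config$n_cells
    DataFrame(
        cell_id = sprintf("cell_%04d", seq_len(n)),
        tlr4_count = rlnorm(n, config$mu_tlr4, config$sigma_tlr4),
        nfkb_total = rlnorm(n, config$mu_nfkb, config$sigma_nfkb)
    )
}

.cellList <- function(cells) {
    lapply(seq_len(nrow(cells)), function(i)
        cellParameters(cells$tlr4_count[i], cells$nfkb_total[i],
                       cells$cell_id[i]))
}

#' Pre-equilibrate a population
#'
#' The resting state depends on the cell's total NF-kB only (no ligand), so
#' screens sharing a population can reuse these states across conditions.
#'
#' @param params an `nfkbParameters` list.
#' @param cells population `DataFrame` from [samplePopulation()].
#' @return matrix of resting states, one row per cell.
#' @export
equilibratePopulation <- function(params, cells) {
    cl <- .cellList(cells)
    t(vapply(cl, function(cell)
        as.numeric(equilibrateCell(params, cell)),
        numeric(length(.STATE_NAMES))))
}

#' Simulate one stimulation condition over a population
#'
#' One deterministic ODE trajectory per sampled cell; features and the
#' activation call come from the analysis pipeline, and the fraction of
#' active cells is recorded with its binomial standard error.
#'
#' @param params an `nfkbParameters` list.
#' @param cells population `DataFrame` ([samplePopulation()]), or a
#'   `populationConfig` (then sampled here).
#' @param profile a [StimulusProfile-class].
#' @param tGrid output grid in minutes (default 1-min over the observation
#'   window).
#' @param threshold classifier settings (list with `theta`,
#'   `smooth_window`); defaults to the calibrated values for the profile's
#'   ligand.
#' @param equilibria optional matrix of pre-computed resting states
#'   ([equilibratePopulation()]).
#' @return list of class `conditionResult`: `trajectories`
#'   ([TrajectorySet-class] with per-cell features in `colData`),
#'   `features` (`DataFrame`), `summary` (one-row `data.frame` from
#'   [summarizeCondition()]), `fraction_active`, `se`, `condition`.
#' @export
simulateCondition <- function(params, cells, profile, tGrid = NULL,
                              threshold = NULL, equilibria = NULL) {
    if (inherits(cells, "populationConfig"))
        cells <- samplePopulation(cells)
    if (is.null(tGrid))
        tGrid <- seq(0, profile@totalObservation, by = 1)
    if (is.null(threshold))
        threshold <- thresholdDefaults(profile@ligand)
    cl <- .cellList(cells)
    n <- length(cl)
    sig <- matrix(NA_real_, length(tGrid), n)
    for (i in seq_len(n)) {
        init <- if (!is.null(equilibria))
            setNames(equilibria[i, ], .STATE_NAMES) else NULL
        sig[, i] <- simulateCell(params, cl[[i]], profile, tGrid,
                                 init = init)
    }
    cond <- list(ligand = profile@ligand, mode = profile@chamberMode,
                 dose_ng_ml = if (nrow(profile@segments))
                     max(profile@segments[, 3]) else 0,
                 duration_s = if (nrow(profile@segments))
                     max(profile@segments[, 2]) else 0,
                 area_ng_s_ml = stimulusArea(profile),
                 n_segments = nrow(profile@segments))
    ts <- TrajectorySet(sig, tGrid, cellData = cells,
                        metadata = list(condition = cond,
                                        threshold = threshold))
    feats <- trajectoryFeatures(ts, threshold = threshold)
    colData(ts) <- cbind(colData(ts), feats[, setdiff(colnames(feats),
                                                      "cell_id")])
    summ <- summarizeCondition(feats)
    fa <- summ$fraction_active
    structure(list(trajectories = ts, features = feats, summary = summ,
                   fraction_active = fa,
                   se = sqrt(fa * (1 - fa) / n),
                   condition = cond),
              class = "conditionResult")
}

#' @export
print.conditionResult <- function(x, ...) {
    cat(sprintf(
        "conditionResult: %s %s, %g ng/ml x %g s (area %g), %d cells\n",
        x$condition$ligand, x$condition$mode, x$condition$dose_ng_ml,
        x$condition$duration_s, x$condition$area_ng_s_ml,
        ncol(x$trajectories)))
    cat(sprintf("  fraction active %.3f (SE %.3f), median peak time %s min\n",
                x$fraction_active, x$se,
                format(x$summary$median_peak_time)))
    invisible(x)
}

#' Run a dose x duration stimulation screen
#'
#' Full cross product of the dose and duration grids. By default each
#' condition draws an independent population of `config$n_cells` cells
#' (seeded deterministically from the root seed); with `sharedCells = TRUE`
#' a single population is drawn once and reused across all conditions,
#' which removes sampling noise from between-condition comparisons.
#'
#' @param params an `nfkbParameters` list.
#' @param doses vector of doses (ng/ml).
#' @param durations vector of durations (seconds). `Inf` means sustained
#'   over the whole observation window.
#' @param config a `populationConfig`.
#' @param chamberMode `"sealed"` or `"perfused"`.
#' @param ligand `"LPS"` or `"TNF"`.
#' @param sharedCells reuse one population across conditions.
#' @param totalObservation observation window, minutes.
#' @param tGrid optional output grid.
#' @param threshold optional classifier override.
#' @return list of `conditionResult`, with a `summary` attribute holding
#'   the tidy one-row-per-condition data.frame (see [screenSummary()]).
#' @export
runScreen <- function(params, doses, durations, config,
                      chamberMode = "sealed", ligand = "LPS",
                      sharedCells = FALSE, totalObservation = 360,
                      tGrid = NULL, threshold = NULL) {
    if (!length(doses) || !length(durations))
        stop("dose and duration grids must be non-empty")
    grid <- expand.grid(dose = doses, duration = durations,
                        KEEP.OUT.ATTRS = FALSE)
    shared <- NULL; eq <- NULL
    if (sharedCells) {
        shared <- samplePopulation(config)
        eq <- equilibratePopulation(params, shared)
    }
    results <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
        dur <- grid$duration[i]
        profile <- if (is.infinite(dur))
            makeSustained(grid$dose[i], chamberMode, ligand,
                          totalObservation)
        else
            makePulse(grid$dose[i], dur, chamberMode, ligand,
                      totalObservation)
        cells <- if (sharedCells) shared else {
            cfg_i <- config
            cfg_i$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
            samplePopulation(cfg_i)
        }
        results[[i]] <- simulateCondition(params, cells, profile,
                                          tGrid = tGrid,
                                          threshold = threshold,
                                          equilibria = eq)
    }
    attr(results, "summary") <- screenSummary(results)
    results
}

#' Tidy per-condition summary of a screen
#'
#' One row per condition: ligand, dose, duration, waveform, area, n_cells,
#' fraction active with binomial SE, and median/IQR/CV of the first-peak
#' features over active cells.
#'
#' @param results list of `conditionResult` (from [runScreen()] or built
#'   manually).
#' @return data.frame.
#' @export
screenSummary <- function(results) {
    do.call(rbind, lapply(results, function(r) {
        s <- r$summary
        data.frame(
            ligand = r$condition$ligand,
            mode = r$condition$mode,
            dose_ng_ml = r$condition$dose_ng_ml,
            duration_s = r$condition$duration_s,
            waveform = if (r$condition$n_segments > 1) "square_wave"
                       else "pulse",
            area_ng_s_ml = r$condition$area_ng_s_ml,
            n_cells = ncol(r$trajectories),
            fraction_active = r$fraction_active,
            se = r$se,
            median_peak_time_min = s$median_peak_time,
            iqr_peak_time = s$iqr_peak_time,
            median_amplitude = s$median_amplitude,
            iqr_amplitude = s$iqr_amplitude,
            median_first_peak_area = s$median_first_peak_area,
            iqr_first_peak_area = s$iqr_first_peak_area,
            cv_peak_time = s$cv_peak_time
        )
    }))
}

#' Write screen outputs
#'
#' Emits the tidy condition summary CSV and, optionally, one trajectory CSV
#' per condition in the analysis-module dialect (`cell_id`, `time_min`,
#' `nuclear_signal`).
#'
#' @param results list of `conditionResult`.
#' @param dir output directory (created if needed).
#' @param trajectories also write per-condition trajectory CSVs.
#' @return the summary CSV path, invisibly.
#' @export
writeScreen <- function(results, dir, trajectories = FALSE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    summ <- attr(results, "summary") %||% screenSummary(results)
    path <- file.path(dir, "screen_summary.csv")
    write.csv(summ, path, row.names = FALSE)
    if (trajectories)
        for (i in seq_along(results)) {
            cond <- results[[i]]$condition
            fn <- file.path(dir, sprintf(
                "trajectories_%s_%g_ngml_%gs.csv", cond$ligand,
                cond$dose_ng_ml, cond$duration_s))
            writeTrajectories(results[[i]]$trajectories, fn)
        }
    invisible(path)
}
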