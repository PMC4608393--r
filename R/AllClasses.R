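#' StimulusProfile: a piecewise-constant ligand input waveform
#'
#' Describes the extracellular ligand input delivered to a microfluidic
#' chamber: an ordered set of non-overlapping segments, each holding a
#' constant nominal concentration, together with the ligand identity and the
#' chamber mode. In `sealed` mode the ligand deposited at a segment start is
#' subject to cellular depletion while the segment lasts and is washed out at
#' the segment end; in `perfused` mode the nominal concentration is held
#' constant by continuous flow. Time inside segments is in seconds
#' (stimulation is sub-minute to minutes); the observation window for
#' trajectories is in minutes.
#'
#' @slot ligand `"LPS"` or `"TNF"`.
#' @slot segments numeric matrix with columns `t0`, `t1`, `conc`
#'   (seconds, seconds, ng/ml), ordered and non-overlapping.
#' @slot chamberMode `"sealed"` or `"perfused"`.
#' @slot totalObservation observation window in minutes (trajectory length).
#'
#' @seealso [makePulse()], [makeSquareWave()], [makeSustained()],
#'   [stimulusArea()], [concentrationAt()]
#' @export
setClass("StimulusProfile",
    representation(
        ligand = "character",
        segments = "matrix",
        chamberMode = "character",
        totalObservation = "numeric"
    ),
    prototype(
        ligand = "LPS",
        segments = matrix(numeric(0), ncol = 3,
                          dimnames = list(NULL, c("t0", "t1", "conc"))),
        chamberMode = "sealed",
        totalObservation = 360
    )
)

setValidity("StimulusProfile", function(object) {
    msg <- character(0)
    if (!object@ligand %in% c("LPS", "TNF"))
        msg <- c(msg, "ligand must be 'LPS' or 'TNF'")
    if (!object@chamberMode %in% c("sealed", "perfused"))
        msg <- c(msg, "chamberMode must be 'sealed' or 'perfused'")
    s <- object@segments
    if (ncol(s) != 3)
        msg <- c(msg, "segments must have columns t0, t1, conc")
    if (nrow(s) > 0) {
        if (any(s[, 1] < 0) || any(s[, 2] <= s[, 1]))
            msg <- c(msg, "segments need 0 <= t0 < t1")
        if (any(s[, 3] < 0))
            msg <- c(msg, "segment concentrations must be >= 0")
        if (nrow(s) > 1 && any(s[-1, 1] < s[-nrow(s), 2] - 1e-9))
            msg <- c(msg, "segments must be ordered and non-overlapping")
    }
    if (length(object@totalObservation) != 1 || object@totalObservation <= 0)
        msg <- c(msg, "totalObservation must be a positive scalar (minutes)")
    if (length(msg)) msg else TRUE
})

#' TrajectorySet: single-cell NF-kB trajectories with per-cell metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one matrix of the analysis signal (rows = time points, columns = cells).
#' For model output the signal is the proportion of total NF-kB in the
#' nucleus; for imaging-style tracks it is the nuclear/cytoplasm intensity
#' ratio. `rowData` carries `time_min`; `colData` carries per-cell
#' parameters (receptor scale, total NF-kB, ground-truth fields for
#' synthetic data, exclusion masks).
#'
#' @seealso [signalMatrix()], [timePoints()], [trajectoryFeatures()]
#' @export
setClass("TrajectorySet", contains = "SummarizedExperiment")

setValidity("TrajectorySet", function(object) {
    msg <- character(0)
    if (!"signal" %in% names(assays(object)))
        msg <- c(msg, "TrajectorySet needs a 'signal' assay")
    if (!"time_min" %in% names(rowData(object)))
        msg <- c(msg, "rowData must carry 'time_min'")
    else {
        tm <- rowData(object)$time_min
        if (length(tm) > 1 && any(diff(tm) <= 0))
            msg <- c(msg, "time_min must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TrajectorySet
#'
#' @param signal numeric matrix, time points x cells.
#' @param time numeric vector of times in minutes (length `nrow(signal)`),
#'   starting at stimulation onset (t = 0).
#' @param cellData `DataFrame`/`data.frame` of per-cell metadata with
#'   `ncol(signal)` rows (may be missing).
#' @param metadata optional list (condition description etc.).
#' @return A [TrajectorySet-class] object.
#' @examples
#' ts <- TrajectorySet(matrix(runif(20), 10, 2), time = seq(0, 45, by = 5))
#' dim(ts)
#' @export
TrajectorySet <- function(signal, time, cellData = NULL, metadata = list()) {
    signal <- as.matrix(signal)
    if (length(time) != nrow(signal))
        stop("length(time) must equal nrow(signal)")
    if (is.null(cellData))
        cellData <- DataFrame(cell_id = colnames(signal) %||%
                                  paste0("cell_", seq_len(ncol(signal))))
    cellData <- DataFrame(cellData)
    if (is.null(cellData$cell_id))
        cellData$cell_id <- colnames(signal) %||%
            paste0("cell_", seq_len(ncol(signal)))
    colnames(signal) <- cellData$cell_id
    se <- SummarizedExperiment(
        assays = list(signal = signal),
        rowData = DataFrame(time_min = as.numeric(time)),
        colData = cellData,
        metadata = metadata
    )
    new("TrajectorySet", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn TrajectorySet signal matrix (time points x cells)
#' @param x a `TrajectorySet`
#' @export
signalMatrix <- function(x) assay(x, "signal")

#' @describeIn TrajectorySet time grid in minutes
#' @export
timePoints <- function(x) rowData(x)$time_min

setMethod("show", "TrajectorySet", function(object) {
    tm <- timePoints(object)
    cat("TrajectorySet:", ncol(object), "cells,", nrow(object),
        "time points (", min(tm), "-", max(tm), "min )\n")
    cond <- metadata(object)$condition
    if (!is.null(cond))
        cat("  condition:", paste(names(cond), unlist(cond),
                                  sep = "=", collapse = ", "), "\n")
})
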