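## Trajectory feature extraction mirroring the imaging analysis pipeline:
## activation call on the baseline-subtracted maximum, centered moving
## average smoothing, first-peak detection (earliest-time tie break),
## baseline-corrected trapezoidal first-peak area, median/IQR condition
## summaries over active cells, Hill dose-response fits, population-CV
## heterogeneity, and unpaired two-sample t-test tables.

#' Centered moving-average smoothing
#'
#' @param x numeric vector.
#' @param window odd window length in samples (default 3). `1` disables
#'   smoothing. Edges use the available samples.
#' @return smoothed vector, same length.
#' @export
smoothSignal <- function(x, window = 3) {
    if (window <= 1) return(x)
    if (window %% 2 == 0) stop("window must be odd")
    h <- (window - 1) / 2
    n <- length(x)
    vapply(seq_len(n), function(i) {
        mean(x[max(1, i - h):min(n, i + h)])
    }, numeric(1))
}

#' Activation call for a single trajectory
#'
#' A cell is active iff the maximum baseline-subtracted signal over the
#' observation window reaches the threshold: `max(signal - baseline) >=
#' theta`. The baseline is the pre-peak sample at t = 0. The experimentally
#' observed all-or-none partition is reproduced with `theta` a calibrated
#' fraction (default 25%) of the median saturating-response amplitude.
#'
#' @param signal numeric trajectory (nuclear fraction or nuclear/cyto
#'   ratio); first sample is the t = 0 baseline.
#' @param theta activation threshold in signal units.
#' @param minLength minimum trajectory length (samples).
#' @return logical.
#' @export
classifyActivation <- function(signal, theta, minLength = 5) {
    if (length(signal) < minLength)
        stop("trajectory shorter than the minimum window (", minLength,
             " samples)")
    max(signal - signal[1]) >= theta
}

#' First-peak detection
#'
#' The signal is smoothed with a centered moving average; the peak is the
#' maximum of the smoothed signal (earliest index on ties), and the first
#' local minimum after it bounds the first peak. The amplitude is reported
#' from the unsmoothed signal at the detected index, so uniform baseline
#' shifts leave timing unchanged and rescaling scales amplitude linearly.
#'
#' @param signal numeric trajectory.
#' @param time time grid in minutes.
#' @param smoothWindow smoothing window in samples (odd; default 3).
#' @return list: `peak_index`, `peak_time` (min), `peak_amplitude`
#'   (unsmoothed), `min_index`/`min_time` of the first post-peak minimum
#'   (`NA` + `truncated = TRUE` when the trajectory ends first).
#' @export
detectFirstPeak <- function(signal, time, smoothWindow = 3) {
    s <- smoothSignal(signal, smoothWindow)
    ipk <- which.max(s)          # earliest index on exact ties
    imin <- NA_integer_
    if (ipk < length(s)) {
        after <- s[ipk:length(s)]
        ## first interior local minimum after the peak
        for (j in seq_len(length(after) - 2)) {
            if (after[j + 1] <= after[j] && after[j + 1] <= after[j + 2]) {
                imin <- ipk + j
                break
            }
        }
    }
    list(peak_index = ipk, peak_time = time[ipk],
         peak_amplitude = signal[ipk],
         min_index = imin,
         min_time = if (is.na(imin)) NA_real_ else time[imin],
         truncated = is.na(imin))
}

#' Baseline-corrected first-peak area
#'
#' Trapezoidal integral of `pmax(signal - baseline, 0)` from t = 0 to the
#' first post-peak minimum (the whole window, flagged truncated, when no
#' minimum is found). The baseline is the t = 0 sample.
#'
#' @param signal numeric trajectory.
#' @param time time grid in minutes.
#' @param peak optional result of [detectFirstPeak()] (recomputed if
#'   missing).
#' @param smoothWindow smoothing window for peak detection.
#' @return area in signal x minutes, with attribute `"truncated"`.
#' @export
firstPeakArea <- function(signal, time, peak = NULL, smoothWindow = 3) {
    if (is.null(peak))
        peak <- detectFirstPeak(signal, time, smoothWindow)
    end <- if (peak$truncated) length(signal) else peak$min_index
    y <- pmax(signal[1:end] - signal[1], 0)
    a <- pracma::trapz(time[1:end], y)
    attr(a, "truncated") <- peak$truncated
    a
}

#' Per-cell trajectory features
#'
#' Applies the activation classifier and first-peak analysis to every cell
#' of a [TrajectorySet-class]. Inactive cells carry `NA` timing/area
#' fields. Cells flagged in an `exclude` column of `colData` (mitotic-cell
#' mask) are dropped from the output.
#'
#' @param ts a [TrajectorySet-class].
#' @param threshold list with `theta` and `smooth_window`; defaults to the
#'   calibrated LPS classifier.
#' @return `DataFrame`: `cell_id`, `active`, `onset_time`, `peak_time`,
#'   `peak_amplitude` (baseline-subtracted), `first_peak_area`,
#'   `truncated`.
#' @export
trajectoryFeatures <- function(ts, threshold = NULL) {
    if (is.null(threshold))
        threshold <- metadata(ts)$threshold %||% thresholdDefaults("LPS")
    sig <- signalMatrix(ts)
    tm <- timePoints(ts)
    keep <- seq_len(ncol(sig))
    if (!is.null(colData(ts)$exclude))
        keep <- keep[!as.logical(colData(ts)$exclude)]
    rows <- lapply(keep, function(i) {
        x <- sig[, i]
        act <- classifyActivation(x, threshold$theta)
        if (!act)
            return(DataFrame(cell_id = colnames(sig)[i], active = FALSE,
                             onset_time = NA_real_, peak_time = NA_real_,
                             peak_amplitude = NA_real_,
                             first_peak_area = NA_real_,
                             truncated = NA))
        pk <- detectFirstPeak(x, tm, threshold$smooth_window %||% 3)
        onset <- tm[which(x - x[1] >= threshold$theta)[1]]
        area <- firstPeakArea(x, tm, peak = pk)
        DataFrame(cell_id = colnames(sig)[i], active = TRUE,
                  onset_time = onset, peak_time = pk$peak_time,
                  peak_amplitude = pk$peak_amplitude - x[1],
                  first_peak_area = as.numeric(area),
                  truncated = attr(area, "truncated"))
    })
    do.call(rbind, rows)
}

.iqr <- function(x) diff(quantile(x, c(0.25, 0.75), names = FALSE))

#' Condition-level summary statistics
#'
#' Fraction active over all (non-excluded) cells; median and interquartile
#' range of first-peak time, amplitude and area, and the coefficient of
#' variation of peak times, over active cells only. With zero active cells
#' the dynamics fields are `NA`.
#'
#' @param features `DataFrame`/`data.frame` from [trajectoryFeatures()].
#' @return one-row data.frame.
#' @export
summarizeCondition <- function(features) {
    if (nrow(features) < 1) stop("need at least one feature record")
    act <- features[features$active %in% TRUE, , drop = FALSE]
    na <- nrow(act)
    stat <- function(f) if (na) f else NA_real_
    data.frame(
        n_cells = nrow(features),
        n_active = na,
        fraction_active = na / nrow(features),
        median_peak_time = stat(median(act$peak_time)),
        iqr_peak_time = stat(.iqr(act$peak_time)),
        median_amplitude = stat(median(act$peak_amplitude)),
        iqr_amplitude = stat(.iqr(act$peak_amplitude)),
        median_first_peak_area = stat(median(act$first_peak_area)),
        iqr_first_peak_area = stat(.iqr(act$first_peak_area)),
        cv_peak_time = if (na >= 2) cvHeterogeneity(act$peak_time)
                       else NA_real_
    )
}

#' Coefficient of variation of response times
#'
#' Population (divide-by-n) standard deviation over the mean. The
#' population convention is fixed here to avoid sd-convention drift between
#' analyses.
#'
#' @param times numeric vector (>= 2 values).
#' @return dimensionless CV; `NaN` with a warning when the mean is 0.
#' @export
cvHeterogeneity <- function(times) {
    if (length(times) < 2) stop("need >= 2 values")
    m <- mean(times)
    if (m == 0) {
        warning("mean response time is 0; CV undefined")
        return(NaN)
    }
    sqrt(mean((times - m)^2)) / m
}

#' Pairwise two-sample t-tests
#'
#' Unpaired two-sample t-tests for every pair of groups (equal-variance by
#' default, matching the classic two-sample form; Welch available via
#' `welch = TRUE`). Raw p-values, no multiple-testing correction.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param welch use the Welch (unequal variance) variant.
#' @param alpha significance flag level (default 0.05).
#' @return list with symmetric matrices `p` and `significant`; pairs where
#'   both groups are constant and identical yield `NA` p-values (flagged
#'   `NA`).
#' @export
pairwiseTests <- function(groups, welch = FALSE, alpha = 0.05) {
    if (any(vapply(groups, length, 1L) < 2))
        stop("each group needs n >= 2")
    k <- length(groups)
    nm <- names(groups) %||% paste0("group", seq_len(k))
    p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (i == j) next
        pv <- tryCatch(
            t.test(groups[[i]], groups[[j]], var.equal = !welch)$p.value,
            error = function(e) NA_real_)
        p[i, j] <- pv
    }
    diag(p) <- NA_real_
    list(p = p, significant = p < alpha)
}

#' Short-strong vs long-low discrimination by response delay
#'
#' Takes condition summaries labeled `SS` (short duration, strong
#' amplitude) or `LL` (long duration, low amplitude), pairs them by
#' stimulus area, and reports the timing margin `median delay(LL) - median
#' delay(SS)` for each matched-area pair. A positive minimum margin means
#' response time separates the two input classes; a monotone separating
#' boundary in (area, delay) space is returned as the pairwise midpoints
#' when one exists.
#'
#' @param summaries data.frame with columns `label` (`"SS"`/`"LL"`),
#'   `area_ng_s_ml`, `median_peak_time_min`.
#' @param areaTol relative tolerance for area matching (default 0.05).
#' @return list: `pairs` (data.frame with per-pair margins), `min_margin`,
#'   `separated` (all margins > 0), `boundary` (data.frame of area /
#'   midpoint delay, or `NULL`).
#' @export
ssLlDiscriminator <- function(summaries, areaTol = 0.05) {
    ss <- summaries[summaries$label == "SS", , drop = FALSE]
    ll <- summaries[summaries$label == "LL", , drop = FALSE]
    if (!nrow(ss) || !nrow(ll)) stop("need both SS and LL conditions")
    pairs <- list()
    for (i in seq_len(nrow(ll))) {
        d <- abs(ss$area_ng_s_ml - ll$area_ng_s_ml[i]) /
            ll$area_ng_s_ml[i]
        j <- which.min(d)
        if (d[j] > areaTol)
            stop(sprintf("no SS condition with area matching %g (rel dev %.2f)",
                         ll$area_ng_s_ml[i], d[j]))
        pairs[[i]] <- data.frame(
            area_ng_s_ml = ll$area_ng_s_ml[i],
            delay_ll = ll$median_peak_time_min[i],
            delay_ss = ss$median_peak_time_min[j],
            margin = ll$median_peak_time_min[i] - ss$median_peak_time_min[j])
    }
    pairs <- do.call(rbind, pairs)
    sep <- all(pairs$margin > 0)
    boundary <- if (sep)
        data.frame(area_ng_s_ml = pairs$area_ng_s_ml,
                   delay_min = (pairs$delay_ll + pairs$delay_ss) / 2)
    else NULL
    list(pairs = pairs, min_margin = min(pairs$margin), separated = sep,
         boundary = boundary)
}

#' Read / write trajectory tables
#'
#' The trajectory CSV dialect is long-format: `cell_id`, `time_min`,
#' `nuclear_signal`, optional `cyto_signal` and `exclude_flag`. When
#' `cyto_signal` is present the analysis signal is the nuclear/cytoplasm
#' intensity ratio.
#'
#' @param path CSV file.
#' @return `readTrajectories`: a [TrajectorySet-class];
#'   `writeTrajectories`: `path` invisibly.
#' @export
readTrajectories <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("cell_id", "time_min", "nuclear_signal")
    if (!all(need %in% names(df)))
        stop("trajectory CSV needs columns: ", paste(need, collapse = ", "))
    if (nrow(df) == 0) stop("empty trajectory table")
    sigcol <- if ("cyto_signal" %in% names(df))
        df$nuclear_signal / df$cyto_signal else df$nuclear_signal
    df$.sig <- sigcol
    tm <- sort(unique(df$time_min))
    ids <- unique(df$cell_id)
    mat <- matrix(NA_real_, length(tm), length(ids),
                  dimnames = list(NULL, ids))
    idx <- cbind(match(df$time_min, tm), match(df$cell_id, ids))
    mat[idx] <- df$.sig
    cd <- DataFrame(cell_id = ids)
    if ("exclude_flag" %in% names(df)) {
        ex <- tapply(df$exclude_flag, df$cell_id, function(v) any(v > 0))
        cd$exclude <- as.logical(ex[ids])
    }
    TrajectorySet(mat, tm, cellData = cd,
                  metadata = list(source = path,
                                  ratio = "cyto_signal" %in% names(df)))
}

#' @rdname readTrajectories
#' @param ts a [TrajectorySet-class].
#' @export
writeTrajectories <- function(ts, path) {
    sig <- signalMatrix(ts)
    df <- data.frame(
        cell_id = rep(colnames(sig), each = nrow(sig)),
        time_min = rep(timePoints(ts), ncol(sig)),
        nuclear_signal = as.vector(sig)
    )
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}
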