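#' Construct a rectangular ligand pulse
#'
#' A single-segment stimulus starting at t = 0: dose `dose` for `duration`
#' seconds, then washout. Stimulation onset defines the clock for all
#' downstream timing features. A sustained stimulation is simply a pulse
#' whose duration covers the whole observation window (see
#' [makeSustained()]).
#'
#' @param dose concentration in ng/ml (>= 0).
#' @param duration pulse length in seconds (> 0).
#' @param chamberMode `"sealed"` (ligand depleted by cellular
#'   internalization while present) or `"perfused"` (concentration held by
#'   flow).
#' @param ligand `"LPS"` or `"TNF"`.
#' @param totalObservation observation window in minutes.
#' @return A [StimulusProfile-class].
#' @examples
#' p <- makePulse(500, 10)         # area 5000 ng s/ml
#' stimulusArea(p)
#' @export
makePulse <- function(dose, duration, chamberMode = "sealed",
                      ligand = "LPS", totalObservation = 360) {
    if (!is.numeric(dose) || length(dose) != 1 || is.na(dose) || dose < 0)
        stop("dose must be a single non-negative number (ng/ml)")
    if (!is.numeric(duration) || length(duration) != 1 || is.na(duration) ||
        duration <= 0)
        stop("duration must be a single positive number (seconds)")
    new("StimulusProfile", ligand = ligand,
        segments = matrix(c(0, duration, dose), 1, 3,
                          dimnames = list(NULL, c("t0", "t1", "conc"))),
        chamberMode = chamberMode, totalObservation = totalObservation)
}

#' Construct a sustained (step) stimulus
#'
#' Ligand applied at t = 0 and left for the entire observation window. In
#' `sealed` mode the chamber is closed after delivery so the concentration
#' decays through cellular internalization, which damps the NF-kB
#' oscillations; in `perfused` mode the ligand is flowed continuously and
#' oscillations sustain.
#'
#' @inheritParams makePulse
#' @return A [StimulusProfile-class].
#' @export
makeSustained <- function(dose, chamberMode = "sealed", ligand = "LPS",
                          totalObservation = 360) {
    makePulse(dose, totalObservation * 60, chamberMode = chamberMode,
              ligand = ligand, totalObservation = totalObservation)
}

#' Construct a square-wave stimulus
#'
#' Alternating high (dose) / low (0) half-periods, truncated at
#' `totalDuration` seconds. With `phase = "start_high"` the first
#' half-period is high; with `"start_low"` it is zero. Duty cycle defaults
#' to 50%. When `totalDuration` is an exact multiple of the period the two
#' phases deliver identical area.
#'
#' @param dose high-level concentration in ng/ml.
#' @param period full period in seconds (> 0); each high/low phase lasts
#'   `period * dutyCycle` and `period * (1 - dutyCycle)` seconds.
#' @param phase `"start_high"` or `"start_low"`.
#' @param totalDuration total length of the wave in seconds.
#' @param dutyCycle fraction of each period spent high (default 0.5).
#' @inheritParams makePulse
#' @return A [StimulusProfile-class]. A `start_low` wave shorter than half a
#'   period yields a valid zero-area profile.
#' @examples
#' ## both phases deliver equal area at every multiple of the period
#' stimulusArea(makeSquareWave(500, 10, "start_high", 30))  # 7500
#' stimulusArea(makeSquareWave(500, 10, "start_low", 30))   # 7500
#' @export
makeSquareWave <- function(dose, period, phase = c("start_high", "start_low"),
                           totalDuration, dutyCycle = 0.5,
                           chamberMode = "sealed", ligand = "LPS",
                           totalObservation = 360) {
    phase <- match.arg(phase)
    if (!is.numeric(period) || length(period) != 1 || period <= 0)
        stop("period must be a single positive number (seconds)")
    if (dose < 0) stop("dose must be >= 0")
    if (totalDuration <= 0) stop("totalDuration must be > 0 (seconds)")
    high <- period * dutyCycle
    s0 <- if (phase == "start_high") 0 else period - high
    starts <- if (s0 >= totalDuration) numeric(0)
              else seq(s0, totalDuration, by = period)
    segs <- cbind(t0 = starts, t1 = pmin(starts + high, totalDuration))
    segs <- segs[segs[, 1] < totalDuration & segs[, 2] > segs[, 1], ,
                 drop = FALSE]
    segs <- cbind(segs, conc = rep(dose, nrow(segs)))
    if (nrow(segs) == 0)
        segs <- matrix(numeric(0), ncol = 3,
                       dimnames = list(NULL, c("t0", "t1", "conc")))
    new("StimulusProfile", ligand = ligand, segments = segs,
        chamberMode = chamberMode, totalObservation = totalObservation)
}

#' Stimulus area (integral of the input)
#'
#' The integral of the nominal delivered waveform, concentration x duration
#' summed over segments, in ng s/ml. Defined on the nominal waveform:
#' sealed-mode depletion acts inside the ODE, not here.
#'
#' @param profile a [StimulusProfile-class].
#' @return area in ng s/ml.
#' @export
stimulusArea <- function(profile) {
    s <- profile@segments
    if (nrow(s) == 0) return(0)
    sum((s[, 2] - s[, 1]) * s[, 3])
}

#' Nominal concentration at a time point
#'
#' @param profile a [StimulusProfile-class].
#' @param t time(s) in seconds (>= 0); vectorized.
#' @return nominal (pre-depletion) concentration in ng/ml; 0 outside all
#'   segments.
#' @export
concentrationAt <- function(profile, t) {
    s <- profile@segments
    vapply(t, function(tt) {
        hit <- which(s[, 1] <= tt & tt < s[, 2])
        if (length(hit)) s[hit[1], 3] else 0
    }, numeric(1))
}

#' Concatenate two stimulus profiles in time
#'
#' Appends `b`'s segments after the end of `a`'s last segment. Used mainly
#' for the area-additivity property.
#'
#' @param a,b [StimulusProfile-class] objects with matching ligand and mode.
#' @return A [StimulusProfile-class].
#' @export
concatProfiles <- function(a, b) {
    if (a@ligand != b@ligand || a@chamberMode != b@chamberMode)
        stop("profiles must share ligand and chamber mode")
    off <- if (nrow(a@segments)) max(a@segments[, 2]) else 0
    sb <- b@segments
    if (nrow(sb)) {
        sb[, 1] <- sb[, 1] + off
        sb[, 2] <- sb[, 2] + off
    }
    new("StimulusProfile", ligand = a@ligand,
        segments = rbind(a@segments, sb), chamberMode = a@chamberMode,
        totalObservation = max(a@totalObservation, b@totalObservation))
}

setMethod("show", "StimulusProfile", function(object) {
    cat("StimulusProfile:", object@ligand, "(", object@chamberMode, ")\n")
    n <- nrow(object@segments)
    cat("  ", n, "segment(s), area", stimulusArea(object), "ng s/ml,",
        "observed", object@totalObservation, "min\n")
    if (n > 0 && n <= 6)
        for (i in seq_len(n))
            cat(sprintf("   [%g, %g) s @ %g ng/ml\n", object@segments[i, 1],
                        object@segments[i, 2], object@segments[i, 3]))
})

#' Serialize / deserialize stimulus profiles
#'
#' Profiles round-trip through a small config block:
#' `{ligand, mode, total_observation_min, segments: [[t0, t1, conc], ...]}`
#' written as YAML (or JSON, which YAML parses).
#'
#' @param profile a [StimulusProfile-class].
#' @param path file path.
#' @return `writeStimulusProfile` returns `path` invisibly;
#'   `readStimulusProfile` returns a [StimulusProfile-class].
#' @export
writeStimulusProfile <- function(profile, path) {
    seg <- profile@segments
    obj <- list(
        ligand = profile@ligand,
        mode = profile@chamberMode,
        total_observation_min = profile@totalObservation,
        segments = lapply(seq_len(nrow(seg)),
                          function(i) as.numeric(seg[i, ]))
    )
    yaml::write_yaml(obj, path)
    invisible(path)
}

#' @rdname writeStimulusProfile
#' @export
readStimulusProfile <- function(path) {
    obj <- yaml::read_yaml(path)
    segs <- do.call(rbind, lapply(obj$segments, as.numeric))
    if (is.null(segs))
        segs <- matrix(numeric(0), ncol = 3)
    dimnames(segs) <- list(NULL, c("t0", "t1", "conc"))
    new("StimulusProfile", ligand = obj$ligand, segments = segs,
        chamberMode = obj$mode,
        totalObservation = as.numeric(obj$total_observation_min))
}
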