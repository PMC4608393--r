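## Per-cell deterministic simulation. The right-hand side lives in C
## (src/nfkb.c); integration uses deSolve::lsoda with a stiff-capable
## method, rtol 1e-6 / atol 1e-9, and the time axis is split at stimulus
## segment boundaries so sub-minute pulses are never stepped over.

.RTOL <- 1e-6
.ATOL <- 1e-9

#' Cooperative activation rate multiplier (Hill kinetics)
#'
#' `T^n / (K^n + T^n)`: the rate multiplier for IKK phosphorylation by
#' active TRAF6. Cooperativity `n = 4` encodes Myddosome/TRAF6-lattice
#' clustering; `n = 1` reduces to Michaelian saturation (the "no
#' clustering" control and the TNF receptor layer).
#'
#' @param T activity level (>= 0); vectorized.
#' @param n Hill coefficient (>= 1).
#' @param K half-saturation constant (> 0).
#' @return multiplier in `[0, 1)`, monotone in `T`.
#' @examples
#' hillActivation(c(0, 1, 2), n = 4, K = 1)  # 0, 0.5, 16/17
#' @export
hillActivation <- function(T, n, K) {
    if (K <= 0) stop("K must be > 0")
    if (n < 1) stop("n must be >= 1")
    if (any(T < 0)) stop("T must be >= 0")
    T^n / (K^n + T^n)
}

#' Evaluate the model right-hand side
#'
#' Derivatives of all 15 species at one state/time, through the same
#' compiled code the integrator uses. Mainly for testing steady states and
#' conservation structure.
#'
#' @param state named numeric vector of length 15 (see
#'   [initialStateGuess()] for the layout).
#' @param t time in minutes.
#' @param params an `nfkbParameters` list.
#' @param cell a `cellParameters` list.
#' @param sealed logical: apply sealed-chamber ligand depletion.
#' @return named numeric vector of derivatives (per minute).
#' @export
nfkbDerivatives <- function(state, t = 0, params, cell = cellParameters(),
                            sealed = TRUE) {
    out <- .Call(C_nfkb_rhs, as.numeric(state), as.numeric(t),
                 parmVector(params, cell, sealed))
    names(out) <- .STATE_NAMES
    out
}

#' Naive pre-equilibration starting state
#'
#' All NF-kB bound to IkBa in the cytoplasm, IKK neutral, no ligand.
#' @param cell a `cellParameters` list.
#' @return named state vector of length 15.
#' @export
initialStateGuess <- function(cell = cellParameters()) {
    setNames(c(0, 0, 0, 1, 0, 0, 0.01, 0.05, 0.001, 0,
               cell$nfkb_total * 0.01, cell$nfkb_total * 0.98,
               cell$nfkb_total * 0.01, 0.01, 0.05),
             .STATE_NAMES)
}

#' Pre-stimulus resting state
#'
#' Integrates the ligand-free model until the right-hand side norm falls
#' below `tol`. The resting state has a small nuclear NF-kB fraction
#' (< 0.1) with most NF-kB sequestered in the cytoplasmic IkBa complex.
#'
#' @param params an `nfkbParameters` list.
#' @param cell a `cellParameters` list.
#' @param tol residual norm (max |dy|) required for convergence.
#' @param horizon integration horizon per attempt, minutes.
#' @param maxAttempts number of successive horizons before giving up.
#' @return named state vector; attribute `"residual"` carries the final
#'   right-hand side max-norm.
#' @export
equilibrateCell <- function(params, cell = cellParameters(), tol = 1e-8,
                            horizon = 4000, maxAttempts = 4) {
    y <- initialStateGuess(cell)
    for (i in seq_len(maxAttempts)) {
        sol <- deSolve::lsoda(
            y, c(0, horizon), func = "nfkb_derivs", parms =
                parmVector(params, cell, sealed = FALSE),
            dllname = "nfkbswitch", initfunc = "nfkb_initmod",
            rtol = .RTOL / 100, atol = .ATOL, maxsteps = 50000)
        y <- setNames(as.numeric(sol[nrow(sol), -1]), .STATE_NAMES)
        res <- max(abs(nfkbDerivatives(y, 0, params, cell, sealed = FALSE)))
        if (res < tol) {
            attr(y, "residual") <- res
            return(y)
        }
    }
    stop(sprintf("equilibration did not converge: residual %.3g after %d min",
                 res, horizon * maxAttempts))
}

## Integrate one cell over [0, tEnd] minutes against a stimulus profile,
## splitting at segment boundaries. Returns the full species matrix on the
## requested grid.
.integrateCell <- function(params, cell, profile, tGrid, init) {
    sealed <- profile@chamberMode == "sealed"
    segs <- profile@segments
    tEnd <- max(tGrid)
    bounds <- sort(unique(c(0, segs[, 1] / 60, segs[, 2] / 60, tEnd)))
    bounds <- bounds[bounds <= tEnd + 1e-12]
    if (max(bounds) < tEnd) bounds <- c(bounds, tEnd)

    y <- init
    out <- matrix(NA_real_, length(tGrid), length(.STATE_NAMES),
                  dimnames = list(NULL, .STATE_NAMES))
    grid_done <- logical(length(tGrid))

    for (k in seq_len(length(bounds) - 1)) {
        a <- bounds[k]; b <- bounds[k + 1]
        ## nominal concentration on (a, b): reset ligand state at boundary
        conc <- concentrationAt(profile, a * 60 + min(b - a, 1e-6) * 30)
        y["L"] <- conc
        take <- which(!grid_done & tGrid >= a - 1e-12 & tGrid < b - 1e-12)
        times <- sort(unique(c(a, tGrid[take], b)))
        pv <- parmVector(params, cell,
                         sealed = sealed && conc > 0)
        sol <- try(deSolve::lsoda(
            y, times, func = "nfkb_derivs", parms = pv,
            dllname = "nfkbswitch", initfunc = "nfkb_initmod",
            rtol = .RTOL, atol = .ATOL, maxsteps = 20000), silent = TRUE)
        if (inherits(sol, "try-error") || nrow(sol) < length(times))
            stop(sprintf(
                "ODE solver failed for cell '%s' in [%g, %g] min (%s, %s)",
                cell$cell_id, a, b, profile@ligand, profile@chamberMode))
        if (length(take)) {
            idx <- match(round(tGrid[take], 9), round(sol[, 1], 9))
            out[take, ] <- sol[idx, -1, drop = FALSE]
            grid_done[take] <- TRUE
        }
        y <- setNames(as.numeric(sol[nrow(sol), -1]), .STATE_NAMES)
    }
    if (any(tGrid >= bounds[length(bounds)] - 1e-12) && !all(grid_done)) {
        ## last grid point coincides with final boundary
        out[!grid_done, ] <- matrix(rep(y, sum(!grid_done)),
                                    ncol = length(y), byrow = TRUE)
    }
    out
}

#' Simulate a single cell
#'
#' Integrates the per-cell ODE model from its equilibrated resting state
#' against a stimulus profile and returns the trajectory of the nuclear
#' NF-kB fraction (proportion of the cell's total NF-kB in the nucleus).
#'
#' @param params an `nfkbParameters` list ([lpsModel()] / [tnfModel()]).
#' @param cell a `cellParameters` list.
#' @param profile a [StimulusProfile-class].
#' @param tGrid output grid in minutes, starting at 0 (stimulation onset);
#'   default 1-min resolution over the profile's observation window.
#' @param init optional pre-computed resting state (from
#'   [equilibrateCell()]); computed on the fly when `NULL`.
#' @param fullState if `TRUE`, attach the full species matrix as attribute
#'   `"species"`.
#' @return numeric vector of nuclear fractions on `tGrid`, with attributes
#'   `"time"` and optionally `"species"`.
#' @export
simulateCell <- function(params, cell = cellParameters(), profile,
                         tGrid = NULL, init = NULL, fullState = FALSE) {
    if (is.null(tGrid))
        tGrid <- seq(0, profile@totalObservation, by = 1)
    if (tGrid[1] != 0 || any(diff(tGrid) <= 0))
        stop("tGrid must start at 0 and be strictly increasing")
    if (is.null(init))
        init <- equilibrateCell(params, cell)
    sp <- .integrateCell(params, cell, profile, tGrid, init)
    nf <- nuclearFraction(sp, cell)
    attr(nf, "time") <- tGrid
    if (fullState) attr(nf, "species") <- sp
    nf
}

#' Nuclear NF-kB fraction from a species matrix
#'
#' `(Nn + NIn) / Ntot`: free plus complexed nuclear NF-kB over the cell's
#' total.
#' @param species matrix with columns named as in [initialStateGuess()].
#' @param cell the `cellParameters` the species were simulated with.
#' @return numeric vector in `[0, 1]`.
#' @export
nuclearFraction <- function(species, cell) {
    (species[, "Nn"] + species[, "NIn"]) / cell$nfkb_total
}

#' Total NF-kB along a trajectory (conservation check)
#'
#' @param species full species matrix (see [simulateCell()] with
#'   `fullState = TRUE`).
#' @return numeric vector of `N + Nn + NI + NIn` per time point.
#' @export
totalNfkb <- function(species) {
    species[, "N"] + species[, "Nn"] + species[, "NI"] + species[, "NIn"]
}
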