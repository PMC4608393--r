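## Model parameter handling. The core IKK--IkBa--A20 module is shared
## between the LPS and TNF variants; the upstream receptor layer differs in
## its rate constants and, critically, in the cooperativity of IKK
## activation (hill_n = 4 for LPS via Myddosome/TRAF6 lattice clustering,
## hill_n = 1 for the TNF receptor layer and for the "no clustering"
## control variant).

.PARM_ORDER <- c(
    "kb", "kdb", "kt", "kdt", "aT", "hill_n", "hill_K", "ka", "ki", "kr",
    "aI", "c1", "c3", "c4", "c5", "d_ikba", "kin_i", "kex_i", "a1", "a1n",
    "kin_n", "kex_c", "d_nic", "c6", "c1a", "c3a", "c4a", "c5a",
    "kdep0", "kdep1", "kself"
)

.STATE_NAMES <- c("L", "B", "T", "IKKn", "IKKa", "IKKi", "Im", "I", "In",
                  "N", "Nn", "NI", "NIn", "Am", "A")

#' Model parameter sets
#'
#' `lpsModel()` and `tnfModel()` return the calibrated default rate
#' constants (units: per minute; concentrations in normalized copy-number
#' units with median total NF-kB = 1 and total IKK = TRAF6 = receptor = 1)
#' loaded from the parameter file shipped with the package. Any constant
#' can be overridden through `...`.
#'
#' Upstream layer: `kb` ligand-receptor binding (per ng/ml per min), `kdb`
#' receptor complex turnover, `kt`/`kdt` TRAF6 activation/deactivation,
#' `aT` A20 inhibition of TRAF6, `kself` autocatalytic TRAF6/Myddosome
#' lattice self-assembly (nucleation-growth, gives the all-or-none ignition),
#' `hill_n`/`hill_K` cooperativity and
#' half-saturation of TRAF6 -> IKK activation, `kdep0`/`kdep1`
#' chamber-level and receptor-proportional ligand depletion (sealed mode).
#' Core module: `ka`/`ki`/`kr` IKK cycle, `c1`/`c3`/`c4`/`c5` IkBa
#' transcription/mRNA decay/translation/degradation, `d_ikba`/`d_nic`
#' IKK-mediated degradation of free and complexed IkBa, `kin_*`/`kex_*`
#' nuclear import/export, `a1`/`a1n` NF-kB:IkBa association, `c6` basal
#' complex turnover, `c1a`/`c3a`/`c4a`/`c5a` A20 expression, `aI` A20
#' inhibition of IKK.
#'
#' @param ... named overrides of individual constants.
#' @return a named list of class `nfkbParameters` with entries
#'   `ligand_variant` plus the rate constants.
#' @examples
#' p <- lpsModel()
#' p$hill_n
#' @export
lpsModel <- function(...) .loadModel("LPS", ...)

#' @rdname lpsModel
#' @export
tnfModel <- function(...) .loadModel("TNF", ...)

.loadModel <- function(variant, ...) {
    path <- system.file("extdata",
                        if (variant == "LPS") "lps_default.yaml"
                        else "tnf_default.yaml",
                        package = "nfkbswitch")
    prm <- yaml::read_yaml(path)$rates
    prm <- modifyList(prm, list(...))
    prm$ligand_variant <- variant
    validateParameters(prm)
    class(prm) <- "nfkbParameters"
    prm
}

#' Validate a model parameter set
#'
#' All rates must be present and non-negative; `hill_n >= 1`, `hill_K > 0`.
#'
#' @param params named list of rate constants.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validateParameters <- function(params) {
    missing <- setdiff(.PARM_ORDER, names(params))
    if (length(missing))
        stop("missing rate constants: ", paste(missing, collapse = ", "))
    vals <- unlist(params[.PARM_ORDER])
    if (any(!is.finite(vals)) || any(vals < 0))
        stop("all rate constants must be finite and >= 0")
    if (params$hill_n < 1) stop("hill_n must be >= 1")
    if (params$hill_K <= 0) stop("hill_K must be > 0")
    invisible(TRUE)
}

#' @export
print.nfkbParameters <- function(x, ...) {
    cat("NF-kB model parameters (", x$ligand_variant, " variant), hill_n = ",
        x$hill_n, "\n", sep = "")
    print(round(unlist(x[.PARM_ORDER]), 5))
    invisible(x)
}

## Pack parameters + cell + mode into the flat vector the C code expects.
parmVector <- function(params, cell, sealed) {
    c(unlist(params[.PARM_ORDER], use.names = FALSE),
      cell$tlr4_count, cell$nfkb_total, as.numeric(sealed))
}

#' A single cell's extrinsic-noise parameter draw
#'
#' @param tlr4_count receptor copy-number scale R (relative to the
#'   population median; > 0). Interpreted as TNFR scale under the TNF
#'   variant.
#' @param nfkb_total total NF-kB copy-number scale (median 1; > 0).
#' @param cell_id identifier.
#' @return a list of class `cellParameters`.
#' @export
cellParameters <- function(tlr4_count = 1, nfkb_total = 1,
                           cell_id = "cell_1") {
    if (tlr4_count <= 0 || nfkb_total <= 0)
        stop("copy-number scales must be > 0")
    structure(list(tlr4_count = tlr4_count, nfkb_total = nfkb_total,
                   cell_id = cell_id), class = "cellParameters")
}

#' Population extrinsic-noise configuration
#'
#' Cell-to-cell variability is purely extrinsic: each cell draws its
#' receptor count and total NF-kB from lognormal distributions. `sigma_tlr4`
#' is the lognormal shape of the receptor distribution (the dominant noise
#' source; it sets how graded the population dose-response is), `mu_tlr4`
#' its log-mean (0 means the median cell has the reference receptor count).
#' Defaults are the calibrated values shipped with the package.
#'
#' @param n_cells number of cells (>= 1); the default screen size is 500
#'   independent simulations per condition.
#' @param sigma_tlr4,mu_tlr4 lognormal log-sd / log-mean for the receptor
#'   scale.
#' @param sigma_nfkb,mu_nfkb lognormal log-sd / log-mean for total NF-kB.
#' @param seed integer root seed; populations are bit-reproducible given
#'   the seed.
#' @param ligand `"LPS"` or `"TNF"` (selects the calibrated receptor-noise
#'   default when `sigma_tlr4` is not given).
#' @return a list of class `populationConfig`.
#' @export
populationConfig <- function(n_cells = 500, sigma_tlr4 = NULL, mu_tlr4 = 0,
                             sigma_nfkb = 0.15, mu_nfkb = 0, seed = 1,
                             ligand = "LPS") {
    if (is.null(sigma_tlr4)) {
        def <- .populationDefaults(ligand)
        sigma_tlr4 <- def$sigma_tlr4
    }
    if (n_cells < 1) stop("n_cells must be >= 1")
    if (sigma_tlr4 < 0 || sigma_nfkb < 0) stop("sigmas must be >= 0")
    structure(list(n_cells = as.integer(n_cells), sigma_tlr4 = sigma_tlr4,
                   mu_tlr4 = mu_tlr4, sigma_nfkb = sigma_nfkb,
                   mu_nfkb = mu_nfkb, seed = as.integer(seed)),
              class = "populationConfig")
}

.populationDefaults <- function(ligand = "LPS") {
    path <- system.file("extdata",
                        if (ligand == "LPS") "lps_default.yaml"
                        else "tnf_default.yaml", package = "nfkbswitch")
    yaml::read_yaml(path)$population
}

#' Calibrated activation-classifier defaults
#'
#' The activation call is `max(signal - baseline) >= theta`. `theta` is a
#' calibrated fraction (25%) of the median saturating-response amplitude of
#' the given model variant.
#'
#' @param ligand `"LPS"` or `"TNF"`.
#' @return list with `theta` (signal units) and `smooth_window` (samples).
#' @export
thresholdDefaults <- function(ligand = "LPS") {
    path <- system.file("extdata",
                        if (ligand == "LPS") "lps_default.yaml"
                        else "tnf_default.yaml", package = "nfkbswitch")
    yaml::read_yaml(path)$classifier
}

#' Write a model parameter file
#'
#' Parameter files are YAML with three blocks: `rates` (per-minute rate
#' constants), `population` (calibrated extrinsic-noise defaults) and
#' `classifier` (activation threshold).
#'
#' @param params an `nfkbParameters` list.
#' @param population a `populationConfig` (optional).
#' @param classifier list with `theta`, `smooth_window` (optional).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelParameters <- function(params, path, population = NULL,
                                 classifier = NULL) {
    obj <- list(
        variant = params$ligand_variant,
        units = "rates per minute; concentrations normalized (median total NF-kB = 1); ligand in ng/ml",
        rates = params[.PARM_ORDER]
    )
    if (!is.null(population))
        obj$population <- population[c("sigma_tlr4", "mu_tlr4", "sigma_nfkb",
                                       "mu_nfkb")]
    if (!is.null(classifier)) obj$classifier <- classifier
    yaml::write_yaml(obj, path)
    invisible(path)
}

#' @rdname writeModelParameters
#' @export
readModelParameters <- function(path) {
    obj <- yaml::read_yaml(path)
    prm <- obj$rates
    prm$ligand_variant <- obj$variant %||% "LPS"
    validateParameters(prm)
    class(prm) <- "nfkbParameters"
    prm
}
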