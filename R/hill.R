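#' Hill dose-response fit
#'
#' Least-squares fit of `f = f_max * x^h / (ec50^h + x^h)` to
#' fraction-active data, used for dose-response curves (fraction vs dose)
#' and area-response curves (fraction vs stimulus area). Deterministic
#' given the data: starts are taken from a fixed grid of (h, ec50) values
#' and refined with Levenberg-Marquardt; the best converged fit wins.
#'
#' @param x doses or areas (> 0), length >= 4, spanning low and high
#'   response.
#' @param f observed fractions in `[0, 1]`.
#' @param fixFmax fix the ceiling at this value instead of fitting it
#'   (e.g. 1); `NULL` (default) fits `f_max`.
#' @return list of class `hillFit`: `hill_coefficient`, `ec50`, `f_max`,
#'   `residual_norm`, `extrapolated` (TRUE when the fitted ec50 leaves the
#'   data range by more than 10x), `fit` (the `nls` object).
#' @examples
#' x <- c(0.25, 0.5, 1, 2, 4, 8, 16)
#' f <- x^2.3 / (2^2.3 + x^2.3)
#' fitHill(x, f)$hill_coefficient
#' @export
fitHill <- function(x, f, fixFmax = NULL) {
    if (length(x) < 4 || length(x) != length(f))
        stop("need >= 4 matched (x, f) points")
    if (any(x <= 0)) stop("x must be > 0")
    if (diff(range(f)) < 1e-10)
        stop("degenerate response (all fractions equal); Hill fit undefined")
    df <- data.frame(x = x, f = f)
    hGrid <- c(0.5, 1, 2, 3, 5, 8)
    eGrid <- exp(seq(log(min(x)), log(max(x)), length.out = 5))
    best <- NULL; bestSS <- Inf
    for (h0 in hGrid) for (e0 in eGrid) {
        fit <- tryCatch({
            if (is.null(fixFmax))
                minpack.lm::nlsLM(
                    f ~ fmax * x^h / (ec50^h + x^h), data = df,
                    start = list(h = h0, ec50 = e0,
                                 fmax = max(max(f), 0.1)),
                    lower = c(h = 0.05, ec50 = min(x) * 1e-3, fmax = 1e-3),
                    upper = c(h = 50, ec50 = max(x) * 1e3, fmax = 1.2),
                    control = minpack.lm::nls.lm.control(maxiter = 200))
            else
                minpack.lm::nlsLM(
                    f ~ fixFmax * x^h / (ec50^h + x^h), data = df,
                    start = list(h = h0, ec50 = e0),
                    lower = c(h = 0.05, ec50 = min(x) * 1e-3),
                    upper = c(h = 50, ec50 = max(x) * 1e3),
                    control = minpack.lm::nls.lm.control(maxiter = 200))
        }, error = function(e) NULL)
        if (is.null(fit)) next
        ss <- sum(resid(fit)^2)
        if (ss < bestSS - 1e-12) { bestSS <- ss; best <- fit }
    }
    if (is.null(best)) stop("Hill fit failed from every start")
    cf <- coef(best)
    ec50 <- unname(cf["ec50"])
    structure(list(
        hill_coefficient = unname(cf["h"]),
        ec50 = ec50,
        f_max = if (is.null(fixFmax)) unname(cf["fmax"]) else fixFmax,
        residual_norm = sqrt(bestSS),
        extrapolated = ec50 < min(x) / 10 || ec50 > max(x) * 10,
        domain = range(x),
        fit = best
    ), class = "hillFit")
}

#' @export
print.hillFit <- function(x, ...) {
    cat(sprintf(
        "Hill fit: h = %.3f, ec50 = %.4g, f_max = %.3f (residual %.3g%s)\n",
        x$hill_coefficient, x$ec50, x$f_max, x$residual_norm,
        if (x$extrapolated) ", ec50 extrapolated" else ""))
    invisible(x)
}
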