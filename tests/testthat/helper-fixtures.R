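## Shared fixtures, computed lazily and cached for the whole test run so
## expensive ODE populations are simulated once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixtures))
        assign(name, builder(), envir = .fixtures)
    get(name, envir = .fixtures)
}

## small shared LPS population (30 cells) with pre-computed resting states
lpsPop <- function() fixture("lpsPop", function() {
    params <- lpsModel()
    cfg <- populationConfig(n_cells = 30, seed = 101)
    cells <- samplePopulation(cfg)
    list(params = params, cfg = cfg, cells = cells,
         eq = equilibratePopulation(params, cells))
})

## single median cell with resting state
medCell <- function() fixture("medCell", function() {
    params <- lpsModel()
    cell <- cellParameters()
    list(params = params, cell = cell,
         eq = equilibrateCell(params, cell))
})

## a synthetic damped-oscillation trace on a 1-min grid (no noise)
dampedTrace <- function(delay = 35, amp = 0.5, period = 90, damp = 0.4,
                        width = 12, baseline = 0.05, tmax = 360) {
    tm <- 0:tmax
    sig <- rep(baseline, length(tm))
    for (k in 0:4) {
        x <- (tm - (delay + k * period - width)) / width
        pos <- x > 0
        sig[pos] <- sig[pos] + amp * damp^k *
            exp(-(log(x[pos]))^2 / (2 * 0.45^2))
    }
    list(time = tm, signal = sig)
}
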