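test_that("hillActivation matches its closed form", {
    expect_equal(hillActivation(0, 4, 0.3), 0)
    expect_equal(hillActivation(0.3, 4, 0.3), 0.5)
    ## half-saturation input at half K with n = 4: (1/2)^4 / (1 + (1/2)^4)
    expect_equal(hillActivation(0.15, 4, 0.3), 1 / 17)
    ## n = 1 reduces to Michaelian saturation
    Tv <- c(0.05, 0.2, 0.5, 1.3, 4)
    expect_equal(hillActivation(Tv, 1, 0.7), Tv / (0.7 + Tv))
    expect_error(hillActivation(1, 4, 0), "K must be")
    expect_error(hillActivation(1, 0.5, 1), "n must be")
    expect_error(hillActivation(-1, 4, 1), "T must be")
})

test_that("equilibrated resting state is a fixed point with low nuclear NF-kB", {
    mc <- medCell()
    eq <- mc$eq
    expect_lt(attr(eq, "residual"), 1e-8)
    d <- nfkbDerivatives(eq, 0, mc$params, mc$cell, sealed = FALSE)
    expect_lt(max(abs(d)), 1e-7)
    expect_lt((eq["Nn"] + eq["NIn"]) / mc$cell$nfkb_total, 0.1)

    ## re-integrating 100 min without ligand stays within 1%
    sig <- simulateCell(mc$params, mc$cell,
                        makePulse(0, 1, totalObservation = 100),
                        tGrid = seq(0, 100, 5), init = eq,
                        fullState = TRUE)
    sp <- attr(sig, "species")
    rel <- abs(sweep(sp, 2, as.numeric(eq), "-")) /
        pmax(matrix(rep(as.numeric(eq), each = nrow(sp)), nrow(sp)), 1e-3)
    expect_lt(max(rel), 0.01)
})

test_that("doubling total NF-kB doubles the conserved total at equilibrium", {
    mc <- medCell()
    eq1 <- mc$eq
    eq2 <- equilibrateCell(mc$params, cellParameters(1, 2, "big"))
    tot <- function(y) y["N"] + y["Nn"] + y["NI"] + y["NIn"]
    expect_equal(unname(tot(eq2) / tot(eq1)), 2, tolerance = 1e-6)
})

test_that("NF-kB mass is conserved along trajectories to 1e-6", {
    mc <- medCell()
    for (prof in list(makeSustained(500), makePulse(500, 10),
                      makeSquareWave(500, 10, "start_low", 30))) {
        sig <- simulateCell(mc$params, mc$cell, prof, init = mc$eq,
                            fullState = TRUE)
        tot <- totalNfkb(attr(sig, "species"))
        expect_lt(max(abs(tot - mc$cell$nfkb_total)) / mc$cell$nfkb_total,
                  1e-6)
    }
})

test_that("null stimulus gives a flat baseline; saturating LPS peaks near 35 min", {
    mc <- medCell()
    flat <- simulateCell(mc$params, mc$cell, makePulse(0, 1), init = mc$eq)
    expect_lt(max(flat) - min(flat), 1e-3)

    sig <- simulateCell(mc$params, mc$cell, makeSustained(500),
                        init = mc$eq)
    tm <- attr(sig, "time")
    pk <- tm[which.max(sig)]
    expect_gte(pk, 25)
    expect_lte(pk, 45)
    expect_gt(max(sig) - sig[1], 0.4)  # near-complete translocation
})

test_that("activation probability is monotone in dose at fixed duration", {
    mc <- medCell()
    amps <- vapply(c(5, 20, 80, 500), function(d) {
        s <- simulateCell(mc$params, mc$cell, makePulse(d, 20),
                          tGrid = seq(0, 240, 2), init = mc$eq)
        max(s - s[1])
    }, numeric(1))
    expect_true(all(diff(amps) >= -1e-9))
})

test_that("ligand depletion damps later oscillations relative to perfusion", {
    mc <- medCell()
    grid <- seq(0, 480, 1)
    envAfter <- function(mode) {
        s <- simulateCell(mc$params, mc$cell,
                          makeSustained(5, mode, totalObservation = 480),
                          tGrid = grid, init = mc$eq)
        max(s[grid > 200] - s[1])
    }
    ## perfused keeps a later oscillation peak the sealed chamber loses
    expect_gt(envAfter("perfused"), envAfter("sealed") + 0.05)
})

test_that("cooperative clustering is required for the low-dose response delay", {
    mc <- medCell()
    cellHi <- cellParameters(4, 1, "hiR")
    eq4 <- equilibrateCell(mc$params, cellHi)
    s4 <- simulateCell(mc$params, cellHi, makeSustained(0.5), init = eq4)
    t4 <- attr(s4, "time")[which.max(s4)]

    ## no-clustering control: hill_n = 1, no lattice self-assembly, drive
    ## rescaled so the variant responds at the same dose
    pn <- lpsModel(hill_n = 1, kself = 0, kt = 150)
    eq1 <- equilibrateCell(pn, cellHi)
    s1 <- simulateCell(pn, cellHi, makeSustained(0.5), init = eq1)
    t1 <- attr(s1, "time")[which.max(s1)]

    expect_gt(max(s4 - s4[1]), 0.3)   # both variants respond
    expect_gt(max(s1 - s1[1]), 0.1)
    expect_gt(t4, t1)                  # clustering delays the response
})

test_that("invalid inputs are rejected with informative errors", {
    mc <- medCell()
    expect_error(simulateCell(mc$params, mc$cell, makeSustained(500),
                              tGrid = c(5, 10)), "start at 0")
    expect_error(simulateCell(mc$params, mc$cell, makeSustained(500),
                              tGrid = c(0, 10, 10)), "increasing")
    expect_error(lpsModel(ka = -1), "finite and >= 0")
    expect_error(lpsModel(hill_n = 0.5), "hill_n")
    expect_error(cellParameters(0, 1), "> 0")
})
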