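test_that("responder mixture and flat non-responders are generated as configured", {
    ## p = 0: all flat traces
    flat <- generateDataset(synthConfig(n_cells = 20, responder_fraction = 0,
                                        noise_cv = 0, seed = 3))
    sig <- signalMatrix(flat$trajectories)
    expect_lt(max(apply(sig, 2, function(x) diff(range(x)))), 1e-9)
    expect_true(all(!flat$truth$responder))

    ## noiseless single responder: the analysis recovers the configured delay
    one <- generateDataset(synthConfig(n_cells = 40, responder_fraction = 1,
                                       delay_median = 40, delay_sdlog = 0,
                                       amplitude_sdlog = 0, noise_cv = 0,
                                       seed = 4))
    feats <- trajectoryFeatures(one$trajectories,
                                threshold = list(theta = 0.5,
                                                 smooth_window = 1))
    expect_true(all(feats$active))
    expect_true(all(abs(feats$peak_time - 40) <= 2.5))  # half the 5-min grid
})

test_that("recovered responder fraction lies in the binomial interval", {
    cfg <- synthConfig(n_cells = 500, responder_fraction = 0.5, seed = 11)
    ds <- generateDataset(cfg)
    feats <- trajectoryFeatures(ds$trajectories,
                                threshold = list(theta = 0.5,
                                                 smooth_window = 3))
    rec <- recoveryReport(ds, feats)
    ci <- qbinom(c(0.025, 0.975), 500, 0.5) / 500
    expect_gte(rec$p_recovered, ci[1])
    expect_lte(rec$p_recovered, ci[2])
})

test_that("noiseless datasets give a perfect confusion matrix", {
    ds <- generateDataset(synthConfig(n_cells = 100, responder_fraction = 0.4,
                                      noise_cv = 0, seed = 6))
    feats <- trajectoryFeatures(ds$trajectories,
                                threshold = list(theta = 0.5,
                                                 smooth_window = 1))
    rec <- recoveryReport(ds, feats)
    expect_equal(sum(diag(rec$confusion)), 100)
})

test_that("delay recovery: RMSE within the sampling interval, CV within 15%", {
    delayCVs <- rmses <- numeric(5)
    for (s in 1:5) {
        cfg <- synthConfig(n_cells = 500, responder_fraction = 1,
                           delay_median = 40, delay_sdlog = 0.3,
                           noise_cv = 0.05, seed = 100 + s)
        ds <- generateDataset(cfg)
        feats <- trajectoryFeatures(ds$trajectories,
                                    threshold = list(theta = 0.5,
                                                     smooth_window = 3))
        rec <- recoveryReport(ds, feats)
        rmses[s] <- rec$delay_rmse
        delayCVs[s] <- rec$delay_cv_recovered
    }
    expect_true(all(rmses <= cfg$sampling_interval))
    ## lognormal CV implied by the configured log-sd
    cvTrue <- sqrt(exp(0.3^2) - 1)
    expect_true(all(abs(delayCVs - cvTrue) / cvTrue < 0.15))
})

test_that("fast-uniform vs slow-variable synthetic datasets separate by delay", {
    mkSumm <- function(label, delay_median, delay_sdlog, area, seed) {
        ds <- generateDataset(synthConfig(n_cells = 200,
                                          responder_fraction = 0.5,
                                          delay_median = delay_median,
                                          delay_sdlog = delay_sdlog,
                                          seed = seed))
        feats <- trajectoryFeatures(ds$trajectories,
                                    threshold = list(theta = 0.5,
                                                     smooth_window = 3))
        s <- summarizeCondition(feats)
        data.frame(label = label, area_ng_s_ml = area,
                   median_peak_time_min = s$median_peak_time)
    }
    summ <- rbind(mkSumm("SS", 32, 0.05, 5000, 21),
                  mkSumm("LL", 75, 0.35, 5000, 22))
    rep <- ssLlDiscriminator(summ)
    expect_true(rep$separated)
    expect_gt(rep$min_margin, 20)
})

test_that("synthetic datasets round-trip through CSV + ground-truth JSON", {
    ds <- generateDataset(synthConfig(n_cells = 12, seed = 8))
    dir <- withr::local_tempdir()
    paths <- writeSyntheticDataset(ds, dir)
    ts <- readTrajectories(paths["trajectories"])
    expect_equal(ncol(ts), 12)
    ## ratio reconstruction matches the in-memory trajectories
    expect_equal(unname(signalMatrix(ts)),
                 unname(signalMatrix(ds$trajectories)), tolerance = 1e-12)
    truth <- jsonlite::read_json(paths["truth"])
    expect_equal(length(truth), 12)
    expect_equal(vapply(truth, function(x) isTRUE(x$responder), logical(1)),
                 setNames(ds$truth$responder, ds$truth$cell_id))

    ## id mismatches are an error
    expect_error(recoveryReport(list(truth = ds$truth[1:5, ]),
                                trajectoryFeatures(ds$trajectories,
                                    threshold = list(theta = 0.5,
                                                     smooth_window = 3))),
                 "match")
})
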