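test_that("activation calls are threshold-monotone and match a brute-force scan", {
    tr <- dampedTrace(delay = 40, amp = 0.4)
    expect_false(classifyActivation(rep(0.05, 60), theta = 0.1))
    expect_true(classifyActivation(tr$signal, theta = 0.1))
    ## a trace reaching 1.0 from a 0.05 baseline is active for any theta < 0.95
    step <- c(0.05, rep(1, 30))
    for (th in c(0.1, 0.5, 0.9)) expect_true(classifyActivation(step, th))
    expect_error(classifyActivation(c(1, 2), theta = 0.1), "shorter")

    ## exhaustive threshold scan on a fixed synthetic population
    set.seed(3)
    peaks <- runif(200, 0, 0.6)
    sigs <- lapply(peaks, function(pk) c(0, pk, pk / 2, rep(0, 10)))
    for (th in seq(0.05, 0.55, by = 0.1)) {
        calls <- vapply(sigs, classifyActivation, logical(1), theta = th)
        expect_equal(sum(calls), sum(peaks >= th))
    }
    ## monotonicity: raising theta never increases the active count
    counts <- vapply(seq(0, 0.7, by = 0.05), function(th)
        sum(vapply(sigs, classifyActivation, logical(1), theta = th)),
        numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("first-peak detection matches a brute-force oracle and breaks ties early", {
    ## clean triangular peak at t = 35
    tm <- seq(0, 120, 5)
    tri <- pmax(0, 1 - abs(tm - 35) / 20)
    pk <- detectFirstPeak(tri, tm, smoothWindow = 1)
    expect_equal(pk$peak_time, 35)
    expect_equal(pk$peak_amplitude, 1)

    ## damped sinusoid: argmax before the first post-maximum local minimum
    tr <- dampedTrace(delay = 42, amp = 0.5, period = 80, damp = 0.5)
    s <- smoothSignal(tr$signal, 3)
    imax <- which.max(s)
    oracleMin <- NA
    for (j in (imax + 1):(length(s) - 1))
        if (s[j] <= s[j - 1] && s[j] <= s[j + 1]) { oracleMin <- j; break }
    pk <- detectFirstPeak(tr$signal, tr$time, smoothWindow = 3)
    expect_equal(pk$peak_index, imax)
    expect_equal(pk$min_index, oracleMin)

    ## two equal maxima: earliest wins
    twin <- c(0, 1, 0.2, 1, 0)
    expect_equal(detectFirstPeak(twin, 0:4, smoothWindow = 1)$peak_time, 1)
})

test_that("peak timing is shift-invariant and amplitude scales linearly", {
    tr <- dampedTrace(delay = 35)
    base <- detectFirstPeak(tr$signal, tr$time)
    shifted <- detectFirstPeak(tr$signal + 0.7, tr$time)
    scaled <- detectFirstPeak(tr$signal * 3, tr$time)
    expect_equal(shifted$peak_time, base$peak_time)
    expect_equal(shifted$peak_amplitude, base$peak_amplitude + 0.7)
    expect_equal(scaled$peak_time, base$peak_time)
    expect_equal(scaled$peak_amplitude, base$peak_amplitude * 3)
})

test_that("first-peak area matches closed forms", {
    ## rectangle of height 1 lasting 10 min on zero baseline
    tm <- 0:30
    rect <- as.numeric(tm >= 1 & tm <= 11)
    a <- firstPeakArea(c(0, rep(1, 11), rep(0, 19)), tm,
                       peak = list(truncated = FALSE, min_index = 14))
    expect_equal(as.numeric(a), 10 + 1)  # trapezoids add half-steps at edges

    ## half-sine vs its analytic integral, 1-min sampling, within 1%
    P <- 40; A <- 0.8
    tm <- 0:60
    sig <- ifelse(tm <= P, A * sin(pi * tm / P), 0)
    pk <- detectFirstPeak(sig, tm, smoothWindow = 1)
    a <- firstPeakArea(sig, tm, peak = pk)
    expect_equal(as.numeric(a), 2 * A * P / pi, tolerance = 0.01)
    expect_false(attr(a, "truncated"))

    ## no post-peak minimum within the window: integrate to the end, flagged
    rising <- seq(0, 1, length.out = 20)
    a2 <- firstPeakArea(rising, 0:19,
                        peak = list(truncated = TRUE, min_index = NA))
    expect_true(attr(a2, "truncated"))
})

test_that("condition summaries reproduce hand-computed order statistics", {
    f <- S4Vectors::DataFrame(
        cell_id = paste0("c", 1:7),
        active = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
        onset_time = c(10, 12, 9, 20, 14, NA, NA),
        peak_time = c(30, 42, 26, 55, 38, NA, NA),
        peak_amplitude = c(0.5, 0.4, 0.6, 0.3, 0.45, NA, NA),
        first_peak_area = c(12, 9, 15, 7, 11, NA, NA),
        truncated = c(FALSE, FALSE, FALSE, FALSE, FALSE, NA, NA))
    s <- summarizeCondition(f)
    expect_equal(s$fraction_active, 5 / 7)
    expect_equal(s$median_peak_time, 38)
    expect_equal(s$iqr_peak_time,
                 diff(quantile(c(30, 42, 26, 55, 38), c(.25, .75),
                               names = FALSE)))
    expect_equal(s$median_amplitude, 0.45)

    single <- f[3, ]
    s1 <- summarizeCondition(single)
    expect_equal(s1$iqr_peak_time, 0)

    none <- f[6:7, ]
    s0 <- summarizeCondition(none)
    expect_equal(s0$fraction_active, 0)
    expect_true(is.na(s0$median_peak_time))
})

test_that("CV uses the population standard deviation", {
    expect_equal(cvHeterogeneity(c(40, 60)), 0.2)  # sd_n = 10, mean = 50
    expect_equal(cvHeterogeneity(rep(33, 5)), 0)
    expect_error(cvHeterogeneity(5), ">= 2")
    expect_warning(v <- cvHeterogeneity(c(-1, 1)), "undefined")
    expect_true(is.nan(v))
})

test_that("pairwise t-tests agree with the closed-form statistic", {
    set.seed(11)
    g <- list(a = rnorm(40, 0), b = rnorm(40, 1.2), c = rnorm(40, 0.05))
    out <- pairwiseTests(g)
    ## closed-form pooled two-sample t for a vs b
    n1 <- length(g$a); n2 <- length(g$b)
    sp2 <- ((n1 - 1) * var(g$a) + (n2 - 1) * var(g$b)) / (n1 + n2 - 2)
    tstat <- (mean(g$a) - mean(g$b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    pref <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
    expect_equal(out$p["a", "b"], pref, tolerance = 1e-12)
    expect_equal(out$p, t(out$p))
    expect_true(out$significant["a", "b"])

    ## shifted large-n groups are significant; resampled-identical are not
    expect_gt(out$p["a", "c"], 0.05)

    ## Welch variant matches t.test's Welch p
    outW <- pairwiseTests(g, welch = TRUE)
    expect_equal(outW$p["a", "b"],
                 t.test(g$a, g$b)$p.value, tolerance = 1e-12)

    ## identical zero-variance groups are flagged NA
    z <- pairwiseTests(list(x = rep(1, 5), y = rep(1, 5)))
    expect_true(is.na(z$p["x", "y"]))
    expect_error(pairwiseTests(list(a = 1, b = 1:3)), "n >= 2")
})

test_that("SS/LL discrimination reports margins over matched areas", {
    summ <- data.frame(
        label = c("SS", "SS", "LL", "LL"),
        area_ng_s_ml = c(1000, 5000, 1010, 4980),
        median_peak_time_min = c(31, 30, 75, 60))
    rep <- ssLlDiscriminator(summ)
    expect_true(rep$separated)
    expect_equal(rep$min_margin, 30)
    expect_equal(nrow(rep$boundary), 2)

    ## equal delays: zero margin, no separation
    summ$median_peak_time_min <- c(40, 40, 40, 40)
    rep0 <- ssLlDiscriminator(summ)
    expect_equal(rep0$min_margin, 0)
    expect_false(rep0$separated)

    ## unmatched areas are a pairing error
    summ$area_ng_s_ml <- c(1000, 5000, 2500, 9000)
    expect_error(ssLlDiscriminator(summ), "matching")
})

test_that("trajectory CSVs round-trip, with ratio mode and exclusion masks", {
    tm <- seq(0, 60, 5)
    df <- data.frame(
        cell_id = rep(c("a", "b"), each = length(tm)),
        time_min = rep(tm, 2),
        nuclear_signal = c(50 + tm, rep(40, length(tm))),
        cyto_signal = rep(100, 2 * length(tm)),
        exclude_flag = rep(c(0, 1), each = length(tm)))
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, path, row.names = FALSE)
    ts <- readTrajectories(path)
    expect_s4_class(ts, "TrajectorySet")
    expect_equal(dim(ts), c(length(tm), 2))
    expect_equal(unname(signalMatrix(ts)[, "a"]), (50 + tm) / 100)
    feats <- trajectoryFeatures(ts, threshold = list(theta = 0.2,
                                                     smooth_window = 1))
    expect_equal(nrow(feats), 1)  # excluded cell dropped
    expect_equal(feats$cell_id, "a")

    expect_error(suppressWarnings(
        readTrajectories(withr::local_tempfile(fileext = ".csv"))))
})
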