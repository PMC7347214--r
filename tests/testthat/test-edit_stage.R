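test_that("cell bottom follows the rotor stretch polynomial", {
    cp <- centerpiece(baseBottom = 7.2)
    cal <- rotorCalibration(c(0, 1e-6, 1e-11))
    expect_identical(bottomPosition(cp, cal, 0), 7.2)
    expect_equal(bottomPosition(cp, cal, 50000), 7.2 + 0.05 + 0.025)
    expect_gte(bottomPosition(cp, cal, 60000), bottomPosition(cp, cal, 10000))
})

test_that("volume-derived meniscus matches the integrated sector volume", {
    # oracle: v(r_m) = integral of h (theta pi / 180) r dr from r_m to r_b
    # (in ml; x1000 for ul), solved for r_m by bisection
    oracle <- function(v, h, theta, rb) {
        vol <- function(rm) 1000 * stats::integrate(function(r)
            h * (theta * pi / 180) * r, rm, rb)$value
        lo <- 1e-6; hi <- rb
        for (i in 1:200) {
            mid <- (lo + hi) / 2
            if (vol(mid) > v) lo <- mid else hi <- mid
        }
        (lo + hi) / 2
    }
    expect_equal(meniscusFromVolume(450, 1.2, 2.5, 7.2),
                 oracle(450, 1.2, 2.5, 7.2), tolerance = 1e-6)
    expect_equal(meniscusFromVolume(450, 1.2, 2.5, 7.2), 5.8865,
                 tolerance = 1e-4)
    expect_identical(meniscusFromVolume(0, 1.2, 2.5, 7.2), 7.2)
    expect_error(meniscusFromVolume(1e5, 1.2, 2.5, 7.2), "overfilled")

    # inverse consistency on 100 random geometries
    set.seed(7)
    for (i in 1:100) {
        h <- stats::runif(1, 0.8, 1.5); th <- stats::runif(1, 1, 4)
        rb <- stats::runif(1, 6.8, 7.3)
        vmax <- sectorVolume(5.8, rb, h, th)
        v <- stats::runif(1, 0, 0.95 * vmax)
        rm <- meniscusFromVolume(v, h, th, rb)
        expect_lt(abs(sectorVolume(rm, rb, h, th) - v) / max(v, 1e-9), 1e-9)
    }
})

test_that("meniscus detection finds the simulator spike from late scans", {
    prof <- editProfileFixture()
    exp0 <- simulateExperiment(prof, list("1A" = list(truthSpecies(
        s = 4, k = 1.4, c0 = 0.6))), noiseSpec(seed = 21))
    imp <- importExperiment(exp0)
    tr <- imp@triples[["1A280"]]
    truthMen <- trueMeniscus(exp0)
    det <- detectMeniscus(tr, truthMen + 0.005, window = 0.05)
    expect_lte(abs(as.numeric(det) - truthMen), gridStep(tr) + 1e-12)

    # exactly the last ceiling(0.2 n) scans are used
    n <- ncol(signalValues(tr))
    expect_identical(attr(det, "scansUsed"),
                     seq.int(n - ceiling(0.2 * n) + 1L, n))

    # 10 scans -> scans 9 and 10
    tr10 <- tr
    tr10@values <- tr10@values[, 1:10]
    tr10@scanTime <- tr10@scanTime[1:10]
    tr10@scanRpm <- tr10@scanRpm[1:10]
    tr10@scanOmega2t <- tr10@scanOmega2t[1:10]
    tr10@scanTemperature <- tr10@scanTemperature[1:10]
    expect_identical(attr(detectMeniscus(tr10, truthMen, 0.05), "scansUsed"),
                     9:10)

    # peakless data raises; fallback returns the estimate
    flat <- tripleFixture(matrix(0.1, 201, 5), rMin = 5.8,
                          signalKind = "pseudo_absorbance")
    expect_error(detectMeniscus(flat, 5.9, window = 0.05), "prominent")
    expect_identical(as.numeric(detectMeniscus(flat, 5.9, window = 0.05,
                                               fallback = TRUE)), 5.9)
    expect_error(detectMeniscus(flat, 5.81, window = 0.05), "window")
})

test_that("edit profiles place limits and averaging windows as specified", {
    set.seed(1)
    vals <- matrix(stats::runif(401 * 5, 0.4, 0.6), 401, 5)  # 5.8 - 6.2 cm
    vals[121:140, 5] <- 0.05       # 20 points around left limit, last scan
    tr <- tripleFixture(vals, signalKind = "pseudo_absorbance")
    ed <- computeEditProfile(tr, rightLimit = 6.18, meniscus = 5.900)
    expect_equal(ed@leftLimit, 5.930)                 # 0.03 cm right, snapped
    expect_equal(ed@rightLimit, 6.18)
    expect_length(ed@plateau, 5)
    # baseline window centred at the left limit: indices 121:140 -> 0.05
    expect_equal(ed@baseline, 0.05)
    expect_error(computeEditProfile(tr, rightLimit = 5.95, meniscus = 5.90),
                 "collapsed")
    expect_error(computeEditProfile(tr, rightLimit = 6.2, meniscus = 5.775),
                 "averaging window")
})

test_that("early-scan plateaus track the diluted loading concentration", {
    prof <- editProfileFixture()
    truth <- list("1A" = list(truthSpecies(s = 4, D = 6e-7, c0 = 0.6)))
    exp0 <- simulateExperiment(prof, truth, noiseSpec(0, 0, 0, seed = 1),
                               meniscusSpike = 0)
    imp <- importExperiment(exp0)
    ed <- autoEdit(imp, fallback = TRUE)[["1A280"]]
    ts <- exp0@timestate
    dil <- exp(-2 * 4e-13 * omega2tAt(ts, imp@triples[["1A280"]]@scanTime[1]))
    expect_equal(ed@plateau[1], 0.6 * dil, tolerance = 0.01)
    # late scans never exceed the early plateau (radial dilution)
    expect_lt(ed@plateau[length(ed@plateau)], ed@plateau[1])
})

test_that("an edit profile propagates to all wavelengths of the channel", {
    prof <- editProfileFixture()
    prof@channels[[1]]@wavelengths <- c(280, 260, 230)
    exp0 <- simulateExperiment(prof, list("1A" = list(truthSpecies(
        s = 4, k = 1.4, c0 = 0.6))), noiseSpec(seed = 2),
        referenceIntensity = c("280" = 10000, "260" = 15000, "230" = 8000))
    imp <- importExperiment(exp0)
    edits <- autoEdit(imp)
    expect_length(edits, 3)
    men <- vapply(edits, function(e) e@meniscus, numeric(1))
    expect_identical(unname(men), rep(men[[1]], 3))
    # baselines are per-triple
    expect_identical(names(edits), c("1A280", "1A260", "1A230"))

    # a triple from another channel is rejected
    alien <- imp@triples[["1A280"]]
    alien@channel <- "B"
    expect_error(applyEditToChannel(edits[["1A280"]], alien),
                 "does not belong")
})

test_that("detected meniscus stays within 2 grid steps across seeds and noise", {
    prof <- editProfileFixture()
    errs <- vapply(1:10, function(seed) {
        set.seed(seed)
        truth <- list("1A" = list(truthSpecies(s = stats::runif(1, 3, 6),
                                               k = stats::runif(1, 1.3, 1.8),
                                               c0 = 0.6)))
        sd <- if (seed %% 2 == 0) 0.005 else 0
        exp0 <- simulateExperiment(prof, truth,
                                   noiseSpec(0.02, 0.005, sd, seed = seed))
        imp <- importExperiment(exp0)
        ed <- autoEdit(imp)[["1A280"]]
        abs(ed@meniscus - trueMeniscus(exp0))
    }, numeric(1))
    expect_lt(max(errs), 2 * 0.001 + 1e-12)
})
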