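waterSol <- function() solution()       # water at 20 C, vbar 0.73

test_that("grid-point conversions satisfy the hydrodynamic identities", {
    cst <- physicalConstants()
    p <- speciesFromGridPoint(4.3, 1.25, 0.73, cst$rho20w, cst$eta20w)
    # Svedberg identity s / D = M (1 - vbar rho) / (R T)
    buoy <- 1 - 0.73 * cst$rho20w
    expect_equal((4.3e-13 / p$D), p$M * buoy / (cst$R * cst$T20),
                 tolerance = 1e-10)
    # k = 1 closes the spherical loop: f == f0
    sphere <- speciesFromGridPoint(4.3, 1, 0.73, cst$rho20w, cst$eta20w)
    expect_equal(sphere$f, sphere$f0, tolerance = 1e-12)
    r0 <- (3 * sphere$M * 0.73 / (4 * pi * cst$NA.))^(1 / 3)
    expect_equal(sphere$f0, 6 * pi * cst$eta20w * r0, tolerance = 1e-12)

    # independent fixed-point oracle for M
    oracle <- function(s, k, vbar, rho, eta) {
        M <- 1e5
        for (i in 1:200) {
            f0 <- 6 * pi * eta * (3 * M * vbar / (4 * pi * cst$NA.))^(1 / 3)
            M <- s * 1e-13 * cst$NA. * k * f0 / (1 - vbar * rho)
        }
        M
    }
    expect_equal(p$M, oracle(4.3, 1.25, 0.73, cst$rho20w, cst$eta20w),
                 tolerance = 1e-8)
    expect_error(speciesFromGridPoint(4, 1.2, 1 / 0.99823, 0.99823, 0.01),
                 "neutral buoyancy")
    expect_error(speciesFromGridPoint(4, 0.9, 0.73, 1, 0.01), ">= 1")
})

test_that("standard-condition corrections isolate their factors", {
    cst <- physicalConstants()
    # water at 20 C: identity
    expect_identical(correctS20W(5, 0.73, cst$rho20w, cst$eta20w), 5)
    # viscosity ratio 1.2 with unit buoyancy ratio -> exactly 1.2 s
    expect_equal(correctS20W(5, 0.73, cst$rho20w, 1.2 * cst$eta20w), 6,
                 tolerance = 1e-12)
    # hand-computed product
    fac <- 1.02 * (1 - 0.73 * cst$rho20w) / (1 - 0.73 * 1.005)
    expect_equal(correctS20W(3.7, 0.73, 1.005, 1.02 * cst$eta20w),
                 3.7 * fac, tolerance = 1e-12)
    expect_equal(correctD20W(6e-7, cst$eta20w, 20), 6e-7)
})

test_that("the internal NNLS agrees with the Lawson-Hanson reference", {
    set.seed(33)
    for (i in 1:8) {
        A <- matrix(stats::rnorm(60 * 9), 60, 9)
        b <- as.numeric(A %*% pmax(stats::rnorm(9), 0) + 0.05 * stats::rnorm(60))
        mine <- aucflow:::fnnls(crossprod(A), as.numeric(crossprod(A, b)))
        ref <- pracma::lsqnonneg(A, b)$x
        expect_equal(mine, ref, tolerance = 1e-7)
    }
})

test_that("design columns are non-negative and refinement never hurts the fit", {
    prof <- lightProfileFixture()
    truth <- list("1A" = list(truthSpecies(s = 4, D = 6e-7, c0 = 0.6)))
    exp0 <- simulateExperiment(prof, truth, noiseSpec(0, 0, 0.002, seed = 4),
                               meniscusSpike = 0)
    imp <- importExperiment(exp0)
    tr <- imp@triples[["1A280"]]
    men <- trueMeniscus(exp0)
    ed <- computeEditProfile(tr, 7.15, men)
    radii <- gridPoints(tr)
    sel <- radii >= ed@leftLimit & radii <= ed@rightLimit
    Y <- signalValues(tr)[sel, ]
    rb <- bottomPosition(prof@centerpieces[["1"]], prof@rotorCalibration,
                         50000)

    mkGrid <- function(sVals) {
        g <- data.frame(s = sVals, k = 1.4)
        cst <- physicalConstants()
        hm <- vapply(g$s, function(s) unlist(
            speciesFromGridPoint(s, 1.4, 0.73, cst$rho20w,
                                 cst$eta20w)[c("D", "M")]),
            numeric(2))
        g$D <- hm[1, ]; g$M <- hm[2, ]
        g
    }
    sCoarse <- 10^seq(0, 1, length.out = 8)
    sFine <- 10^seq(0, 1, length.out = 15)    # superset of the coarse grid
    Xc <- buildDesignMatrix(mkGrid(sCoarse), radii[sel], tr@scanTime, men,
                            rb, prof@speedSteps, solverStep = 0.005)
    Xf <- buildDesignMatrix(mkGrid(sFine), radii[sel], tr@scanTime, men,
                            rb, prof@speedSteps, solverStep = 0.005)
    expect_gt(min(Xc), -1e-8)
    fc <- fitNNLS(Y, Xc, fitTI = FALSE, fitRI = FALSE)
    ff <- fitNNLS(Y, Xf, fitTI = FALSE, fitRI = FALSE)
    expect_lte(rmsd(ff), rmsd(fc) + 1e-12)

    # adding TI/RI fitting never increases the RMSD on the same data/grid
    fTI <- fitNNLS(Y, Xc, fitTI = TRUE, fitRI = FALSE)
    fTIRI <- fitNNLS(Y, Xc, fitTI = TRUE, fitRI = TRUE)
    expect_lte(rmsd(fTI), rmsd(fc) + 1e-12)
    expect_lte(rmsd(fTIRI), rmsd(fTI) + 1e-12)

    expect_error(buildDesignMatrix(mkGrid(sCoarse), radii[sel], tr@scanTime,
                                   men + 1, rb, prof@speedSteps), "inside")
})

test_that("a noiseless on-grid species is recovered exactly", {
    prof <- lightProfileFixture()
    truth <- list("1A" = list(truthSpecies(s = 4, D = 6e-7, c0 = 0.6)))
    exp0 <- simulateExperiment(prof, truth, noiseSpec(0, 0, 0, seed = 1),
                               meniscusSpike = 0)
    imp <- importExperiment(exp0)
    tr <- imp@triples[["1A280"]]
    men <- trueMeniscus(exp0)
    rb <- bottomPosition(prof@centerpieces[["1"]], prof@rotorCalibration,
                         50000)
    ed <- computeEditProfile(tr, 7.15, men)
    radii <- gridPoints(tr)
    sel <- radii >= ed@leftLimit & radii <= ed@rightLimit
    Y <- signalValues(tr)[sel, ]

    grid <- data.frame(s = c(2, 4, 6), k = 1.4,
                       D = c(4e-7, 6e-7, 8e-7), M = NA)
    X <- buildDesignMatrix(grid, radii[sel], tr@scanTime, men, rb,
                           prof@speedSteps, solverStep = prof@radialStep)
    m <- fitNNLS(Y, X, fitTI = FALSE, fitRI = FALSE)
    sp <- speciesTable(m)
    expect_equal(sp$concentration[sp$s == 4], 0.6, tolerance = 1e-6)
    expect_lt(sum(sp$concentration[sp$s != 4]), 1e-8)
    expect_lt(rmsd(m), 1e-7)

    # a single-column design at the truth reproduces the data up to loading
    X1 <- buildDesignMatrix(grid[2, ], radii[sel], tr@scanTime, men, rb,
                            prof@speedSteps, solverStep = prof@radialStep)
    expect_equal(as.numeric(X1) * 0.6, as.numeric(Y), tolerance = 1e-9)

    # all-zero data give the zero model
    m0 <- fitNNLS(Y * 0, X, fitTI = FALSE, fitRI = FALSE)
    expect_identical(nrow(speciesTable(m0)), 0L)
    expect_identical(rmsd(m0), 0)
})

test_that("fitted TI noise recovers the injected baseline", {
    prof <- lightProfileFixture()
    truth <- list("1A" = list(truthSpecies(s = 4, D = 6e-7, c0 = 0.6)))
    noisy <- simulateExperiment(prof, truth, noiseSpec(0.02, 0, 0, seed = 9),
                                meniscusSpike = 0)
    clean <- simulateExperiment(prof, truth, noiseSpec(0, 0, 0, seed = 9),
                                meniscusSpike = 0)
    impN <- importExperiment(noisy); impC <- importExperiment(clean)
    tr <- impN@triples[["1A280"]]
    men <- trueMeniscus(noisy)
    rb <- bottomPosition(prof@centerpieces[["1"]], prof@rotorCalibration,
                         50000)
    ed <- computeEditProfile(tr, 7.15, men)
    radii <- gridPoints(tr)
    sel <- radii >= ed@leftLimit & radii <= ed@rightLimit
    beta <- (signalValues(impN@triples[["1A280"]]) -
             signalValues(impC@triples[["1A280"]]))[sel, 1]
    grid <- data.frame(s = c(2, 4, 6), k = 1.4,
                       D = c(4e-7, 6e-7, 8e-7), M = NA)
    X <- buildDesignMatrix(grid, radii[sel], tr@scanTime, men, rb,
                           prof@speedSteps, solverStep = prof@radialStep)
    m <- fitNNLS(signalValues(tr)[sel, ], X, fitTI = TRUE, fitRI = FALSE)
    d <- tiNoise(m) - beta
    expect_lt(stats::sd(d), 0.05 * stats::sd(beta))
})

test_that("without noise fitting the RMSD reports the stochastic noise level", {
    prof <- lightProfileFixture()
    truth <- list("1A" = list(truthSpecies(s = 4, D = 6e-7, c0 = 0)))
    exp0 <- simulateExperiment(prof, truth, noiseSpec(0, 0, 0.003, seed = 17),
                               meniscusSpike = 0)
    imp <- importExperiment(exp0)
    tr <- imp@triples[["1A280"]]
    radii <- gridPoints(tr)
    sel <- radii >= 6.0 & radii <= 7.1
    grid <- data.frame(s = 4, k = 1.4, D = 6e-7, M = NA)
    rb <- bottomPosition(prof@centerpieces[["1"]], prof@rotorCalibration,
                         50000)
    X <- buildDesignMatrix(grid, radii[sel], tr@scanTime, 5.98, rb,
                           prof@speedSteps, solverStep = 0.005)
    m <- fitNNLS(signalValues(tr)[sel, ], X, fitTI = FALSE, fitRI = FALSE)
    expect_equal(rmsd(m), 0.003, tolerance = 0.1)
})

test_that("meniscus refinement recovers the truth and breaks ties leftward", {
    prof <- lightProfileFixture()
    truth <- list("1A" = list(truthSpecies(s = 4, D = 6e-7, c0 = 0.6)))
    exp0 <- simulateExperiment(prof, truth, noiseSpec(0, 0, 0.001, seed = 13),
                               meniscusSpike = 0)
    imp <- importExperiment(exp0)
    tr <- imp@triples[["1A280"]]
    men <- trueMeniscus(exp0)
    rb <- bottomPosition(prof@centerpieces[["1"]], prof@rotorCalibration,
                         50000)
    ed <- computeEditProfile(tr, 7.15, men)
    radii <- gridPoints(tr)
    sel <- radii >= ed@leftLimit & radii <= ed@rightLimit
    wf <- lightWorkflow()
    mf <- fitMeniscus(signalValues(tr)[sel, ], radii[sel], tr@scanTime, men,
                      rb, prof@speedSteps, wf, waterSol())
    spacing <- 2 * wf@meniscusSpan / (wf@meniscusPoints - 1)
    expect_lt(abs(mf$meniscus - men), spacing)
    expect_false(mf$edgeWarning)

    # flat zero data: every candidate ties; lowest radius wins
    mfFlat <- suppressWarnings(fitMeniscus(
        signalValues(tr)[sel, ] * 0, radii[sel], tr@scanTime, men, rb,
        prof@speedSteps, wf, waterSol()))
    expect_equal(mfFlat$meniscus, men - wf@meniscusSpan)
})

test_that("workflow stages run in order and are gated by their flags", {
    prof <- lightProfileFixture(monteCarlo = 2L)
    truth <- list("1A" = list(truthSpecies(s = 4, k = 1.4, c0 = 0.6)))
    exp0 <- simulateExperiment(prof, truth, noiseSpec(0.01, 0.003, 0.002,
                                                      seed = 8))
    imp <- importExperiment(exp0)
    ed <- autoEdit(imp)[["1A280"]]
    tr <- imp@triples[["1A280"]]

    res <- runWorkflow(tr, ed, prof, mcSeed = 2)
    expect_identical(res$stages, c("2DSA-TI", "meniscus-fit-TI+RI",
                                   "iterative", "Monte Carlo"))
    mc <- res$models[[4]]
    expect_identical(mc@stage, "Monte Carlo")
    expect_true(all(mc@mcStats$sd[mc@mcStats$statistic %in%
                                  c("s", "conc")] > 0))

    # Monte Carlo off: three stages
    prof2 <- prof; prof2@workflow@monteCarlo <- 0L
    res3 <- runWorkflow(tr, ed, prof2)
    expect_identical(res3$stages, c("2DSA-TI", "meniscus-fit-TI+RI",
                                    "iterative"))
    # meniscus and iteration off as well: a single stage
    prof1 <- prof2
    prof1@workflow@fitMeniscus <- FALSE
    prof1@workflow@maxIterations <- 0L
    expect_identical(runWorkflow(tr, ed, prof1)$stages, "2DSA-TI")

    # models persist to the store when requested
    store <- aucStore(withr::local_tempdir())
    runWorkflow(tr, ed, prof1, store = store, runName = "wfrun")
    expect_true(file.exists(file.path(store@path, "experiments", "wfrun",
                                      "models", "1A280-01.json")))
    back <- loadModel(store, "wfrun", "1A280-01")
    expect_identical(back@stage, "2DSA-TI")
})
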