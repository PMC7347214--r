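test_that("binary store round trip preserves signal values bit-exactly", {
    store <- aucStore(withr::local_tempdir())
    set.seed(42)
    vals <- matrix(stats::rnorm(101 * 3), 101, 3)
    vals[1, 1] <- 0.1234567890123456    # full double-precision payload
    tr <- tripleFixture(vals)
    storeTriple(store, "exp1", tr)
    back <- loadTriple(store, "exp1", 1, "A", 280)
    expect_identical(signalValues(back), signalValues(tr))
    expect_equal(max(abs(signalValues(back) - signalValues(tr))), 0)
    expect_identical(signalValues(back)[1, 1], 0.1234567890123456)
    expect_equal(gridPoints(back), gridPoints(tr))
    expect_equal(scanTable(back), scanTable(tr))
    expect_identical(signalKind(back), "intensity")
})

test_that("triple keys are unique per experiment and case-insensitive", {
    store <- aucStore(withr::local_tempdir())
    tr <- tripleFixture(matrix(1, 11, 2))
    storeTriple(store, "exp1", tr)
    dup <- tripleFixture(matrix(2, 11, 2), channel = "a")
    expect_error(storeTriple(store, "exp1", dup), "duplicate")
    # same key in a different experiment is fine
    expect_silent(storeTriple(store, "exp2", dup))
    expect_error(loadTriple(store, "exp1", 2, "B", 280), "not found")
    expect_identical(listTriples(store, "exp1"), "1A280")
})

test_that("legacy ASCII scans parse, round trip, and report bad lines", {
    f <- withr::local_tempfile(fileext = ".ra1")
    writeLines(c("Velocity scan, cell 1",
                 "I 1 20.0 50000 4980 1.2345678E+10 280",
                 "6.0000 0.12345",
                 "6.0010 0.23456",
                 "6.0020 0.34567"), f)
    sc <- readLegacyScan(f)
    expect_length(sc@values, 3)
    expect_equal(sc@rpm, 50000)
    expect_equal(sc@time, 4980)
    expect_equal(sc@omega2t, 1.2345678e10)
    expect_equal(sc@wavelength, 280)
    expect_equal(sc@radii, c(6.0, 6.001, 6.002))

    # write/read round trip reproduces numeric content to printed precision
    f2 <- withr::local_tempfile(fileext = ".ra1")
    writeLegacyScan(sc, f2, description = "round trip")
    sc2 <- readLegacyScan(f2)
    expect_equal(sc2@radii, sc@radii, tolerance = 1e-4)
    expect_equal(sc2@values, sc@values, tolerance = 1e-5)
    expect_equal(sc2@omega2t, sc@omega2t, tolerance = 1e-7)

    # a non-numeric value names the offending line
    writeLines(c("desc", "I 1 20.0 50000 10 1e9 280",
                 "6.0000 0.1", "6.0010 abc"), f)
    expect_error(readLegacyScan(f), "line 4")
    # truncated header
    writeLines(c("desc only"), f)
    expect_error(readLegacyScan(f), "truncated")
    # non-monotone radii
    writeLines(c("desc", "I 1 20.0 50000 10 1e9 280",
                 "6.0010 0.1", "6.0000 0.2"), f)
    expect_error(readLegacyScan(f), "increasing")
})

test_that("profile validation reports missing fields and duplicate run names", {
    prof <- lightProfileFixture("val-run")
    expect_identical(validateProfile(prof), character(0))

    broken <- prof
    broken@channels <- list(channelSpec(cell = 2L, channel = "A",
                                        loadingVolume = 1,
                                        wavelengths = numeric(0)))
    v <- validateProfile(broken)
    expect_true(any(grepl("2A", v)))

    # monotone: supplying the missing field never adds violations
    fixed <- broken
    fixed@channels[[1]]@wavelengths <- 280
    expect_lt(length(validateProfile(fixed)), length(v))

    store <- aucStore(withr::local_tempdir(), userLevel = "designer")
    storeProfile(store, freezeProfile(lightProfileFixture("taken")))
    dup <- lightProfileFixture("taken")
    expect_true(any(grepl("duplicate run name", validateProfile(dup, store))))
    expect_false(any(grepl("duplicate", validateProfile(prof, store))))
})

test_that("frozen profiles are immutable; derived changes get a new GUID", {
    prof <- freezeProfile(lightProfileFixture("frozen-run"))
    expect_true(prof@readOnly)
    expect_true(nzchar(prof@guid))
    expect_error(profileField(prof, "temperature") <- 25, "permission denied")

    # store-level immutability at any user level
    store <- aucStore(withr::local_tempdir(), userLevel = "designer")
    storeProfile(store, prof)
    expect_error(storeProfile(store, prof), "frozen")
    op <- aucStore(store@path, userLevel = "operator")
    expect_error(storeProfile(op, freezeProfile(lightProfileFixture("x2"))),
                 "designer")

    # derived change: new guid, new run name required
    m <- mutateFrozen(prof, list(temperature = 22), newRunName = "frozen-run-2")
    expect_false(identical(m@guid, prof@guid))
    expect_identical(m@runName, "frozen-run-2")
    expect_error(mutateFrozen(prof, list(), newRunName = "frozen-run"),
                 "new run name")
    # a content-identical derivation still gets a distinct guid
    m2 <- mutateFrozen(prof, list(), newRunName = "frozen-run-3")
    expect_false(identical(m2@guid, prof@guid))

    # frozen profile content never changes across store round trips
    back <- loadProfile(store, prof@guid)
    expect_equal(aucflow:::profileToList(back), aucflow:::profileToList(prof))
})

test_that("experiment deletion cascades and is admin-gated", {
    store <- aucStore(withr::local_tempdir())
    storeTriple(store, "expd", tripleFixture(matrix(1, 11, 2)))
    expect_error(deleteExperiment(store, "expd"), "admin")
    adm <- aucStore(store@path, userLevel = "admin")
    deleteExperiment(adm, "expd")
    expect_length(listTriples(store, "expd"), 0)
})

test_that("class validity catches malformed objects", {
    expect_error(radialGrid(7, 6), "rMin < rMax")
    g <- radialGrid(6, 6.01, 0.001)
    expect_error(tripleData(1, "A", 280, g, matrix(1, 5, 2),
                            scanTime = c(10, 20), scanRpm = c(1, 1),
                            scanOmega2t = c(1, 2)),
                 "values rows")
    expect_error(tripleData(1, "A", 280, g, matrix(1, 11, 2),
                            scanTime = c(20, 10), scanRpm = c(1, 1),
                            scanOmega2t = c(1, 2)),
                 "strictly increasing")
    expect_error(rotorCalibration(c(0.1, 1e-6, 0)), "stretch")
    expect_error(speedStep(initialDelay = 10), "acceleration time")
    expect_error(new("EditProfile", cell = 1L, channel = "A",
                     wavelength = 280, meniscus = 6, leftLimit = 6.05,
                     rightLimit = 7, baseline = 0, plateau = 0.5,
                     gridStep = 0.001),
                 "0.03")
})
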