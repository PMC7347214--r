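# Metric-set builder for threshold tests (no simulation needed).
metricFixture <- function(volume = 450, conc = 0.55, duration = 3800,
                          rpm = 50000, scans = 40, column = 1.3,
                          rmsd = 0.003, fractions = c(0, 100, 0, 0)) {
    new("MetricSet",
        values = c(loading_volume = volume, loading_concentration = conc,
                   duration = duration, rotor_speed = rpm,
                   scan_count = scans, column_length = column, rmsd = rmsd),
        wavelengths = 280,
        speciesTable = data.frame(sMin = c(0, 2, 5, 10),
                                  sMax = c(2, 5, 10, Inf),
                                  fraction = fractions),
        sBins = c(0, 2, 5, 10, Inf))
}

test_that("self-comparison always passes regardless of tolerances", {
    m <- metricFixture()
    rec <- compareToReference(m, m)
    expect_identical(reportGrade(rec), "Pass")
    expect_true(all(rec@entries$deviation == 0))
    tight <- lapply(defaultTolerances(), function(x) 0)
    expect_identical(reportGrade(compareToReference(m, m, tight)), "Pass")
})

test_that("deviations beyond tolerance flag the entry and fail the grade", {
    # 460 vs 450 is 2.22% against a 2% volume tolerance
    rec <- compareToReference(metricFixture(volume = 460),
                              metricFixture(volume = 450))
    expect_identical(reportGrade(rec), "Fail")
    flagged <- rec@entries$name[rec@entries$flagged]
    expect_identical(flagged, "loading_volume")
    expect_equal(rec@entries$deviation[rec@entries$name == "loading_volume"],
                 100 * 10 / 450, tolerance = 1e-12)
    # species fractions compare in absolute percentage points
    recF <- compareToReference(metricFixture(fractions = c(0, 94, 6, 0)),
                               metricFixture(fractions = c(0, 100, 0, 0)))
    expect_identical(reportGrade(recF), "Fail")
    expect_identical(sum(recF@entries$flagged), 2L)
})

test_that("grades are monotone in the tolerances", {
    set.seed(55)
    for (i in 1:20) {
        m <- metricFixture(volume = 450 * (1 + stats::rnorm(1, 0, 0.02)),
                           conc = 0.55 * (1 + stats::rnorm(1, 0, 0.03)),
                           rmsd = 0.003 * (1 + stats::rnorm(1, 0, 0.1)))
        ref <- metricFixture()
        tol <- defaultTolerances()
        g1 <- reportGrade(compareToReference(m, ref, tol))
        tol2 <- lapply(tol, function(x) x * 2 + 1)
        g2 <- reportGrade(compareToReference(m, ref, tol2))
        if (g1 == "Pass") expect_identical(g2, "Pass")
    }
})

test_that("as-is reports list values without grading", {
    rec <- compareToReference(metricFixture(), NULL)
    expect_identical(reportGrade(rec), "AsIs")
    expect_false(any(rec@entries$flagged))
    doc <- renderReport(rec)
    expect_false(any(grepl("Pass|Fail", doc$text)))
    expect_true(any(grepl("as-is", doc$text)))
})

test_that("rendering is deterministic and lists exactly the failing metrics", {
    rec <- compareToReference(metricFixture(volume = 460, rmsd = 0.03),
                              metricFixture())
    d1 <- renderReport(rec); d2 <- renderReport(rec)
    expect_identical(d1$text, d2$text)
    flagSec <- d1$text[grep("^  - ", d1$text)]
    expect_length(flagSec, sum(rec@entries$flagged))
    expect_true(any(grepl("loading_volume", flagSec)))
    expect_true(any(grepl("rmsd", flagSec)))

    store <- aucStore(withr::local_tempdir())
    storeReport(store, "reprun", rec)
    expect_true(file.exists(file.path(store@path, "experiments", "reprun",
                                      "reports", "report.txt")))
})

test_that("wavelength sets must agree when a reference is present", {
    m <- metricFixture(); m@wavelengths <- c(280, 260)
    rec <- compareToReference(m, metricFixture())
    expect_identical(reportGrade(rec), "Fail")
    expect_true("wavelength_set" %in% rec@entries$name[rec@entries$flagged])
})

test_that("metric extraction reports counts, geometry and fractions", {
    prof <- lightProfileFixture(monteCarlo = 0L)
    truth <- list("1A" = list(truthSpecies(s = 4, k = 1.4, c0 = 0.6)))
    exp0 <- simulateExperiment(prof, truth, noiseSpec(0.01, 0.003, 0.002,
                                                      seed = 12))
    imp <- importExperiment(exp0)
    edits <- autoEdit(imp)
    res <- runWorkflow(imp@triples[["1A280"]], edits[["1A280"]], prof)
    models <- list("1A280" = res$models[[length(res$models)]])
    met <- extractMetrics(imp, edits, models)
    v <- met@values
    expect_identical(unname(v["scan_count"]),
                     as.numeric(ncol(signalValues(imp@triples[["1A280"]]))))
    expect_identical(unname(v["rotor_speed"]), 50000)
    # inferred loading volume within 1% of the 450 ul truth
    expect_lt(abs(v[["loading_volume"]] - 450) / 450, 0.01)
    expect_equal(sum(met@speciesTable$fraction), 100, tolerance = 1e-6)
    # a 4 S species puts its signal in the 2-5 S bin and its neighbour (the
    # coarse test grid straddles the bin edge), none below 2 S
    expect_gt(sum(met@speciesTable$fraction[2:3]), 99)
    expect_lt(met@speciesTable$fraction[1], 1)
    expect_error(extractMetrics(imp, edits, list()), "missing final model")
})
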