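#' Extract the GMP comparison metrics of an analyzed experiment
#'
#' Computes the reportable properties of the primary data and the final
#' fitted model: the loading volume inferred from the detected meniscus
#' (exact sector-volume inverse of the meniscus formula), the loading
#' concentration (plateau of the earliest used scan), experiment duration,
#' rotor speed, scan count, solution column length, fit RMSD, and the
#' distribution of fitted signal over sedimentation-coefficient ranges.
#'
#' @param experiment an [AucExperiment-class] (pseudo-absorbance).
#' @param edits named list of [EditProfile-class] from [autoEdit()].
#' @param models named list: triple key to final [ModelRecord-class].
#' @param sBins sedimentation-coefficient bin edges (svedberg) for the signal
#'   fractions.
#' @param cell,channel channel to report on.
#' @return A [MetricSet-class].
#' @export
extractMetrics <- function(experiment, edits, models, sBins = c(0, 2, 5, 10, Inf),
                           cell = 1L, channel = "A") {
    prof <- experiment@profile
    ch <- channelFor(prof, cell, channel)
    key <- tripleKey(cell * 1.0, channel, ch@wavelengths[1])
    edit <- edits[[key]]
    model <- models[[key]]
    if (is.null(edit)) stop("no edit profile for triple ", key)
    if (is.null(model)) stop("missing final model for triple ", key)
    tr <- experiment@triples[[key]]
    cp <- prof@centerpieces[[as.character(cell)]]
    rpmMax <- max(vapply(prof@speedSteps, function(s) s@setRpm, numeric(1)))
    rb <- bottomPosition(cp, prof@rotorCalibration, rpmMax)

    vol <- sectorVolume(edit@meniscus, rb, cp@pathlength, cp@sectorAngle)
    # loading concentration: earliest-scan plateau, corrected for the fitted
    # time-invariant baseline under the plateau window (otherwise the local
    # radial baseline of each run biases the comparison)
    conc <- edit@plateau[1]
    if (length(tiNoise(model))) {
        radii <- gridPoints(tr)
        fitRadii <- radii[radii >= edit@leftLimit & radii <= edit@rightLimit]
        if (length(tiNoise(model)) == length(fitRadii)) {
            iPl <- snapIndex(fitRadii, edit@rightLimit - 0.03)
            win <- (iPl - 19L):iPl
            win <- win[win >= 1L]
            conc <- conc - mean(tiNoise(model)[win])
        }
    }
    vals <- c(loading_volume = vol,
              loading_concentration = conc,
              duration = max(tr@scanTime),
              rotor_speed = rpmMax,
              scan_count = as.numeric(ncol(signalValues(tr))),
              column_length = rb - edit@meniscus,
              rmsd = rmsd(model))

    sp <- speciesTable(model)
    frac <- numeric(length(sBins) - 1L)
    if (nrow(sp) && sum(sp$concentration) > 0) {
        bin <- findInterval(sp$s, sBins, rightmost.closed = TRUE)
        for (b in seq_along(frac))
            frac[b] <- 100 * sum(sp$concentration[bin == b]) /
                sum(sp$concentration)
    }
    new("MetricSet", values = vals, wavelengths = ch@wavelengths,
        speciesTable = data.frame(sMin = sBins[-length(sBins)],
                                  sMax = sBins[-1], fraction = frac),
        sBins = sBins)
}

#' Default reporting tolerances
#'
#' Percent tolerances per metric; `species_points` is an absolute tolerance in
#' percentage points on the per-bin signal fractions, and metrics with
#' tolerance 0 (scan count, rotor speed) must match exactly. Overridable per
#' profile/report.
#'
#' @return Named list of tolerances.
#' @export
defaultTolerances <- function() list(
    loading_volume = 2, loading_concentration = 5, duration = 1,
    rotor_speed = 0, scan_count = 0, column_length = 2, rmsd = 25,
    species_points = 5)

#' Compare extracted metrics to a reference dataset
#'
#' Percent deviation per metric, `100 |measured - reference| /
#' max(|reference|, 1e-12)`; species-table bins compare in absolute
#' percentage points. A deviation beyond its tolerance flags the entry; the
#' overall grade is Pass iff no toleranced entry is flagged. Without a
#' reference the values are reported as-is (grade `"AsIs"`, nothing flagged).
#'
#' @param metrics a [MetricSet-class].
#' @param reference a [MetricSet-class] from the reference run, or NULL.
#' @param tolerances named list, see [defaultTolerances()].
#' @param runName label recorded in the report.
#' @return A [ReportRecord-class].
#' @export
compareToReference <- function(metrics, reference = NULL,
                               tolerances = defaultTolerances(),
                               runName = "run") {
    nm <- names(metrics@values)
    if (is.null(reference)) {
        entries <- data.frame(name = nm, measured = unname(metrics@values),
                              reference = NA_real_, deviation = NA_real_,
                              tolerance = NA_real_, flagged = FALSE)
        for (b in seq_len(nrow(metrics@speciesTable)))
            entries <- rbind(entries, data.frame(
                name = sprintf("signal_fraction_%g_%gS",
                               metrics@speciesTable$sMin[b],
                               metrics@speciesTable$sMax[b]),
                measured = metrics@speciesTable$fraction[b],
                reference = NA_real_, deviation = NA_real_,
                tolerance = NA_real_, flagged = FALSE))
        return(new("ReportRecord", entries = entries, grade = "AsIs",
                   runName = runName))
    }
    stopifnot(identical(nm, names(reference@values)))
    entries <- do.call(rbind, lapply(nm, function(n) {
        m <- metrics@values[[n]]; r <- reference@values[[n]]
        dev <- 100 * abs(m - r) / max(abs(r), 1e-12)
        tol <- tolerances[[n]] %||% Inf
        data.frame(name = n, measured = m, reference = r, deviation = dev,
                   tolerance = tol, flagged = dev > tol)
    }))
    stopifnot(identical(metrics@sBins, reference@sBins))
    for (b in seq_len(nrow(metrics@speciesTable))) {
        m <- metrics@speciesTable$fraction[b]
        r <- reference@speciesTable$fraction[b]
        tol <- tolerances$species_points %||% Inf
        entries <- rbind(entries, data.frame(
            name = sprintf("signal_fraction_%g_%gS",
                           metrics@speciesTable$sMin[b],
                           metrics@speciesTable$sMax[b]),
            measured = m, reference = r, deviation = abs(m - r),
            tolerance = tol, flagged = abs(m - r) > tol))
    }
    if (!setequal(metrics@wavelengths, reference@wavelengths))
        entries <- rbind(entries, data.frame(
            name = "wavelength_set", measured = NA_real_,
            reference = NA_real_, deviation = 100, tolerance = 0,
            flagged = TRUE))
    grade <- if (any(entries$flagged)) "Fail" else "Pass"
    new("ReportRecord", entries = entries, grade = grade, runName = runName)
}

#' Render a report as a deterministic document
#'
#' Produces a human-readable plain-text document (stable ordering, no
#' timestamps, byte-identical across renderings of the same record) and a
#' machine-readable summary list. Failing records carry a flagged-items
#' section listing exactly the out-of-tolerance metrics; as-is records list
#' values only, with no Pass/Fail line.
#'
#' @param record a [ReportRecord-class].
#' @return List with `text` (character lines) and `summary` (list, JSON-able).
#' @export
renderReport <- function(record) {
    e <- record@entries
    lines <- c(sprintf("GMP analysis report for run '%s'", record@runName),
               strrep("=", 40), "")
    if (record@grade == "AsIs") {
        lines <- c(lines, "No reference dataset supplied; values as-is.", "",
                   sprintf("  %-28s %14.6g", e$name, e$measured))
    } else {
        lines <- c(lines,
                   sprintf("Overall grade: %s", record@grade), "",
                   sprintf("  %-28s %14.6g %14.6g %9.3f%% tol %6.4g%% %s",
                           e$name, e$measured, e$reference, e$deviation,
                           e$tolerance, ifelse(e$flagged, "FLAG", "ok")))
        if (any(e$flagged))
            lines <- c(lines, "", "Flagged items:",
                       sprintf("  - %s (deviation %.3f%% > tolerance %g%%)",
                               e$name[e$flagged], e$deviation[e$flagged],
                               e$tolerance[e$flagged]))
    }
    summary <- list(runName = record@runName, grade = record@grade,
                    entries = e)
    list(text = lines, summary = summary)
}

#' Persist a rendered report
#'
#' @param store an [AucStore-class]; @param runName experiment name.
#' @param record a [ReportRecord-class].
#' @export
storeReport <- function(store, runName, record) {
    d <- file.path(store@path, "experiments", runName, "reports")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    r <- renderReport(record)
    writeLines(r$text, file.path(d, "report.txt"))
    jsonlite::write_json(r$summary, file.path(d, "report.json"),
                         digits = NA, auto_unbox = TRUE)
    invisible(TRUE)
}
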