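## Generics, accessors and show methods.

#' Radii of a grid or dataset
#' @param x a [RadialGrid-class] or [TripleData-class].
#' @return Numeric vector of radii (cm).
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' @rdname gridPoints
#' @export
setMethod("gridPoints", "RadialGrid", function(x) x@points)

#' @rdname gridPoints
#' @export
setMethod("gridPoints", "TripleData", function(x) x@grid@points)

#' Grid step in cm
#' @param x a [RadialGrid-class] or [TripleData-class].
#' @export
setGeneric("gridStep", function(x) standardGeneric("gridStep"))

#' @rdname gridStep
#' @export
setMethod("gridStep", "RadialGrid", function(x) mean(diff(x@points)))

#' @rdname gridStep
#' @export
setMethod("gridStep", "TripleData", function(x) gridStep(x@grid))

#' Signal matrix (radii x scans)
#' @param x a [TripleData-class].
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname signalValues
#' @export
setMethod("signalValues", "TripleData", function(x) x@values)

#' Kind of signal stored in a triple
#' @param x a [TripleData-class].
#' @return `"intensity"` or `"pseudo_absorbance"`.
#' @export
setGeneric("signalKind", function(x) standardGeneric("signalKind"))

#' @rdname signalKind
#' @export
setMethod("signalKind", "TripleData", function(x) x@signalKind)

#' Scan header table
#' @param x a [TripleData-class].
#' @return data.frame with time, rpm, omega2t and temperature per scan.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname scanTable
#' @export
setMethod("scanTable", "TripleData", function(x)
    data.frame(time = x@scanTime, rpm = x@scanRpm,
               omega2t = x@scanOmega2t, temperature = x@scanTemperature))

#' Triple identity key
#'
#' Canonical "cell channel wavelength" key, e.g. `"1A280"`. Channel labels are
#' case-insensitive.
#' @param x a [TripleData-class], or cell/channel/wavelength passed separately.
#' @param channel,wavelength used when `x` is a bare cell number.
#' @export
setGeneric("tripleKey", function(x, channel, wavelength) standardGeneric("tripleKey"))

#' @rdname tripleKey
#' @export
setMethod("tripleKey", "TripleData", function(x, channel, wavelength)
    sprintf("%d%s%g", x@cell, toupper(x@channel), x@wavelength))

#' @rdname tripleKey
#' @export
setMethod("tripleKey", "numeric", function(x, channel, wavelength)
    sprintf("%d%s%g", as.integer(x), toupper(channel), wavelength))

#' Fit RMSD of a model
#' @param x a [ModelRecord-class].
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname rmsd
#' @export
setMethod("rmsd", "ModelRecord", function(x) x@rmsd)

#' Species table of a fitted model
#' @param x a [ModelRecord-class].
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname speciesTable
#' @export
setMethod("speciesTable", "ModelRecord", function(x) x@species)

#' Systematic noise vectors of a fit
#' @param x a [ModelRecord-class].
#' @export
setGeneric("tiNoise", function(x) standardGeneric("tiNoise"))

#' @rdname tiNoise
#' @export
setMethod("tiNoise", "ModelRecord", function(x) x@tiNoise)

#' @rdname tiNoise
#' @export
setGeneric("riNoise", function(x) standardGeneric("riNoise"))

#' @rdname tiNoise
#' @export
setMethod("riNoise", "ModelRecord", function(x) x@riNoise)

#' Autoflow status of a record
#' @param x an [AutoflowRecord-class].
#' @export
setGeneric("flowStatus", function(x) standardGeneric("flowStatus"))

#' @rdname flowStatus
#' @export
setMethod("flowStatus", "AutoflowRecord", function(x) x@status)

#' Overall grade of a report
#' @param x a [ReportRecord-class].
#' @export
setGeneric("reportGrade", function(x) standardGeneric("reportGrade"))

#' @rdname reportGrade
#' @export
setMethod("reportGrade", "ReportRecord", function(x) x@grade)

## ------------------------------- show methods ------------------------------

setMethod("show", "RadialGrid", function(object) {
    p <- object@points
    cat(sprintf("RadialGrid: %d points, %.4f - %.4f cm, step %.4g cm\n",
                length(p), p[1], p[length(p)], gridStep(object)))
})

setMethod("show", "TripleData", function(object) {
    cat(sprintf("TripleData %s (%s): %d radii x %d scans, %.4f - %.4f cm\n",
                tripleKey(object), object@signalKind, nrow(object@values),
                ncol(object@values), min(gridPoints(object)),
                max(gridPoints(object))))
    if (ncol(object@values))
        cat(sprintf("  scans at %.0f - %.0f s, %.0f rpm\n",
                    min(object@scanTime), max(object@scanTime),
                    max(object@scanRpm)))
})

setMethod("show", "TimeState", function(object) {
    r <- object@records
    cat(sprintf("TimeState: %d one-second records", nrow(r)))
    if (nrow(r))
        cat(sprintf(", final omega2t %.4g rad^2/s at %d s",
                    r$omega2t[nrow(r)], r$time[nrow(r)]))
    cat("\n")
})

setMethod("show", "AnalysisProfile", function(object) {
    cat(sprintf("AnalysisProfile '%s'%s\n", object@runName,
                if (object@readOnly) sprintf(" [frozen, guid %s]", object@guid) else ""))
    cat(sprintf("  %d speed step(s), %d channel(s), T = %.1f C\n",
                length(object@speedSteps), length(object@channels),
                object@temperature))
})

setMethod("show", "EditProfile", function(object) {
    cat(sprintf("EditProfile %s: meniscus %.4f cm, range [%.4f, %.4f] cm, baseline %.4g AU, %d plateau value(s)\n",
                tripleKey(object@cell * 1.0, object@channel, object@wavelength),
                object@meniscus, object@leftLimit, object@rightLimit,
                object@baseline, length(object@plateau)))
})

setMethod("show", "ModelRecord", function(object) {
    cat(sprintf("ModelRecord [%s]: %d species, rmsd %.4g AU, meniscus %.4f cm\n",
                object@stage, nrow(object@species), object@rmsd, object@meniscus))
    if (nrow(object@species)) {
        tab <- object@species[order(-object@species$concentration), , drop = FALSE]
        print(utils::head(tab, 5), row.names = FALSE, digits = 4)
    }
})

setMethod("show", "AucExperiment", function(object) {
    cat(sprintf("AucExperiment '%s': %d triple(s), timestate of %d s\n",
                object@runName, length(object@triples),
                nrow(object@timestate@records)))
})

setMethod("show", "AutoflowRecord", function(object) {
    cat(sprintf("AutoflowRecord '%s' on %s: %s%s\n", object@runName,
                object@instrument, object@status,
                if (nzchar(object@lock)) sprintf(" [locked by %s]", object@lock) else ""))
})

setMethod("show", "ReportRecord", function(object) {
    cat(sprintf("ReportRecord '%s': grade %s (%d metric(s), %d flagged)\n",
                object@runName, object@grade, nrow(object@entries),
                sum(object@entries$flagged)))
})

setMethod("show", "VerificationReport", function(object) {
    cat(sprintf("VerificationReport: %s (%d scan(s), %d flagged)\n",
                if (object@pass) "PASS" else "FAIL", nrow(object@perScan),
                sum(!object@perScan$pass)))
})

setMethod("show", "AucStore", function(object) {
    cat(sprintf("AucStore at %s [%s]\n", object@path, object@userLevel))
})
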