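#' Reference intensity from the air region above the meniscus
#'
#' The air gap above the meniscus transmits the full lamp intensity and
#' defines the per-wavelength reference for converting intensity data to
#' pseudo-absorbance. The reference is the mean intensity over the region's
#' grid points across all scans of the triple (all-scan mean for lower
#' variance).
#'
#' @param triple an intensity [TripleData-class].
#' @param region numeric length 2, radial interval in cm; must lie inside the
#'   grid and entirely left of the meniscus. Defaults to
#'   `[estimate - 0.10, estimate - 0.02]` when a meniscus estimate is given.
#' @param meniscusEstimate meniscus estimate (cm) used for the default region.
#' @return Reference intensity (counts) with attribute `region`.
#' @export
selectAirReference <- function(triple, region = NULL, meniscusEstimate = NULL) {
    if (signalKind(triple) != "intensity")
        stop("air reference requires intensity data")
    if (is.null(region)) {
        if (is.null(meniscusEstimate))
            stop("either a region or a meniscus estimate is required")
        region <- c(meniscusEstimate - 0.10, meniscusEstimate - 0.02)
    }
    radii <- gridPoints(triple)
    if (region[1] < radii[1] - 1e-12 || region[2] > radii[length(radii)] + 1e-12)
        stop("air region [", region[1], ", ", region[2],
             "] cm lies outside the radial grid")
    if (!is.null(meniscusEstimate) && region[2] > meniscusEstimate)
        stop("air region must lie entirely left of the meniscus")
    sel <- radii >= region[1] & radii <= region[2]
    if (!any(sel)) stop("air region contains no grid points")
    iRef <- mean(signalValues(triple)[sel, ])
    if (iRef <= 0) stop("non-positive reference intensity in the air region")
    structure(iRef, region = region)
}

#' Convert intensity data to pseudo-absorbance
#'
#' \eqn{A(r,t) = \log_{10}(I_{ref} / I(r,t))} against the per-wavelength air
#' reference. Intensities below \eqn{I_{ref}\,10^{-3.5}} (absorbance beyond
#' the instrument's linear range) are clamped to that floor; the clamp count
#' is returned as an attribute.
#'
#' @param triple an intensity [TripleData-class].
#' @param iRef reference intensity (counts), > 0.
#' @param floorOD absorbance cap in OD (default 3.5).
#' @return A pseudo-absorbance [TripleData-class] with attribute `clamped`
#'   (number of clamped points).
#' @export
toPseudoAbsorbance <- function(triple, iRef, floorOD = 3.5) {
    if (signalKind(triple) != "pseudo_absorbance" &&
        signalKind(triple) != "intensity")
        stop("unknown signal kind")
    if (signalKind(triple) == "pseudo_absorbance")
        stop("triple is already pseudo-absorbance; conversion cannot be applied twice")
    if (iRef <= 0) stop("reference intensity must be > 0")
    I <- signalValues(triple)
    if (any(apply(I, 2, function(col) all(col <= 0))))
        stop("a scan contains no positive intensities")
    floorI <- iRef * 10^(-floorOD)
    clamped <- sum(I < floorI)
    I <- pmax(I, floorI)
    out <- triple
    out@values <- log10(iRef / I)
    out@signalKind <- "pseudo_absorbance"
    validObject(out)
    structure(out, clamped = clamped)
}

#' Import an intensity experiment as pseudo-absorbance
#'
#' GMP import path: for every channel, the air region above the volume-derived
#' meniscus estimate defines the per-wavelength reference intensity and all
#' triples are converted to pseudo-absorbance. Optionally registers the
#' converted triples and the timestate in a store.
#'
#' @param experiment an intensity [AucExperiment-class].
#' @param region optional explicit air region (cm); default derives one per
#'   channel from the loading volume.
#' @param store optional [AucStore-class] to register the converted data.
#' @return The experiment with pseudo-absorbance triples.
#' @export
importExperiment <- function(experiment, region = NULL, store = NULL) {
    prof <- experiment@profile
    rpmMax <- max(vapply(prof@speedSteps, function(s) s@setRpm, numeric(1)))
    out <- experiment
    for (ch in prof@channels) {
        cp <- prof@centerpieces[[as.character(ch@cell)]]
        rb <- bottomPosition(cp, prof@rotorCalibration, rpmMax)
        est <- meniscusFromVolume(ch@loadingVolume, cp@pathlength,
                                  cp@sectorAngle, rb)
        for (wl in ch@wavelengths) {
            key <- tripleKey(ch@cell * 1.0, ch@channel, wl)
            tr <- experiment@triples[[key]]
            if (is.null(tr)) stop("missing triple ", key)
            iRef <- selectAirReference(tr, region = region,
                                       meniscusEstimate = est)
            out@triples[[key]] <- toPseudoAbsorbance(tr, as.numeric(iRef))
        }
    }
    if (!is.null(store)) {
        for (tr in out@triples) storeTriple(store, out@runName, tr)
        storeTimestate(store, out@runName, out@timestate)
    }
    out
}
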