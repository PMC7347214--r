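#' Rotor-stretch corrected cell bottom position
#'
#' The cell bottom moves outward with rotor speed according to the rotor's
#' polynomial stretch calibration: `r_b = r_b0 + stretch(rpm)`.
#'
#' @param centerpiece a [Centerpiece-class].
#' @param calibration a [RotorCalibration-class].
#' @param rpm rotor speed, rev/min in `[0, 60000]`.
#' @return Bottom radius in cm.
#' @export
bottomPosition <- function(centerpiece, calibration, rpm) {
    stopifnot(rpm >= 0, rpm <= 60000)
    cf <- calibration@stretchCoeffs
    centerpiece@baseBottom + cf[1] + cf[2] * rpm + cf[3] * rpm^2
}

#' Meniscus position implied by the loading volume
#'
#' For a sector-shaped centerpiece the air/liquid interface sits at
#' \deqn{r_m = \sqrt{r_b^2 - 0.36\,v / (h\,\theta\,\pi)}}
#' with the loading volume v in microliters, pathlength h in cm and sector
#' angle theta in degrees: the exact inverse of the sector volume
#' \eqn{v = 1000\,h\,(\theta\pi/180)\,(r_b^2 - r_m^2)/2}.
#'
#' @param volume loading volume, microliters (0 gives `bottom`).
#' @param pathlength centerpiece pathlength h, cm.
#' @param sectorAngle sector angle theta, degrees.
#' @param bottom cell bottom r_b, cm.
#' @return Meniscus radius in cm.
#' @examples
#' meniscusFromVolume(450, 1.2, 2.5, 7.2)  # ~5.8865 cm
#' @export
meniscusFromVolume <- function(volume, pathlength, sectorAngle, bottom) {
    stopifnot(volume >= 0, pathlength > 0, sectorAngle > 0)
    radicand <- bottom^2 - 0.36 * volume / (pathlength * sectorAngle * pi)
    if (radicand < 0)
        stop("overfilled channel: loading volume ", volume,
             " ul exceeds the cell capacity")
    sqrt(radicand)
}

#' Sector volume between meniscus and bottom
#'
#' Inverse of [meniscusFromVolume()]: the liquid volume (microliters) held
#' between `meniscus` and `bottom` in a sector-shaped channel.
#'
#' @param meniscus,bottom radii in cm.
#' @param pathlength pathlength h, cm.
#' @param sectorAngle sector angle theta, degrees.
#' @export
sectorVolume <- function(meniscus, bottom, pathlength, sectorAngle)
    1000 * pathlength * (sectorAngle * pi / 180) * (bottom^2 - meniscus^2) / 2

#' Detect the meniscus from the scan stack
#'
#' Searches a window around the volume-derived estimate for the meniscus
#' artifact peak. Only the last ~20 percent of the scans (`ceiling(0.2 n)`,
#' minimum 2) are used -- late scans are depleted near the meniscus, so the
#' artifact stands out against the baseline. Per scan, the radius of the
#' maximum within the window is that scan's meniscus; the returned meniscus is
#' the average over the used scans. A peak counts as prominent when it exceeds
#' the window median by at least `prominence` times the robust (MAD-based)
#' window noise; if a majority of the used scans lack a prominent peak an
#' error is raised (or the estimate is returned when `fallback = TRUE`).
#'
#' @param triple a pseudo-absorbance [TripleData-class].
#' @param estimate volume-derived meniscus estimate, cm.
#' @param window half-width of the search window, cm.
#' @param prominence prominence threshold in robust-noise units.
#' @param fallback return `estimate` instead of raising when no peak is found.
#' @return Meniscus radius in cm, with attribute `perScan` (used scans'
#'   positions).
#' @export
detectMeniscus <- function(triple, estimate, window = 0.05, prominence = 5,
                           fallback = FALSE) {
    if (signalKind(triple) != "pseudo_absorbance")
        stop("meniscus detection expects pseudo-absorbance data")
    radii <- gridPoints(triple)
    if (estimate - window < radii[1] || estimate + window > radii[length(radii)])
        stop("search window extends beyond the radial grid")
    sel <- radii >= estimate - window & radii <= estimate + window
    n <- ncol(signalValues(triple))
    nUse <- max(2L, ceiling(0.2 * n))
    use <- seq.int(n - nUse + 1L, n)

    rs <- radii[sel]
    pos <- numeric(0); ok <- logical(0)
    for (i in use) {
        v <- signalValues(triple)[sel, i]
        med <- stats::median(v)
        noise <- stats::mad(v)
        prom <- if (noise > 0) (max(v) - med) / noise else Inf
        promOk <- is.finite(prom) && prom >= prominence && max(v) > med
        ok <- c(ok, promOk)
        pos <- c(pos, rs[which.max(v)])
    }
    if (sum(ok) <= length(ok) / 2) {
        if (fallback) return(structure(estimate, perScan = numeric(0)))
        stop("no prominent meniscus peak in a majority of the used scans")
    }
    structure(mean(pos[ok]), perScan = pos[ok], scansUsed = use)
}

#' Compute the edit profile of a triple
#'
#' Sets the left data limit 0.03 cm right of the meniscus (snapped to the
#' grid), the right limit from the channel specification, the baseline as the
#' mean of 20 grid points centred at the left limit in the last scan, and the
#' per-scan plateau as the mean of 20 points ending 0.03 cm left of the right
#' limit.
#'
#' @param triple a pseudo-absorbance [TripleData-class].
#' @param rightLimit right data limit in cm (e.g. the channel's
#'   `rightDataLimit`).
#' @param meniscus detected meniscus in cm.
#' @param offset left/right guard offset in cm (0.03).
#' @param points averaging window size in grid samples (20).
#' @return An [EditProfile-class].
#' @export
computeEditProfile <- function(triple, rightLimit, meniscus, offset = 0.03,
                               points = 20L) {
    radii <- gridPoints(triple)
    step <- gridStep(triple)
    if (meniscus + offset >= rightLimit - offset)
        stop("data range collapsed: meniscus + ", offset, " must lie left of ",
             "rightLimit - ", offset)
    iLeft <- snapIndex(radii, meniscus + offset)
    iRight <- snapIndex(radii, rightLimit)
    half <- points %/% 2L
    bIdx <- (iLeft - half):(iLeft + half - 1L)
    iPl <- snapIndex(radii, rightLimit - offset)
    pIdx <- (iPl - points + 1L):iPl
    if (min(bIdx) < 1L || max(bIdx) > length(radii) || min(pIdx) < 1L ||
        max(pIdx) > iRight)
        stop("fewer than ", points, " grid points available in an averaging window")
    vals <- signalValues(triple)
    new("EditProfile", cell = triple@cell, channel = triple@channel,
        wavelength = triple@wavelength, meniscus = meniscus,
        leftLimit = radii[iLeft], rightLimit = radii[iRight],
        baseline = mean(vals[bIdx, ncol(vals)]),
        plateau = colMeans(vals[pIdx, , drop = FALSE]),
        gridStep = step)
}

#' Apply an edit profile to all triples of a channel
#'
#' In a multi-wavelength experiment the meniscus and data range determined on
#' one triple apply to every wavelength of the same cell and channel; the
#' baseline and plateau are recomputed per triple.
#'
#' @param edit an [EditProfile-class].
#' @param triples list of pseudo-absorbance [TripleData-class] sharing the
#'   edit's cell and channel (one may be passed bare).
#' @return Named list of [EditProfile-class], keyed by triple.
#' @export
applyEditToChannel <- function(edit, triples) {
    if (is(triples, "TripleData")) triples <- list(triples)
    ref <- triples[[1]]@grid@points
    out <- list()
    for (tr in triples) {
        if (tr@cell != edit@cell ||
            toupper(tr@channel) != toupper(edit@channel))
            stop(sprintf("triple %s does not belong to channel %d%s",
                         tripleKey(tr), edit@cell, edit@channel))
        if (length(gridPoints(tr)) != length(ref) ||
            max(abs(gridPoints(tr) - ref)) > 1e-9)
            stop("triples must share the radial grid")
        out[[tripleKey(tr)]] <- computeEditProfile(
            tr, edit@rightLimit, edit@meniscus)
    }
    out
}

#' Automated editing of a full experiment
#'
#' Runs the editing chain per channel: volume-derived meniscus estimate
#' (stretch-corrected bottom), peak detection, edit-profile computation, and
#' propagation to every wavelength of the channel.
#'
#' @param experiment an [AucExperiment-class] with pseudo-absorbance triples.
#' @param window,prominence,fallback passed to [detectMeniscus()].
#' @return Named list of [EditProfile-class] keyed by triple.
#' @export
autoEdit <- function(experiment, window = 0.05, prominence = 5,
                     fallback = FALSE) {
    prof <- experiment@profile
    rpmMax <- max(vapply(prof@speedSteps, function(s) s@setRpm, numeric(1)))
    out <- list()
    for (ch in prof@channels) {
        cp <- prof@centerpieces[[as.character(ch@cell)]]
        rb <- bottomPosition(cp, prof@rotorCalibration, rpmMax)
        est <- meniscusFromVolume(ch@loadingVolume, cp@pathlength,
                                  cp@sectorAngle, rb)
        keys <- vapply(ch@wavelengths, function(wl)
            tripleKey(ch@cell * 1.0, ch@channel, wl), character(1))
        trs <- experiment@triples[keys]
        if (any(vapply(trs, is.null, logical(1))))
            stop("experiment is missing triples for channel ",
                 ch@cell, ch@channel)
        men <- detectMeniscus(trs[[1]], est, window = window,
                              prominence = prominence, fallback = fallback)
        edit <- computeEditProfile(trs[[1]], ch@rightDataLimit, as.numeric(men))
        out <- c(out, applyEditToChannel(edit, trs))
    }
    out
}
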