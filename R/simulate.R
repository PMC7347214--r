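#' Simulate a sedimentation-velocity experiment
#'
#' Stands in for the instrument: solves the sedimentation-diffusion equation
#' for the ground-truth species of every channel, places the true meniscus at
#' the volume-derived position (sector geometry, stretch-corrected bottom),
#' and emits intensity triples plus the 1-second timestate. The recorded
#' intensity is
#' \deqn{I(r,t) = I_{ref,\lambda}\,10^{-[A_{true}(r,t) + \beta(r) + \gamma(t)]}
#'   + \epsilon}
#' where \eqn{\beta(r)} is a smooth time-invariant radial baseline (sum of 5
#' random-phase sinusoids scaled to sd `tiAmplitude`), \eqn{\gamma(t)} an
#' i.i.d. radially-invariant per-scan offset (sd `riAmplitude`), and
#' \eqn{\epsilon} detector noise scaled so the induced pseudo-absorbance noise
#' has sd `stochasticSd`. The air region above the meniscus transmits
#' \eqn{I_{ref,\lambda}}; a narrow absorbance spike marks the meniscus
#' (the optical artifact used by the peak detector). Scan times and
#' \eqn{\omega^2 t} headers come from the generated timestate. Fully
#' reproducible given the noise seed: per-triple RNG substreams are derived
#' deterministically from it.
#'
#' @param profile an [AnalysisProfile-class].
#' @param truth named list: channel key (e.g. `"1A"`) to list of
#'   [TruthSpecies-class].
#' @param noise a [NoiseSpec-class].
#' @param referenceIntensity per-wavelength reference counts: a single value
#'   or a named vector keyed by wavelength; all values must be > 0.
#' @param meniscusSpike spike amplitude in AU (0 disables the artifact).
#' @param spikeWidth Gaussian sigma of the spike in cm.
#' @return An [AucExperiment-class] with intensity triples.
#' @export
simulateExperiment <- function(profile, truth, noise = noiseSpec(),
                               referenceIntensity = 10000,
                               meniscusSpike = 0.8, spikeWidth = 0.002) {
    if (any(referenceIntensity <= 0))
        stop("reference intensity must be > 0")
    steps <- profile@speedSteps
    rpmMax <- max(vapply(steps, function(s) s@setRpm, numeric(1)))
    for (st in steps)
        if (st@initialDelay < st@setRpm / st@rampRate)
            stop("initial delay shorter than the rotor acceleration time")

    ts <- generateTimestate(steps, temperature = profile@temperature)
    scanTimes <- profileScanTimes(steps)
    fullGrid <- radialGrid(profile@radialRange[1], profile@radialRange[2],
                           profile@radialStep)
    radii <- gridPoints(fullGrid)

    nTriples <- sum(vapply(profile@channels,
                           function(ch) length(ch@wavelengths), integer(1)))
    set.seed(noise@seed)
    subSeeds <- sample.int(.Machine$integer.max - 1L, nTriples)

    triples <- list()
    idx <- 0L
    for (ch in profile@channels) {
        cp <- profile@centerpieces[[as.character(ch@cell)]]
        rb <- bottomPosition(cp, profile@rotorCalibration, rpmMax)
        men <- snapRadius(radii, meniscusFromVolume(
            ch@loadingVolume, cp@pathlength, cp@sectorAngle, rb))
        spKey <- paste0(ch@cell, toupper(ch@channel))
        species <- truth[[spKey]]
        if (is.null(species))
            stop("no ground-truth species for channel ", spKey)
        if (is(species, "TruthSpecies")) species <- list(species)

        conc <- solveLamm(species, men, rb, steps, scanTimes,
                          gridStep = profile@radialStep,
                          solution = ch@solution,
                          temperature = profile@temperature)
        solRadii <- attr(conc, "radii")
        inCell <- radii >= men - 1e-9 & radii <= rb + 1e-9

        for (wl in ch@wavelengths) {
            idx <- idx + 1L
            set.seed(subSeeds[idx])
            iRef <- if (length(referenceIntensity) > 1L)
                referenceIntensity[[as.character(wl)]]
            else referenceIntensity

            Atrue <- matrix(0, length(radii), length(scanTimes))
            Atrue[inCell, ] <- apply(conc, 2, function(col)
                stats::approx(solRadii, col, xout = radii[inCell])$y)
            if (meniscusSpike > 0)
                Atrue <- Atrue + meniscusSpike *
                    exp(-((radii - men) / spikeWidth)^2)

            beta <- smoothRadialNoise(radii, noise@tiAmplitude)
            gamma <- stats::rnorm(length(scanTimes), 0, noise@riAmplitude)
            I <- iRef * 10^(-(Atrue + beta +
                              rep(gamma, each = length(radii))))
            if (noise@stochasticSd > 0)
                I <- I + stats::rnorm(length(I), 0,
                                      noise@stochasticSd * log(10)) * I

            triples[[tripleKey(ch@cell * 1.0, ch@channel, wl)]] <- tripleData(
                cell = ch@cell, channel = ch@channel, wavelength = wl,
                grid = fullGrid, values = I, scanTime = scanTimes,
                scanRpm = rpmAtTime(steps, scanTimes),
                scanOmega2t = omega2tAt(ts, scanTimes),
                scanTemperature = rep(profile@temperature, length(scanTimes)),
                signalKind = "intensity")
        }
    }
    new("AucExperiment", runName = profile@runName, profile = profile,
        triples = triples, timestate = ts, truth = truth)
}

# Smooth time-invariant radial baseline: 5 random-phase sinusoids over the
# radial range, scaled to the requested standard deviation. Mimics window
# scratches/dust against which the per-scan lamp flicker is i.i.d. Always
# consumes the same RNG draws so experiments differing only in amplitudes
# share the remaining noise stream.
smoothRadialNoise <- function(radii, amplitude) {
    span <- diff(range(radii))
    x <- (radii - radii[1]) / span
    b <- numeric(length(radii))
    for (j in 1:5)
        b <- b + stats::runif(1, 0.5, 1) *
            sin(2 * pi * (stats::runif(1, 0.5, 3) * j * x + stats::runif(1)))
    b <- b - mean(b)
    b * amplitude / stats::sd(b)
}

#' Ground-truth meniscus of a simulated channel
#'
#' Convenience accessor: the grid-snapped meniscus position the simulator used
#' for a channel (volume-derived, stretch-corrected bottom).
#'
#' @param experiment an [AucExperiment-class].
#' @param cell,channel channel identity.
#' @return Meniscus radius in cm.
#' @export
trueMeniscus <- function(experiment, cell = 1L, channel = "A") {
    prof <- experiment@profile
    ch <- channelFor(prof, cell, channel)
    cp <- prof@centerpieces[[as.character(ch@cell)]]
    rpmMax <- max(vapply(prof@speedSteps, function(s) s@setRpm, numeric(1)))
    rb <- bottomPosition(cp, prof@rotorCalibration, rpmMax)
    radii <- gridPoints(radialGrid(prof@radialRange[1], prof@radialRange[2],
                                   prof@radialStep))
    snapRadius(radii, meniscusFromVolume(ch@loadingVolume, cp@pathlength,
                                         cp@sectorAngle, rb))
}
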