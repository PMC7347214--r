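#' @title Core S4 classes for the sedimentation-velocity workflow
#'
#' @description
#' The package models one analytical-ultracentrifugation (AUC) experiment as a
#' set of "triples" (cell / channel / wavelength datasets), each a stack of
#' radial scans, plus a second-by-second rotor timestate. Protocol objects
#' (analysis profiles) are immutable once frozen, mirroring GMP requirements.
#'
#' @name aucflow-classes
#' @keywords internal
NULL

## ---------------------------------------------------------------------------
## Radial grid
## ---------------------------------------------------------------------------

#' Uniform radial measurement grid
#'
#' Ordered radii (cm) at which the detector samples the cell. The grid must be
#' strictly increasing and uniformly spaced (within 1e-9 cm).
#'
#' @slot points numeric, ordered radii in cm.
#' @exportClass RadialGrid
setClass("RadialGrid", representation(points = "numeric"), validity = function(object) {
    p <- object@points
    if (length(p) < 2L) return("grid needs at least 2 points")
    d <- diff(p)
    if (any(d <= 0)) return("radii must be strictly increasing")
    if (max(d) - min(d) > 1e-9) return("grid spacing must be uniform within 1e-9 cm")
    TRUE
})

#' Construct a uniform radial grid
#'
#' @param rMin,rMax radial range in cm (`rMin < rMax`).
#' @param step nominal grid step in cm; the actual step is adjusted so that
#'   `rMax` falls exactly on the grid.
#' @return A [RadialGrid-class] object.
#' @examples
#' g <- radialGrid(5.8, 7.2, 0.001)
#' length(gridPoints(g))
#' @export
radialGrid <- function(rMin, rMax, step = 0.001) {
    stopifnot(rMin < rMax, step > 0)
    n <- max(1L, round((rMax - rMin) / step))
    new("RadialGrid", points = rMin + (0:n) * ((rMax - rMin) / n))
}

## ---------------------------------------------------------------------------
## Scans and triples
## ---------------------------------------------------------------------------

#' A single radial scan
#'
#' One detector sweep over the cell at a fixed time: per-radius signal values
#' (intensity counts or pseudo-absorbance AU) plus the scan header recorded by
#' the instrument (time since run start, cumulative omega^2 t, rotor speed,
#' temperature).
#'
#' @slot radii numeric, radii in cm.
#' @slot values numeric, per-radius signal.
#' @slot time numeric, seconds since run start.
#' @slot omega2t numeric, cumulative integral of omega^2 in rad^2/s.
#' @slot rpm numeric, rotor speed in rev/min.
#' @slot temperature numeric, degrees C.
#' @slot cell integer cell number.
#' @slot wavelength numeric, nm.
#' @exportClass Scan
setClass("Scan", representation(
    radii = "numeric", values = "numeric", time = "numeric",
    omega2t = "numeric", rpm = "numeric", temperature = "numeric",
    cell = "integer", wavelength = "numeric"),
    validity = function(object) {
        if (length(object@values) != length(object@radii))
            return("values length must equal radii length")
        if (any(diff(object@radii) <= 0))
            return("radii must be strictly increasing")
        if (object@omega2t < 0) return("omega2t must be >= 0")
        TRUE
    })

#' One cell/channel/wavelength dataset
#'
#' The unit of AUC data: all scans of one optical channel at one wavelength,
#' sharing a radial grid. `values` is a radii-by-scans matrix; scan headers are
#' stored as parallel vectors.
#'
#' @slot cell integer cell number (>= 1).
#' @slot channel character channel label ("A"/"B").
#' @slot wavelength numeric wavelength in nm.
#' @slot grid a [RadialGrid-class].
#' @slot signalKind `"intensity"` or `"pseudo_absorbance"`.
#' @slot values numeric matrix, radii x scans.
#' @slot scanTime numeric, s since run start, strictly increasing.
#' @slot scanRpm numeric, rev/min per scan.
#' @slot scanOmega2t numeric, cumulative rad^2/s, non-decreasing.
#' @slot scanTemperature numeric, degrees C per scan.
#' @exportClass TripleData
setClass("TripleData", representation(
    cell = "integer", channel = "character", wavelength = "numeric",
    grid = "RadialGrid", signalKind = "character", values = "matrix",
    scanTime = "numeric", scanRpm = "numeric", scanOmega2t = "numeric",
    scanTemperature = "numeric"),
    validity = function(object) {
        ns <- ncol(object@values)
        if (nrow(object@values) != length(object@grid@points))
            return("values rows must match grid length")
        for (nm in c("scanTime", "scanRpm", "scanOmega2t", "scanTemperature"))
            if (length(slot(object, nm)) != ns)
                return(sprintf("%s length must equal scan count", nm))
        if (ns > 1 && any(diff(object@scanTime) <= 0))
            return("scan times must be strictly increasing")
        if (any(object@scanOmega2t < 0) ||
            (ns > 1 && any(diff(object@scanOmega2t) < 0)))
            return("omega2t must be >= 0 and non-decreasing")
        if (object@cell < 1L) return("cell must be >= 1")
        if (!object@signalKind %in% c("intensity", "pseudo_absorbance"))
            return("signalKind must be 'intensity' or 'pseudo_absorbance'")
        TRUE
    })

#' Construct a TripleData object
#'
#' @param cell cell number (>= 1).
#' @param channel channel label, "A" or "B" (case-insensitive).
#' @param wavelength wavelength in nm.
#' @param grid a [RadialGrid-class].
#' @param values radii x scans signal matrix.
#' @param scanTime,scanRpm,scanOmega2t,scanTemperature per-scan headers.
#' @param signalKind `"intensity"` or `"pseudo_absorbance"`.
#' @return A [TripleData-class] object.
#' @export
tripleData <- function(cell, channel, wavelength, grid, values,
                       scanTime, scanRpm, scanOmega2t,
                       scanTemperature = rep(20, length(scanTime)),
                       signalKind = "intensity") {
    new("TripleData", cell = as.integer(cell), channel = toupper(channel),
        wavelength = wavelength, grid = grid,
        values = as.matrix(values), scanTime = as.numeric(scanTime),
        scanRpm = as.numeric(scanRpm), scanOmega2t = as.numeric(scanOmega2t),
        scanTemperature = as.numeric(scanTemperature), signalKind = signalKind)
}

## ---------------------------------------------------------------------------
## Hardware / solution descriptors
## ---------------------------------------------------------------------------

#' Sector-shaped centerpiece geometry
#'
#' @slot sectorAngle numeric, sector angle theta in degrees.
#' @slot pathlength numeric, optical pathlength h in cm.
#' @slot baseBottom numeric, unstretched cell-bottom radius in cm.
#' @slot shape character, currently only `"sector"`.
#' @exportClass Centerpiece
setClass("Centerpiece", representation(
    sectorAngle = "numeric", pathlength = "numeric",
    baseBottom = "numeric", shape = "character"),
    prototype(shape = "sector"),
    validity = function(object) {
        if (object@sectorAngle <= 0) return("sector angle must be > 0")
        if (object@pathlength <= 0) return("pathlength must be > 0")
        if (object@shape != "sector") return("only sector centerpieces supported")
        TRUE
    })

#' @rdname Centerpiece-class
#' @param sectorAngle sector angle in degrees.
#' @param pathlength optical pathlength in cm.
#' @param baseBottom unstretched bottom radius in cm.
#' @export
centerpiece <- function(sectorAngle = 2.5, pathlength = 1.2, baseBottom = 7.2)
    new("Centerpiece", sectorAngle = sectorAngle, pathlength = pathlength,
        baseBottom = baseBottom, shape = "sector")

#' Rotor stretch calibration
#'
#' Polynomial stretch (cm) as a function of rotor speed (rpm), degree <= 2,
#' with zero stretch at rest. The cell bottom moves outward by this amount.
#'
#' @slot stretchCoeffs numeric length 3: intercept (must be 0), linear and
#'   quadratic coefficients in cm/rpm and cm/rpm^2.
#' @exportClass RotorCalibration
setClass("RotorCalibration", representation(stretchCoeffs = "numeric"),
    validity = function(object) {
        cf <- object@stretchCoeffs
        if (length(cf) != 3L) return("stretchCoeffs must have length 3")
        if (cf[1] != 0) return("stretch(0) must be 0")
        rpm <- seq(0, 60000, by = 1000)
        st <- cf[1] + cf[2] * rpm + cf[3] * rpm^2
        if (any(st < -1e-12) || any(diff(st) < -1e-12))
            return("stretch must be non-negative and non-decreasing on [0, 60000] rpm")
        TRUE
    })

#' @rdname RotorCalibration-class
#' @param stretchCoeffs polynomial coefficients `c(0, a1, a2)`.
#' @export
rotorCalibration <- function(stretchCoeffs = c(0, 1e-6, 1e-11))
    new("RotorCalibration", stretchCoeffs = stretchCoeffs)

#' Buffer/analyte solution
#'
#' @slot density numeric, g/ml at run temperature.
#' @slot viscosity numeric, poise at run temperature.
#' @slot analytes data.frame with columns `vbar` (ml/g), `extinction`
#'   (AU ml/(g cm)) and `molarRatio`.
#' @exportClass Solution
setClass("Solution", representation(
    density = "numeric", viscosity = "numeric", analytes = "data.frame"),
    validity = function(object) {
        if (object@density <= 0) return("density must be > 0")
        if (object@viscosity <= 0) return("viscosity must be > 0")
        if (nrow(object@analytes) &&
            (any(object@analytes$vbar <= 0) || any(object@analytes$vbar >= 2)))
            return("vbar must lie in (0, 2) ml/g")
        TRUE
    })

#' @rdname Solution-class
#' @param density buffer density in g/ml.
#' @param viscosity buffer viscosity in poise.
#' @param vbar,extinction,molarRatio per-analyte properties.
#' @export
solution <- function(density = 0.998234, viscosity = 0.010020,
                     vbar = 0.73, extinction = 1, molarRatio = 1)
    new("Solution", density = density, viscosity = viscosity,
        analytes = data.frame(vbar = vbar, extinction = extinction,
                              molarRatio = molarRatio))

#' One rotor speed step
#'
#' @slot setRpm numeric target speed, rev/min in `[0, 60000]`.
#' @slot rampRate numeric acceleration, rpm/s.
#' @slot duration numeric total step duration in s (including the ramp).
#' @slot scanInterval numeric s between scans.
#' @slot initialDelay numeric s from step start to the first scan; must be at
#'   least the rotor acceleration time.
#' @exportClass SpeedStep
setClass("SpeedStep", representation(
    setRpm = "numeric", rampRate = "numeric", duration = "numeric",
    scanInterval = "numeric", initialDelay = "numeric"),
    validity = function(object) {
        if (object@setRpm < 0 || object@setRpm > 60000)
            return("setRpm must lie in [0, 60000]")
        if (object@scanInterval <= 0) return("scanInterval must be > 0")
        if (object@rampRate <= 0) return("rampRate must be > 0")
        TRUE
    })

#' @rdname SpeedStep-class
#' @param setRpm,rampRate,duration,scanInterval,initialDelay see slots.
#' @export
speedStep <- function(setRpm = 50000, rampRate = 400, duration = 6 * 3600,
                      scanInterval = 120, initialDelay = setRpm / rampRate) {
    if (initialDelay < setRpm / rampRate)
        stop("initialDelay (", initialDelay, " s) is shorter than the rotor ",
             "acceleration time (", setRpm / rampRate, " s)")
    new("SpeedStep", setRpm = setRpm, rampRate = rampRate, duration = duration,
        scanInterval = scanInterval, initialDelay = initialDelay)
}

#' Per-channel loading specification
#'
#' @slot cell integer cell number.
#' @slot channel character channel label.
#' @slot solution a [Solution-class].
#' @slot loadingVolume numeric, microliters.
#' @slot volumeTolerance numeric, percent.
#' @slot concentrationRatio numeric, loading ratio vs the reference run
#'   (default 1).
#' @slot ratioTolerance numeric, percent.
#' @slot rightDataLimit numeric, cm; right edge of the analyzed data range.
#' @slot wavelengths numeric, nm.
#' @exportClass ChannelSpec
setClass("ChannelSpec", representation(
    cell = "integer", channel = "character", solution = "Solution",
    loadingVolume = "numeric", volumeTolerance = "numeric",
    concentrationRatio = "numeric", ratioTolerance = "numeric",
    rightDataLimit = "numeric", wavelengths = "numeric"),
    validity = function(object) {
        if (length(object@loadingVolume) && object@loadingVolume <= 0)
            return("loadingVolume must be > 0")
        if (any(c(object@volumeTolerance, object@ratioTolerance) < 0))
            return("tolerances must be >= 0")
        TRUE
    })

#' @rdname ChannelSpec-class
#' @param cell,channel channel identity.
#' @param solution a [Solution-class].
#' @param loadingVolume microliters loaded.
#' @param volumeTolerance,ratioTolerance percent tolerances for reporting.
#' @param concentrationRatio loading ratio vs the reference experiment.
#' @param rightDataLimit right data limit in cm.
#' @param wavelengths wavelengths (nm) scanned for this channel.
#' @export
channelSpec <- function(cell = 1L, channel = "A", solution = aucflow::solution(),
                        loadingVolume = 450, volumeTolerance = 2,
                        concentrationRatio = 1, ratioTolerance = 5,
                        rightDataLimit = 7.15, wavelengths = 280)
    new("ChannelSpec", cell = as.integer(cell), channel = toupper(channel),
        solution = solution, loadingVolume = loadingVolume,
        volumeTolerance = volumeTolerance, concentrationRatio = concentrationRatio,
        ratioTolerance = ratioTolerance, rightDataLimit = rightDataLimit,
        wavelengths = wavelengths)

## ---------------------------------------------------------------------------
## Fit workflow options
## ---------------------------------------------------------------------------

#' Analysis workflow options for the grid fit
#'
#' Controls the two-dimensional (s, f/f0) grid, noise fitting, meniscus
#' refinement, iterative refinement, and Monte Carlo iterations.
#'
#' @slot sRange numeric length 2, sedimentation-coefficient range in svedbergs.
#' @slot sPoints integer, grid points along s.
#' @slot kRange numeric length 2, frictional-ratio (f/f0) range, min >= 1.
#' @slot kPoints integer, grid points along f/f0.
#' @slot gridSpacing `"log"` (default) or `"linear"` spacing in s.
#' @slot fitTI,fitRI logical, fit time-invariant / radially-invariant noise.
#' @slot fitMeniscus logical, refine the meniscus by a candidate scan.
#' @slot meniscusPoints odd integer >= 3, candidate count.
#' @slot meniscusSpan numeric, half-width of the candidate range in cm.
#' @slot maxIterations integer, iterative refinement cap (0 disables stage).
#' @slot monteCarlo integer, Monte Carlo iterations B (0 disables stage).
#' @slot solverStep numeric, radial step (cm) of the internal grid used to
#'   simulate design-matrix columns.
#' @slot subgridSize integer, accepted for protocol compatibility; inert in
#'   the single-solve implementation.
#' @exportClass FitWorkflowSpec
setClass("FitWorkflowSpec", representation(
    sRange = "numeric", sPoints = "integer", kRange = "numeric",
    kPoints = "integer", gridSpacing = "character",
    fitTI = "logical", fitRI = "logical", fitMeniscus = "logical",
    meniscusPoints = "integer", meniscusSpan = "numeric",
    maxIterations = "integer", monteCarlo = "integer",
    solverStep = "numeric", subgridSize = "integer"),
    validity = function(object) {
        if (object@kRange[1] < 1) return("f/f0 minimum must be >= 1")
        if (diff(object@sRange) <= 0 || diff(object@kRange) < 0)
            return("grid ranges must be non-empty")
        if (object@fitMeniscus &&
            (object@meniscusPoints < 3L || object@meniscusPoints %% 2L == 0L))
            return("meniscusPoints must be an odd integer >= 3")
        TRUE
    })

#' @rdname FitWorkflowSpec-class
#' @param sRange,sPoints,kRange,kPoints,gridSpacing grid definition.
#' @param fitTI,fitRI,fitMeniscus,meniscusPoints,meniscusSpan noise/meniscus
#'   options.
#' @param maxIterations,monteCarlo refinement stage controls.
#' @param solverStep,subgridSize solver resolution and (inert) subgrid size.
#' @export
fitWorkflowSpec <- function(sRange = c(1, 10), sPoints = 32L, kRange = c(1, 2.5),
                            kPoints = 5L, gridSpacing = "log",
                            fitTI = TRUE, fitRI = TRUE, fitMeniscus = TRUE,
                            meniscusPoints = 3L, meniscusSpan = 0.004,
                            maxIterations = 3L, monteCarlo = 0L,
                            solverStep = 0.002, subgridSize = 64L)
    new("FitWorkflowSpec", sRange = sRange, sPoints = as.integer(sPoints),
        kRange = kRange, kPoints = as.integer(kPoints), gridSpacing = gridSpacing,
        fitTI = fitTI, fitRI = fitRI, fitMeniscus = fitMeniscus,
        meniscusPoints = as.integer(meniscusPoints), meniscusSpan = meniscusSpan,
        maxIterations = as.integer(maxIterations), monteCarlo = as.integer(monteCarlo),
        solverStep = solverStep, subgridSize = as.integer(subgridSize))

## ---------------------------------------------------------------------------
## Analysis profile (the GMP protocol)
## ---------------------------------------------------------------------------

#' GMP experimental analysis profile
#'
#' The complete protocol for one experiment: speed steps, per-channel loading
#' with tolerances, centerpiece geometry, rotor stretch calibration, radial
#' measurement range, and the analysis workflow. Once frozen (read-only) no
#' field may change; any derived change must produce a new GUID and run name.
#'
#' @slot guid character global unique identifier ("" until assigned).
#' @slot runName character run label, unique within a store.
#' @slot temperature numeric run temperature, degrees C.
#' @slot speedSteps list of [SpeedStep-class].
#' @slot channels list of [ChannelSpec-class].
#' @slot centerpieces named list of [Centerpiece-class], names = cell numbers.
#' @slot rotorCalibration a [RotorCalibration-class].
#' @slot workflow a [FitWorkflowSpec-class].
#' @slot radialRange numeric length 2, instrument radial measurement range (cm).
#' @slot radialStep numeric, radial grid step (cm).
#' @slot readOnly logical, TRUE once frozen.
#' @exportClass AnalysisProfile
setClass("AnalysisProfile", representation(
    guid = "character", runName = "character", temperature = "numeric",
    speedSteps = "list", channels = "list", centerpieces = "list",
    rotorCalibration = "RotorCalibration", workflow = "FitWorkflowSpec",
    radialRange = "numeric", radialStep = "numeric", readOnly = "logical"))

#' @rdname AnalysisProfile-class
#' @param runName run label.
#' @param temperature run temperature in degrees C.
#' @param speedSteps list of [SpeedStep-class] (a single step may be passed
#'   bare).
#' @param channels list of [ChannelSpec-class] (a single spec may be passed
#'   bare).
#' @param centerpieces named list of [Centerpiece-class] keyed by cell number.
#' @param rotorCalibration a [RotorCalibration-class].
#' @param workflow a [FitWorkflowSpec-class].
#' @param radialRange,radialStep radial measurement range and step (cm).
#' @export
analysisProfile <- function(runName, temperature = 20,
                            speedSteps = list(speedStep()),
                            channels = list(channelSpec()),
                            centerpieces = NULL,
                            rotorCalibration = aucflow::rotorCalibration(),
                            workflow = fitWorkflowSpec(),
                            radialRange = c(5.75, 7.3), radialStep = 0.001) {
    if (is(speedSteps, "SpeedStep")) speedSteps <- list(speedSteps)
    if (is(channels, "ChannelSpec")) channels <- list(channels)
    if (is.null(centerpieces)) {
        cells <- unique(vapply(channels, function(ch) ch@cell, integer(1)))
        centerpieces <- stats::setNames(replicate(length(cells), centerpiece()),
                                        as.character(cells))
    }
    new("AnalysisProfile", guid = "", runName = runName, temperature = temperature,
        speedSteps = speedSteps, channels = channels, centerpieces = centerpieces,
        rotorCalibration = rotorCalibration, workflow = workflow,
        radialRange = radialRange, radialStep = radialStep, readOnly = FALSE)
}

## ---------------------------------------------------------------------------
## Edit profile
## ---------------------------------------------------------------------------

#' Edit profile for one triple
#'
#' Records the detected meniscus, the edited data range, the baseline and the
#' per-scan plateau values. The left limit sits 0.03 cm right of the meniscus
#' (within one grid step) so that a meniscus fit never moves the boundary
#' condition into the data range.
#'
#' @slot cell,channel,wavelength parent triple identity.
#' @slot meniscus numeric, cm.
#' @slot leftLimit,rightLimit numeric, cm; `meniscus < leftLimit < rightLimit`.
#' @slot baseline numeric, AU.
#' @slot plateau numeric, AU per scan.
#' @slot gridStep numeric, cm (snap tolerance for the 0.03 cm offset).
#' @exportClass EditProfile
setClass("EditProfile", representation(
    cell = "integer", channel = "character", wavelength = "numeric",
    meniscus = "numeric", leftLimit = "numeric", rightLimit = "numeric",
    baseline = "numeric", plateau = "numeric", gridStep = "numeric"),
    validity = function(object) {
        if (!(object@meniscus < object@leftLimit &&
              object@leftLimit < object@rightLimit))
            return("need meniscus < leftLimit < rightLimit")
        if (abs(object@leftLimit - object@meniscus - 0.03) > object@gridStep + 1e-12)
            return("leftLimit must sit 0.03 cm right of the meniscus (within one grid step)")
        TRUE
    })

## ---------------------------------------------------------------------------
## Timestate & verification
## ---------------------------------------------------------------------------

#' Second-by-second rotor timestate
#'
#' One record per second from t = 1 s: set and actual rotor speed, cumulative
#' omega^2 t (trapezoidal accumulation), temperature and speed-stage index.
#' The record at t = 0 (all zeros) is implicit.
#'
#' @slot records data.frame with columns `time`, `setRpm`, `actualRpm`,
#'   `omega2t`, `temperature`, `stage`.
#' @exportClass TimeState
setClass("TimeState", representation(records = "data.frame"),
    validity = function(object) {
        r <- object@records
        need <- c("time", "setRpm", "actualRpm", "omega2t", "temperature", "stage")
        if (!all(need %in% names(r))) return("missing timestate columns")
        if (nrow(r) && any(diff(r$time) != 1)) return("times must be consecutive seconds")
        if (nrow(r) && (any(r$omega2t < 0) || any(diff(r$omega2t) < -1e-9)))
            return("omega2t must be non-negative and non-decreasing")
        TRUE
    })

#' Scan-vs-timestate verification report
#'
#' @slot perScan data.frame with per-scan deviations and pass flags.
#' @slot pass logical overall flag (TRUE iff every scan passes).
#' @slot tolerances named list of the tolerances used.
#' @exportClass VerificationReport
setClass("VerificationReport", representation(
    perScan = "data.frame", pass = "logical", tolerances = "list"))

## ---------------------------------------------------------------------------
## Simulation inputs
## ---------------------------------------------------------------------------

#' Ground-truth species for the simulator
#'
#' @slot s numeric sedimentation coefficient in svedbergs (1 S = 1e-13 s).
#' @slot D numeric diffusion coefficient in cm^2/s (NA to derive from `k`).
#' @slot k numeric frictional ratio f/f0 (used when `D` is NA).
#' @slot c0 numeric loading signal in AU at the centerpiece pathlength.
#' @exportClass TruthSpecies
setClass("TruthSpecies", representation(
    s = "numeric", D = "numeric", k = "numeric", c0 = "numeric"),
    validity = function(object) {
        if (object@s <= 0) return("s must be > 0 for a sedimenting species")
        if (!is.na(object@D) && object@D <= 0) return("D must be > 0")
        if (is.na(object@D) && (is.na(object@k) || object@k < 1))
            return("either D or a frictional ratio k >= 1 is required")
        if (object@c0 < 0) return("c0 must be >= 0")
        TRUE
    })

#' @rdname TruthSpecies-class
#' @param s svedbergs; @param D cm^2/s (NA to derive from `k`);
#' @param k f/f0; @param c0 loading signal (AU).
#' @export
truthSpecies <- function(s, D = NA_real_, k = NA_real_, c0 = 0.6)
    new("TruthSpecies", s = s, D = D, k = k, c0 = c0)

#' Noise model for the simulator
#'
#' Three components: a time-invariant radial baseline beta(r) (smooth random
#' function, sd = `tiAmplitude`), a radially-invariant per-scan offset gamma(t)
#' (i.i.d. normal, sd = `riAmplitude`), and stochastic detector noise whose
#' induced pseudo-absorbance sd is `stochasticSd`.
#'
#' @slot tiAmplitude,riAmplitude,stochasticSd numeric, AU (all >= 0).
#' @slot seed integer RNG seed; the experiment is fully reproducible given it.
#' @exportClass NoiseSpec
setClass("NoiseSpec", representation(
    tiAmplitude = "numeric", riAmplitude = "numeric",
    stochasticSd = "numeric", seed = "integer"),
    validity = function(object) {
        if (any(c(object@tiAmplitude, object@riAmplitude, object@stochasticSd) < 0))
            return("noise amplitudes must be >= 0")
        TRUE
    })

#' @rdname NoiseSpec-class
#' @param tiAmplitude,riAmplitude,stochasticSd amplitudes in AU.
#' @param seed RNG seed.
#' @export
noiseSpec <- function(tiAmplitude = 0.02, riAmplitude = 0.005,
                      stochasticSd = 0.003, seed = 1L)
    new("NoiseSpec", tiAmplitude = tiAmplitude, riAmplitude = riAmplitude,
        stochasticSd = stochasticSd, seed = as.integer(seed))

#' A simulated (or imported) experiment
#'
#' @slot runName character.
#' @slot profile the [AnalysisProfile-class] that generated it.
#' @slot triples named list of [TripleData-class] keyed "cell channel wl".
#' @slot timestate a [TimeState-class].
#' @slot truth named list (per channel) of [TruthSpecies-class] lists; empty
#'   for real data.
#' @exportClass AucExperiment
setClass("AucExperiment", representation(
    runName = "character", profile = "AnalysisProfile", triples = "list",
    timestate = "TimeState", truth = "list"))

## ---------------------------------------------------------------------------
## Models, metrics, reports, autoflow
## ---------------------------------------------------------------------------

#' Fitted model for one triple
#'
#' Discrete species recovered by the grid decomposition plus the systematic
#' noise vectors and the fit RMSD.
#'
#' @slot species data.frame with columns `s` (svedberg), `s20w`, `D` (cm^2/s),
#'   `k` (f/f0), `M` (g/mol), `concentration` (AU, >= 0).
#' @slot rmsd numeric, AU.
#' @slot tiNoise numeric per-radius offset (AU).
#' @slot riNoise numeric per-scan offset (AU, zero mean).
#' @slot meniscus numeric, meniscus used (cm).
#' @slot stage character workflow stage label.
#' @slot iterations integer refinement iterations actually used.
#' @slot mcStats data.frame Monte Carlo statistics (possibly empty).
#' @exportClass ModelRecord
setClass("ModelRecord", representation(
    species = "data.frame", rmsd = "numeric", tiNoise = "numeric",
    riNoise = "numeric", meniscus = "numeric", stage = "character",
    iterations = "integer", mcStats = "data.frame"),
    prototype(iterations = 0L, mcStats = data.frame()),
    validity = function(object) {
        if (nrow(object@species) && any(object@species$concentration < 0))
            return("partial concentrations must be >= 0")
        if (object@rmsd < 0) return("rmsd must be >= 0")
        TRUE
    })

#' Extracted GMP metrics for one experiment/channel
#'
#' @slot values named numeric metric values (volume, concentration, duration,
#'   rotor speed, scan count, column length, rmsd).
#' @slot wavelengths numeric, nm measured.
#' @slot speciesTable data.frame of signal fractions (percent) per s-range bin.
#' @slot sBins numeric bin edges in svedbergs.
#' @exportClass MetricSet
setClass("MetricSet", representation(
    values = "numeric", wavelengths = "numeric",
    speciesTable = "data.frame", sBins = "numeric"))

#' Tolerance comparison report
#'
#' @slot entries data.frame: metric name, measured, reference, percent (or
#'   point) deviation, tolerance, flag.
#' @slot grade `"Pass"`, `"Fail"` or `"AsIs"` (no reference supplied).
#' @slot runName character.
#' @exportClass ReportRecord
setClass("ReportRecord", representation(
    entries = "data.frame", grade = "character", runName = "character"),
    validity = function(object) {
        if (!object@grade %in% c("Pass", "Fail", "AsIs"))
            return("grade must be Pass, Fail or AsIs")
        TRUE
    })

#' Autoflow supervisor record
#'
#' Tracks one experiment through the staged workflow
#' DESIGN -> LIVE_UPDATE -> IMPORT -> EDITING -> ANALYSIS -> REPORT -> DONE.
#'
#' @slot runName,profileGuid,instrument identity fields.
#' @slot status current stage label.
#' @slot timestamps named numeric POSIX times of each transition.
#' @slot lock session GUID holding the record ("" when free).
#' @slot note failure note ("" when clean).
#' @exportClass AutoflowRecord
setClass("AutoflowRecord", representation(
    runName = "character", profileGuid = "character", instrument = "character",
    status = "character", timestamps = "numeric", lock = "character",
    note = "character"))

#' File-backed experiment store
#'
#' Directory-backed storage for triples (binary double precision), profiles,
#' edit profiles, models, reports and autoflow state. Access is gated by a
#' user level: `"operator"` may read and import, `"designer"` may freeze
#' profiles, `"admin"` may delete.
#'
#' @slot path character store root directory.
#' @slot userLevel one of `"operator"`, `"designer"`, `"admin"`.
#' @exportClass AucStore
setClass("AucStore", representation(path = "character", userLevel = "character"),
    validity = function(object) {
        if (!object@userLevel %in% c("operator", "designer", "admin"))
            return("userLevel must be operator, designer or admin")
        TRUE
    })
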