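# Shared builders for the test suite. All fixtures are generated in code.

# Instrument-like profile: fine radial grid, short run. Used for editing and
# conversion tests where the 0.001 cm detector step matters.
editProfileFixture <- function(runName = "edit-run",
                               workflow = fitWorkflowSpec()) {
    analysisProfile(runName,
        speedSteps = speedStep(setRpm = 50000, duration = 2500,
                               scanInterval = 125, initialDelay = 250),
        channels = channelSpec(loadingVolume = 450, rightDataLimit = 7.15),
        workflow = workflow, radialStep = 0.001)
}

# Fit-study profile: coarser 0.0025 cm grid, 40 scans, solver step matching
# the data step so on-grid species reproduce the data exactly.
fitProfileFixture <- function(runName = "fit-run",
                              workflow = fitWorkflowSpec(solverStep = 0.0025)) {
    analysisProfile(runName,
        speedSteps = speedStep(setRpm = 50000, duration = 3800,
                               scanInterval = 90, initialDelay = 200),
        channels = channelSpec(loadingVolume = 450, rightDataLimit = 7.15),
        workflow = workflow, radialStep = 0.0025)
}

# Small light workflow for stage-gating tests (cheap design builds).
lightWorkflow <- function(...)
    fitWorkflowSpec(sPoints = 8L, kPoints = 2L, meniscusPoints = 3L,
                    meniscusSpan = 0.004, solverStep = 0.005, ...)

lightProfileFixture <- function(runName = "light-run", ...)
    analysisProfile(runName,
        speedSteps = speedStep(setRpm = 50000, duration = 3000,
                               scanInterval = 250, initialDelay = 250),
        channels = channelSpec(loadingVolume = 450, rightDataLimit = 7.15),
        workflow = lightWorkflow(...), radialStep = 0.005)

randomTruth <- function(seed, c0 = 0.6) {
    set.seed(seed)
    list("1A" = list(truthSpecies(s = stats::runif(1, 2, 8),
                                  k = stats::runif(1, 1.2, 2), c0 = c0)))
}

# Simple triple on a uniform grid with given value matrix.
tripleFixture <- function(values, rMin = 5.8, step = 0.001, cell = 1L,
                          channel = "A", wavelength = 280,
                          signalKind = "intensity", dt = 100) {
    values <- as.matrix(values)
    g <- radialGrid(rMin, rMin + (nrow(values) - 1) * step, step)
    ns <- ncol(values)
    tripleData(cell, channel, wavelength, g, values,
               scanTime = seq(dt, by = dt, length.out = ns),
               scanRpm = rep(50000, ns),
               scanOmega2t = seq(1e8, by = 1e8, length.out = ns),
               signalKind = signalKind)
}

# Valid frozen profile for autoflow tests (no simulation involved).
frozenProfileFixture <- function(runName = "af-run")
    freezeProfile(lightProfileFixture(runName))
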