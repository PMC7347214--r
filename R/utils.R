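## Internal helpers shared across modules.

.aucflowEnv <- new.env(parent = emptyenv())
.aucflowEnv$guidCounter <- 0L

# Session-unique identifier; does not consume the user's RNG stream.
newGuid <- function() {
    .aucflowEnv$guidCounter <- .aucflowEnv$guidCounter + 1L
    sprintf("%08x-%04x-%06x",
            as.integer(as.numeric(Sys.time()) %% 0x7fffffff),
            Sys.getpid() %% 0xffff, .aucflowEnv$guidCounter)
}

# Index of the grid point nearest to radius x.
snapIndex <- function(radii, x) which.min(abs(radii - x))

# Grid value nearest to radius x.
snapRadius <- function(radii, x) radii[snapIndex(radii, x)]

`%||%` <- function(a, b) if (is.null(a)) b else a

## ----------------------- rotor speed profile helpers -----------------------

# Piecewise rotor speed (rpm) at time t (s since run start) for a list of
# SpeedStep objects. Each step ramps linearly from the previous speed at its
# rampRate, then holds at setRpm for the remainder of its duration.
rpmAtTime <- function(speedSteps, t) {
    out <- numeric(length(t))
    start <- 0
    prevRpm <- 0
    for (st in speedSteps) {
        rampTime <- abs(st@setRpm - prevRpm) / st@rampRate
        stEnd <- start + st@duration
        inRamp <- t >= start & t < start + rampTime
        inHold <- t >= start + rampTime & t <= stEnd
        out[inRamp] <- prevRpm + sign(st@setRpm - prevRpm) * st@rampRate *
            (t[inRamp] - start)
        out[inHold] <- st@setRpm
        start <- stEnd
        prevRpm <- st@setRpm
    }
    out[t > start] <- prevRpm
    out
}

# Stage index (1-based speed step) at time t.
stageAtTime <- function(speedSteps, t) {
    bounds <- cumsum(vapply(speedSteps, function(s) s@duration, numeric(1)))
    pmin(findInterval(t, c(-Inf, bounds[-length(bounds)])), length(speedSteps))
}

rpmToOmega <- function(rpm) rpm * pi / 30

# Scan times implied by a speed profile: per step, initialDelay + k*interval
# while within the step duration (times measured from run start).
profileScanTimes <- function(speedSteps) {
    start <- 0
    times <- numeric(0)
    for (st in speedSteps) {
        tk <- seq(st@initialDelay, st@duration, by = st@scanInterval)
        times <- c(times, start + tk)
        start <- start + st@duration
    }
    times
}

totalDuration <- function(speedSteps)
    sum(vapply(speedSteps, function(s) s@duration, numeric(1)))
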