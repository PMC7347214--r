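#' Generate the second-by-second rotor timestate
#'
#' Emulates the instrument's 1-second system log: one record per second from
#' t = 1 s to the end of the run, carrying set and actual rotor speed, the
#' cumulative \eqn{\omega^2 t} integral (per-second trapezoidal accumulation
#' of \eqn{\omega(t)^2} over the ramp/hold speed profile), temperature, and
#' the speed-stage index.
#'
#' @param speedSteps list of [SpeedStep-class] (one may be passed bare).
#' @param totalDuration run length in s (default: sum of step durations).
#' @param temperature chamber temperature, degrees C.
#' @return A [TimeState-class].
#' @examples
#' ts <- generateTimestate(speedStep(50000, duration = 600))
#' nrow(timestateRecords(ts))
#' @export
generateTimestate <- function(speedSteps, totalDuration = NULL,
                              temperature = 20) {
    if (is(speedSteps, "SpeedStep")) speedSteps <- list(speedSteps)
    dur <- round(totalDuration %||%
                 sum(vapply(speedSteps, function(s) s@duration, numeric(1))))
    tt <- 0:dur
    om2 <- rpmToOmega(rpmAtTime(speedSteps, tt))^2
    o2t <- cumsum(c(0, (om2[-1] + om2[-length(om2)]) / 2))
    rec <- data.frame(time = tt[-1],
                      setRpm = vapply(stageAtTime(speedSteps, tt[-1]),
                                      function(i) speedSteps[[i]]@setRpm,
                                      numeric(1)),
                      actualRpm = rpmAtTime(speedSteps, tt[-1]),
                      omega2t = o2t[-1],
                      temperature = temperature,
                      stage = stageAtTime(speedSteps, tt[-1]))
    new("TimeState", records = rec)
}

#' Timestate record table
#' @param ts a [TimeState-class].
#' @return The per-second data.frame.
#' @export
timestateRecords <- function(ts) ts@records

#' Interpolate the omega^2 t integral at an arbitrary time
#'
#' Linear interpolation between the bracketing 1-second records; exact at
#' record times, 0 at t = 0.
#'
#' @param ts a [TimeState-class].
#' @param t time(s) in s, within `[0, last record]`.
#' @return omega^2 t in rad^2/s.
#' @export
omega2tAt <- function(ts, t) {
    r <- ts@records
    if (any(t < 0 | t > r$time[nrow(r)]))
        stop("t outside the timestate span [0, ", r$time[nrow(r)], "] s")
    stats::approx(c(0, r$time), c(0, r$omega2t), xout = t)$y
}

# Invert the omega2t integral: time at which the timestate reached o2t.
# Uses the strictly increasing part of the record.
timeAtOmega2t <- function(ts, o2t) {
    r <- ts@records
    x <- c(0, r$omega2t); y <- c(0, r$time)
    keep <- c(TRUE, diff(x) > 0)
    stats::approx(x[keep], y[keep], xout = o2t, rule = 2)$y
}

#' Verify scan headers against the timestate
#'
#' Cross-checks every scan of every triple against the independent 1-second
#' rotor log: the scan time against the time implied by inverting the
#' omega^2 t integral (a separate-timer consistency check), the recorded
#' omega^2 t against the interpolated timestate value (relative, with a floor
#' of 1 on the denominator), and the recorded rotor speed against the actual
#' speed at that second. Scans beyond the timestate span are flagged, not
#' raised.
#'
#' @param ts a [TimeState-class].
#' @param triples list of [TripleData-class] (one may be passed bare).
#' @param tolTime seconds.
#' @param tolOmega2tRel relative tolerance on omega^2 t.
#' @param tolRpm rev/min.
#' @return A [VerificationReport-class].
#' @export
verifyScans <- function(ts, triples, tolTime = 1, tolOmega2tRel = 1e-4,
                        tolRpm = 5) {
    if (is(triples, "TripleData")) triples <- list(triples)
    rows <- list()
    span <- ts@records$time[nrow(ts@records)]
    for (tr in triples) {
        key <- tripleKey(tr)
        for (i in seq_along(tr@scanTime)) {
            tm <- tr@scanTime[i]
            if (tm < 0 || tm > span) {
                rows[[length(rows) + 1L]] <- data.frame(
                    triple = key, scan = i, dTime = NA_real_,
                    dOmega2tRel = NA_real_, dRpm = NA_real_, pass = FALSE)
                next
            }
            dT <- abs(tm - timeAtOmega2t(ts, tr@scanOmega2t[i]))
            o2 <- omega2tAt(ts, tm)
            dO <- abs(tr@scanOmega2t[i] - o2) / max(o2, 1)
            rpmTs <- stats::approx(c(0, ts@records$time),
                                   c(0, ts@records$actualRpm), xout = tm)$y
            dR <- abs(tr@scanRpm[i] - rpmTs)
            rows[[length(rows) + 1L]] <- data.frame(
                triple = key, scan = i, dTime = dT, dOmega2tRel = dO,
                dRpm = dR,
                pass = dT <= tolTime && dO <= tolOmega2tRel && dR <= tolRpm)
        }
    }
    perScan <- do.call(rbind, rows)
    new("VerificationReport", perScan = perScan, pass = all(perScan$pass),
        tolerances = list(tolTime = tolTime, tolOmega2tRel = tolOmega2tRel,
                          tolRpm = tolRpm))
}

#' Write / read a timestate as CSV
#'
#' One row per second; plain text for audit portability.
#'
#' @param ts a [TimeState-class].
#' @param path CSV file path.
#' @export
writeTimestateCsv <- function(ts, path)
    utils::write.csv(ts@records, path, row.names = FALSE)

#' @rdname writeTimestateCsv
#' @export
readTimestateCsv <- function(path)
    new("TimeState", records = utils::read.csv(path))
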