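#' Hydrodynamic parameters of an (s, f/f0) grid point
#'
#' Converts a sedimentation coefficient and frictional ratio into the implied
#' molar mass and diffusion coefficient under standard hydrodynamics:
#' \eqn{f_0 = 6\pi\eta (3 M \bar v / (4\pi N_A))^{1/3}}, \eqn{f = k f_0},
#' \eqn{s = M(1-\bar v \rho)/(N_A f)} solved for M (closed form), then
#' \eqn{D = s R T / (M (1-\bar v \rho))} (Svedberg relation).
#'
#' @param s sedimentation coefficient in svedbergs.
#' @param k frictional ratio f/f0, >= 1.
#' @param vbar partial specific volume, ml/g.
#' @param density buffer density, g/ml.
#' @param viscosity buffer viscosity, poise.
#' @param temperature run temperature, degrees C.
#' @param constants physical constants, see [physicalConstants()].
#' @return List with `D` (cm^2/s), `M` (g/mol), `f` and `f0` (g/s).
#' @examples
#' sp <- speciesFromGridPoint(4.3, 1.25, 0.73, 0.998234, 0.010020)
#' sp$M
#' @export
speciesFromGridPoint <- function(s, k, vbar, density, viscosity,
                                 temperature = 20,
                                 constants = physicalConstants()) {
    if (k < 1) stop("frictional ratio k must be >= 1")
    buoy <- 1 - vbar * density
    if (abs(buoy) < 1e-6)
        stop("neutral buoyancy: |1 - vbar*rho| < 1e-6, mass is undetermined")
    sSec <- s * SVEDBERG
    TK <- temperature + 273.15
    cf <- k * 6 * pi * viscosity * (3 * vbar / (4 * pi * constants$NA.))^(1 / 3)
    M <- (sSec * constants$NA. * cf / buoy)^(3 / 2)
    f0 <- 6 * pi * viscosity * (3 * M * vbar / (4 * pi * constants$NA.))^(1 / 3)
    D <- sSec * constants$R * TK / (M * buoy)
    list(D = D, M = M, f = k * f0, f0 = f0)
}

#' Correct a sedimentation coefficient to water at 20 C
#'
#' \eqn{s_{20,W} = s \cdot (\eta_{T,B}/\eta_{20,W}) \cdot
#' ((1-\bar v\rho_{20,W})/(1-\bar v\rho_{T,B}))}.
#'
#' @param s sedimentation coefficient (any unit; scales linearly).
#' @param vbar partial specific volume, ml/g.
#' @param density,viscosity buffer density (g/ml) and viscosity (poise) at run
#'   temperature.
#' @param constants see [physicalConstants()].
#' @return Corrected coefficient in the unit of `s`.
#' @export
correctS20W <- function(s, vbar, density, viscosity,
                        constants = physicalConstants()) {
    b20 <- 1 - vbar * constants$rho20w
    bTB <- 1 - vbar * density
    if (abs(b20) < 1e-6) stop("neutral buoyancy in water at 20 C")
    s * (viscosity / constants$eta20w) * (b20 / bTB)
}

#' Correct a diffusion coefficient to water at 20 C
#'
#' \eqn{D_{20,W} = D \cdot (\eta_{T,B}/\eta_{20,W}) \cdot (293.15/T)}.
#'
#' @param D diffusion coefficient, cm^2/s.
#' @param viscosity buffer viscosity at run temperature, poise.
#' @param temperature run temperature, degrees C.
#' @param constants see [physicalConstants()].
#' @export
correctD20W <- function(D, viscosity, temperature = 20,
                        constants = physicalConstants())
    D * (viscosity / constants$eta20w) * (constants$T20 / (temperature + 273.15))

#' Build the (s, f/f0) grid of a workflow specification
#'
#' @param workflow a [FitWorkflowSpec-class].
#' @param solution a [Solution-class] providing vbar/density/viscosity.
#' @param temperature run temperature in degrees C.
#' @return data.frame with columns `s` (svedberg), `k`, `D` (cm^2/s), `M`.
#' @export
fitGrid <- function(workflow, solution, temperature = 20) {
    sVals <- if (workflow@gridSpacing == "log")
        exp(seq(log(workflow@sRange[1]), log(workflow@sRange[2]),
                length.out = workflow@sPoints))
    else seq(workflow@sRange[1], workflow@sRange[2],
             length.out = workflow@sPoints)
    kVals <- if (workflow@kPoints == 1L) workflow@kRange[1]
             else seq(workflow@kRange[1], workflow@kRange[2],
                      length.out = workflow@kPoints)
    g <- expand.grid(s = sVals, k = kVals)
    vb <- solution@analytes$vbar[1]
    hm <- mapply(function(s, k) {
        p <- speciesFromGridPoint(s, k, vb, solution@density,
                                  solution@viscosity, temperature)
        c(p$D, p$M)
    }, g$s, g$k)
    g$D <- hm[1, ]
    g$M <- hm[2, ]
    g
}

#' Design matrix of unit-loading solutions
#'
#' One column per grid point: the sector-cell solution for loading 1 AU,
#' simulated on an internal grid and sampled at the edited data radii and scan
#' times. Columns are stacked radius-fastest (matching `as.vector` of a
#' radii x scans matrix).
#'
#' @param grid data.frame from [fitGrid()] (columns `s`, `D`).
#' @param dataRadii radii (cm) of the edited data range.
#' @param scanTimes scan times (s since run start).
#' @param meniscus,bottom solution-column walls in cm.
#' @param speedSteps list of [SpeedStep-class].
#' @param solverStep internal radial step (cm).
#' @param dtMax solver substep cap (s).
#' @return Matrix `length(dataRadii)*length(scanTimes)` x `nrow(grid)`, with
#'   the grid as attribute `grid`.
#' @export
buildDesignMatrix <- function(grid, dataRadii, scanTimes, meniscus, bottom,
                              speedSteps, solverStep = 0.002, dtMax = 10) {
    if (min(dataRadii) < meniscus || max(dataRadii) > bottom)
        stop("data radii must lie inside [meniscus, bottom]")
    X <- matrix(0, length(dataRadii) * length(scanTimes), nrow(grid))
    for (j in seq_len(nrow(grid))) {
        sol <- solveLamm(truthSpecies(s = grid$s[j], D = grid$D[j], c0 = 1),
                         meniscus, bottom, speedSteps, scanTimes,
                         gridStep = solverStep, dtMax = dtMax)
        r <- attr(sol, "radii")
        X[, j] <- as.vector(apply(sol, 2, function(col)
            stats::approx(r, col, xout = dataRadii)$y))
    }
    attr(X, "grid") <- grid
    X
}

## ------------------------- internal NNLS machinery -------------------------

# Fast NNLS (Bro & de Jong) on precomputed normal equations. Active-set
# method; returns the non-negative x minimizing ||Ax - b|| given AtA = A'A
# and Atb = A'b. Cross-checked in the tests against pracma::lsqnonneg.
fnnls <- function(AtA, Atb, eps = NULL) {
    n <- length(Atb)
    eps <- eps %||% (10 * .Machine$double.eps * max(abs(AtA)) * n)
    x <- numeric(n)
    P <- logical(n)
    wv <- Atb
    iter <- 0L; maxIter <- 30L * n
    while (any(!P) && any(wv[!P] > eps) && iter < maxIter) {
        j <- which(!P)[which.max(wv[!P])]
        P[j] <- TRUE
        repeat {
            iter <- iter + 1L
            sP <- numeric(n)
            sP[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
            if (all(sP[P] > 0)) break
            neg <- P & sP <= 0
            alpha <- min(x[neg] / (x[neg] - sP[neg]))
            x <- x + alpha * (sP - x)
            P[P & x <= eps] <- FALSE
            x[!P] <- 0
            if (iter >= maxIter) break
        }
        x <- sP
        wv <- as.numeric(Atb - AtA %*% x)
    }
    pmax(x, 0)
}

## ---------------------------------------------------------------------------

#' Grid decomposition with systematic noise removal
#'
#' Non-negative least-squares fit of the edited data onto the design-matrix
#' columns, with optional time-invariant (per-radius) and radially-invariant
#' (per-scan, zero-mean) offsets. The augmented linear system -- design
#' columns plus per-radius and per-scan offset unknowns, the latter
#' constrained to zero mean for identifiability -- is solved exactly: because
#' the offsets enter linearly and unconstrained, they concentrate out of the
#' least-squares problem, leaving an NNLS on the data and design columns with
#' the offset subspace projected away (row/column centering of the radii x
#' scans reshape). The offsets are then recovered from the residual means.
#'
#' @param Y edited data matrix (radii x scans, pseudo-absorbance AU).
#' @param X design matrix from [buildDesignMatrix()].
#' @param fitTI,fitRI fit the time-invariant / radially-invariant offsets.
#' @param solution a [Solution-class] for the standard-condition corrections.
#' @param temperature run temperature, degrees C.
#' @param meniscus meniscus used (recorded in the model).
#' @param stage stage label recorded in the model.
#' @return A [ModelRecord-class]; species with zero weight are dropped.
#' @export
fitNNLS <- function(Y, X, fitTI = TRUE, fitRI = FALSE, solution = NULL,
                    temperature = 20, meniscus = NA_real_, stage = "2DSA") {
    nr <- nrow(Y); ns <- ncol(Y)
    stopifnot(nrow(X) == nr * ns)
    grid <- attr(X, "grid")

    # project the offset subspace out of one stacked (nr*ns) vector
    project <- function(v) {
        B <- matrix(v, nr)
        g <- mean(B)
        if (fitTI) B <- B - rowMeans(B)
        if (fitRI) {
            B <- B - rep(colMeans(B), each = nr)
            if (!fitTI) B <- B + g   # zero-mean RI spans no constant
        }
        as.numeric(B)
    }
    Xp <- if (fitTI || fitRI) apply(X, 2, project) else X
    Yp <- if (fitTI || fitRI) project(as.numeric(Y)) else as.numeric(Y)
    w <- fnnls(crossprod(Xp), as.numeric(crossprod(Xp, Yp)))

    resid <- Y - matrix(X %*% w, nr, ns)
    ti <- numeric(nr); ri <- numeric(ns)
    if (fitTI) ti <- rowMeans(resid)
    if (fitRI) {
        ri <- colMeans(resid - ti)
        ri <- ri - mean(ri)
    }
    lastRmsd <- sqrt(mean((resid - ti - rep(ri, each = nr))^2))
    iters <- 1L
    keep <- which(w > 0)
    sp <- if (length(keep)) {
        g <- grid[keep, , drop = FALSE]
        vb <- if (!is.null(solution)) solution@analytes$vbar[1] else NA_real_
        s20 <- if (!is.null(solution))
            correctS20W(g$s, vb, solution@density, solution@viscosity)
        else g$s
        data.frame(s = g$s, s20w = s20, D = g$D, k = g$k, M = g$M,
                   concentration = w[keep])
    } else data.frame(s = numeric(0), s20w = numeric(0), D = numeric(0),
                      k = numeric(0), M = numeric(0),
                      concentration = numeric(0))
    new("ModelRecord", species = sp, rmsd = lastRmsd, tiNoise = ti,
        riNoise = ri, meniscus = meniscus, stage = stage,
        iterations = iters, mcStats = data.frame())
}

#' Refine the meniscus by a candidate scan
#'
#' Performs a full grid fit for each candidate meniscus spanning
#' `+/- span` around the edited value, picks the RMSD minimum (ties break to
#' the lowest radius), and refines the value by parabolic interpolation
#' through the three lowest points. The model is refit at the refined
#' meniscus.
#'
#' @param Y edited data (radii x scans).
#' @param dataRadii,scanTimes edited data coordinates.
#' @param meniscus edited meniscus (cm), candidate centre.
#' @param bottom cell bottom (cm).
#' @param speedSteps rotor speed profile.
#' @param workflow a [FitWorkflowSpec-class] (candidate count, span, grid).
#' @param solution,temperature buffer conditions.
#' @return List with `meniscus` (refined), `model` ([ModelRecord-class]),
#'   `candidates` (data.frame meniscus/rmsd) and `edgeWarning` (TRUE when the
#'   minimum sat on the span edge).
#' @export
fitMeniscus <- function(Y, dataRadii, scanTimes, meniscus, bottom, speedSteps,
                        workflow, solution, temperature = 20) {
    span <- workflow@meniscusSpan
    cand <- seq(meniscus - span, meniscus + span,
                length.out = workflow@meniscusPoints)
    cand <- cand[cand < min(dataRadii)]   # wall must stay left of the data
    grid <- fitGrid(workflow, solution, temperature)
    fits <- lapply(cand, function(m) {
        X <- buildDesignMatrix(grid, dataRadii, scanTimes, m, bottom,
                               speedSteps, solverStep = workflow@solverStep)
        fitNNLS(Y, X, fitTI = workflow@fitTI, fitRI = workflow@fitRI,
                solution = solution, temperature = temperature, meniscus = m,
                stage = "meniscus-fit-TI+RI")
    })
    rm <- vapply(fits, rmsd, numeric(1))
    best <- which.min(rm)                  # first minimum = lowest radius
    edge <- best %in% c(1L, length(cand))
    if (edge) warning("meniscus range exhausted: minimum at span edge")

    refined <- cand[best]
    o <- order(rm)[seq_len(min(3L, length(rm)))]
    if (length(o) == 3L) {
        xs <- cand[o]; ys <- rm[o]
        den <- (xs[1] - xs[2]) * (xs[1] - xs[3]) * (xs[2] - xs[3])
        a <- (xs[3] * (ys[2] - ys[1]) + xs[2] * (ys[1] - ys[3]) +
              xs[1] * (ys[3] - ys[2])) / den
        b <- (xs[3]^2 * (ys[1] - ys[2]) + xs[2]^2 * (ys[3] - ys[1]) +
              xs[1]^2 * (ys[2] - ys[3])) / den
        if (is.finite(a) && a > 0) {
            vertex <- -b / (2 * a)
            if (vertex >= min(cand) && vertex <= max(cand) &&
                vertex < min(dataRadii))
                refined <- vertex
        }
    }
    model <- if (abs(refined - cand[best]) > 1e-12) {
        X <- buildDesignMatrix(grid, dataRadii, scanTimes, refined, bottom,
                               speedSteps, solverStep = workflow@solverStep)
        fitNNLS(Y, X, fitTI = workflow@fitTI, fitRI = workflow@fitRI,
                solution = solution, temperature = temperature,
                meniscus = refined, stage = "meniscus-fit-TI+RI")
    } else fits[[best]]
    list(meniscus = refined, model = model,
         candidates = data.frame(meniscus = cand, rmsd = rm),
         edgeWarning = edge)
}

#' Run the staged analysis workflow on one edited triple
#'
#' Applies, in order and gated by the workflow flags: (1) grid fit with
#' time-invariant noise removal ("2DSA-TI"); (2) meniscus refinement with
#' time- and radially-invariant noise ("meniscus-fit-TI+RI"); (3) iterative
#' refinement, re-estimating noise and refitting until the RMSD change falls
#' below 1e-6 AU or the iteration cap ("iterative"); (4) residual-bootstrap
#' Monte Carlo with B refits ("Monte Carlo"). A stage failure is recorded in
#' the stage log and later stages are skipped.
#'
#' @param triple an edited pseudo-absorbance [TripleData-class].
#' @param edit the matching [EditProfile-class].
#' @param profile the [AnalysisProfile-class] (workflow, speeds, geometry).
#' @param mcSeed RNG seed for the Monte Carlo stage.
#' @param store,runName optional [AucStore-class]: every stage model is
#'   persisted under the run.
#' @return List with `models` (ordered [ModelRecord-class] list), `stages`
#'   (character log) and `meniscus` (final value).
#' @export
runWorkflow <- function(triple, edit, profile, mcSeed = 1L,
                        store = NULL, runName = NULL) {
    wf <- profile@workflow
    chan <- channelFor(profile, triple@cell, triple@channel)
    sol <- chan@solution
    temperature <- profile@temperature
    cp <- profile@centerpieces[[as.character(triple@cell)]]
    rpmMax <- max(vapply(profile@speedSteps, function(s) s@setRpm, numeric(1)))
    bottom <- bottomPosition(cp, profile@rotorCalibration, rpmMax)

    radii <- gridPoints(triple)
    sel <- radii >= edit@leftLimit & radii <= edit@rightLimit
    Y <- signalValues(triple)[sel, , drop = FALSE]
    dataRadii <- radii[sel]
    scanTimes <- triple@scanTime

    models <- list(); stages <- character(0)
    meniscus <- edit@meniscus
    grid <- fitGrid(wf, sol, temperature)
    fail <- NULL
    push <- function(label, m) {
        stages <<- c(stages, label)
        models[[length(models) + 1L]] <<- m
        if (!is.null(store) && !is.null(runName))
            storeModel(store, runName, m,
                       sprintf("%s-%02d", tripleKey(triple), length(models)))
    }

    # stage 1: grid fit with TI noise
    X <- NULL
    tryCatch({
        X <- buildDesignMatrix(grid, dataRadii, scanTimes, meniscus, bottom,
                               profile@speedSteps, solverStep = wf@solverStep)
        push("2DSA-TI", fitNNLS(Y, X, fitTI = wf@fitTI, fitRI = FALSE,
                                solution = sol, temperature = temperature,
                                meniscus = meniscus, stage = "2DSA-TI"))
    }, error = function(e) fail <<- conditionMessage(e))

    # stage 2: meniscus fit with TI+RI noise
    if (is.null(fail) && wf@fitMeniscus) {
        tryCatch({
            mf <- fitMeniscus(Y, dataRadii, scanTimes, meniscus, bottom,
                              profile@speedSteps, wf, sol, temperature)
            meniscus <- mf$meniscus
            X <- buildDesignMatrix(grid, dataRadii, scanTimes, meniscus,
                                   bottom, profile@speedSteps,
                                   solverStep = wf@solverStep)
            push("meniscus-fit-TI+RI", mf$model)
        }, error = function(e) fail <<- conditionMessage(e))
    }

    # stage 3: iterative refinement
    if (is.null(fail) && wf@maxIterations > 0L) {
        tryCatch({
            prev <- models[[length(models)]]
            m <- prev; lastR <- rmsd(prev); used <- 0L
            for (i in seq_len(wf@maxIterations)) {
                m <- fitNNLS(Y, X, fitTI = wf@fitTI, fitRI = wf@fitRI,
                             solution = sol, temperature = temperature,
                             meniscus = meniscus, stage = "iterative")
                used <- i
                if (abs(lastR - rmsd(m)) < 1e-6) break
                lastR <- rmsd(m)
            }
            m@iterations <- used
            push("iterative", m)
        }, error = function(e) fail <<- conditionMessage(e))
    }

    # stage 4: Monte Carlo (residual bootstrap)
    if (is.null(fail) && wf@monteCarlo > 0L) {
        tryCatch({
            base <- models[[length(models)]]
            nr <- nrow(Y); ns <- ncol(Y)
            fitted <- matrix(0, nr, ns)
            if (nrow(base@species)) {
                gAll <- attr(X, "grid")
                idx <- match(paste(base@species$s, base@species$k),
                             paste(gAll$s, gAll$k))
                fitted <- matrix(X[, idx, drop = FALSE] %*%
                                 base@species$concentration, nr, ns)
            }
            fitted <- fitted + tiNoise(base) + rep(riNoise(base), each = nr)
            resid <- as.numeric(Y - fitted)
            set.seed(mcSeed)
            stats <- replicate(wf@monteCarlo, {
                Yb <- fitted + matrix(sample(resid, length(resid),
                                             replace = TRUE), nr, ns)
                mb <- fitNNLS(Yb, X, fitTI = wf@fitTI, fitRI = wf@fitRI,
                              solution = sol, temperature = temperature,
                              meniscus = meniscus, stage = "Monte Carlo")
                c(s = weightedMeanS(mb), k = weightedMeanK(mb),
                  conc = totalConcentration(mb), rmsd = rmsd(mb))
            })
            mc <- models[[length(models)]]
            mc@stage <- "Monte Carlo"
            mc@mcStats <- data.frame(statistic = rownames(stats),
                                     mean = rowMeans(stats),
                                     sd = apply(stats, 1, stats::sd))
            push("Monte Carlo", mc)
        }, error = function(e) fail <<- conditionMessage(e))
    }

    if (!is.null(fail)) stages <- c(stages, paste("FAILED:", fail))
    list(models = models, stages = stages, meniscus = meniscus)
}

#' Signal-weighted summary statistics of a model
#'
#' @param model a [ModelRecord-class].
#' @return Concentration-weighted mean of s (svedberg) / f-f0 ratio, or the
#'   total fitted concentration (AU).
#' @export
weightedMeanS <- function(model) {
    sp <- model@species
    if (!nrow(sp) || sum(sp$concentration) == 0) return(NA_real_)
    sum(sp$s * sp$concentration) / sum(sp$concentration)
}

#' @rdname weightedMeanS
#' @export
weightedMeanK <- function(model) {
    sp <- model@species
    if (!nrow(sp) || sum(sp$concentration) == 0) return(NA_real_)
    sum(sp$k * sp$concentration) / sum(sp$concentration)
}

#' @rdname weightedMeanS
#' @export
totalConcentration <- function(model) sum(model@species$concentration)

# ChannelSpec lookup within a profile (case-insensitive channel label).
channelFor <- function(profile, cell, channel) {
    for (ch in profile@channels)
        if (ch@cell == cell && toupper(ch@channel) == toupper(channel))
            return(ch)
    stop(sprintf("profile has no channel %d%s", cell, toupper(channel)))
}
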