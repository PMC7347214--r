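#' Open (or create) a file-backed experiment store
#'
#' The store mirrors the GMP data hierarchy on disk:
#' `experiments/<run>/triples/<cell><channel><wl>.dat` holds signal values as
#' little-endian 8-byte doubles (full detector precision, no text
#' truncation) next to a JSON metadata sidecar; profiles, edit profiles,
#' models, reports and autoflow state live in structured text. Operations are
#' gated by the handle's user level: operators read and import, designers
#' freeze protocols, admins delete.
#'
#' @param path store root directory (created if absent).
#' @param userLevel `"operator"`, `"designer"` or `"admin"`.
#' @return An [AucStore-class] handle.
#' @export
aucStore <- function(path, userLevel = "operator") {
    dir.create(file.path(path, "experiments"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(path, "profiles"), showWarnings = FALSE)
    dir.create(file.path(path, "autoflow"), showWarnings = FALSE)
    new("AucStore", path = normalizePath(path), userLevel = userLevel)
}

tripleFile <- function(store, runName, key)
    file.path(store@path, "experiments", runName, "triples", key)

#' Store / load a triple
#'
#' Signal values and radii round trip bit-exactly through the binary store
#' (8-byte little-endian doubles). Storing a second triple with the same
#' (cell, channel, wavelength) key in the same experiment is rejected;
#' channel labels compare case-insensitively.
#'
#' @param store an [AucStore-class].
#' @param runName experiment name.
#' @param triple a [TripleData-class].
#' @return `storeTriple` returns the triple key invisibly; `loadTriple`
#'   returns the [TripleData-class].
#' @export
storeTriple <- function(store, runName, triple) {
    validObject(triple)
    key <- tripleKey(triple)
    base <- tripleFile(store, runName, key)
    if (file.exists(paste0(base, ".dat")))
        stop("duplicate triple ", key, " in experiment '", runName, "'")
    dir.create(dirname(base), recursive = TRUE, showWarnings = FALSE)
    meta <- list(cell = triple@cell, channel = triple@channel,
                 wavelength = triple@wavelength,
                 signalKind = triple@signalKind,
                 nRadii = length(gridPoints(triple)),
                 nScans = ncol(signalValues(triple)),
                 scanTime = triple@scanTime, scanRpm = triple@scanRpm,
                 scanOmega2t = triple@scanOmega2t,
                 scanTemperature = triple@scanTemperature,
                 byteOrder = "little")
    jsonlite::write_json(meta, paste0(base, ".json"), digits = NA,
                         auto_unbox = TRUE)
    con <- file(paste0(base, ".dat"), "wb")
    on.exit(close(con))
    writeBin(c(gridPoints(triple), as.numeric(signalValues(triple))), con,
             size = 8, endian = "little")
    invisible(key)
}

#' @rdname storeTriple
#' @param cell,channel,wavelength triple identity.
#' @export
loadTriple <- function(store, runName, cell, channel, wavelength) {
    key <- tripleKey(cell * 1.0, channel, wavelength)
    base <- tripleFile(store, runName, key)
    if (!file.exists(paste0(base, ".dat")))
        stop("triple ", key, " not found in experiment '", runName, "'")
    meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
    n <- meta$nRadii * (meta$nScans + 1L)
    con <- file(paste0(base, ".dat"), "rb")
    on.exit(close(con))
    raw <- readBin(con, "double", n = n, size = 8, endian = "little")
    radii <- raw[seq_len(meta$nRadii)]
    vals <- matrix(raw[-seq_len(meta$nRadii)], meta$nRadii, meta$nScans)
    tripleData(cell = meta$cell, channel = meta$channel,
               wavelength = meta$wavelength,
               grid = new("RadialGrid", points = radii), values = vals,
               scanTime = meta$scanTime, scanRpm = meta$scanRpm,
               scanOmega2t = meta$scanOmega2t,
               scanTemperature = meta$scanTemperature,
               signalKind = meta$signalKind)
}

#' List triples of an experiment
#' @param store an [AucStore-class]; @param runName experiment name.
#' @return Character vector of triple keys.
#' @export
listTriples <- function(store, runName) {
    d <- file.path(store@path, "experiments", runName, "triples")
    if (!dir.exists(d)) return(character(0))
    sub("\\.dat$", "", list.files(d, pattern = "\\.dat$"))
}

#' Store / load a timestate under an experiment
#' @param store an [AucStore-class]; @param runName experiment name.
#' @param ts a [TimeState-class].
#' @export
storeTimestate <- function(store, runName, ts) {
    d <- file.path(store@path, "experiments", runName)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    writeTimestateCsv(ts, file.path(d, "timestate.csv"))
    invisible(TRUE)
}

#' @rdname storeTimestate
#' @export
loadTimestate <- function(store, runName)
    readTimestateCsv(file.path(store@path, "experiments", runName,
                               "timestate.csv"))

#' Delete an experiment (cascading)
#'
#' Removes the experiment and all child artifacts (triples, edit profiles,
#' models, reports). Requires admin level. Frozen protocol profiles live
#' outside the experiment tree and are never deleted by the cascade.
#'
#' @param store an [AucStore-class]; @param runName experiment name.
#' @export
deleteExperiment <- function(store, runName) {
    if (store@userLevel != "admin")
        stop("permission denied: deletion requires admin level")
    unlink(file.path(store@path, "experiments", runName), recursive = TRUE)
    invisible(TRUE)
}

## ------------------------------ legacy ASCII -------------------------------

#' Read a legacy ASCII scan file
#'
#' The legacy dialect: line 1 is a free-text description; line 2 holds
#' whitespace-separated header fields in the order type-code, cell,
#' temperature (C), rpm, time (s), omega^2 t (rad^2/s), wavelength (nm); each
#' following row is `radius value [stddev]`. Parse failures name the
#' offending line.
#'
#' @param path file path.
#' @return A [Scan-class] with attribute `description`.
#' @export
readLegacyScan <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 3L)
        stop("truncated legacy scan file (", length(lines),
             " line(s)): need header plus data at line 3")
    hdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    if (length(hdr) < 7L)
        stop("parse error at line 2: expected 7 header fields, got ",
             length(hdr))
    num <- suppressWarnings(as.numeric(hdr[-1]))
    if (any(is.na(num)))
        stop("parse error at line 2: non-numeric header field")
    radii <- values <- numeric(0)
    for (i in 3:length(lines)) {
        if (!nzchar(trimws(lines[i]))) next
        f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                  "\\s+")[[1]]))
        if (length(f) < 2L || any(is.na(f[1:2])))
            stop("parse error at line ", i, ": expected numeric radius/value")
        radii <- c(radii, f[1]); values <- c(values, f[2])
    }
    if (any(diff(radii) <= 0))
        stop("parse error: radii are not strictly increasing")
    structure(new("Scan", radii = radii, values = values, time = num[4],
                  omega2t = num[5], rpm = num[3], temperature = num[2],
                  cell = as.integer(num[1]), wavelength = num[6]),
              description = lines[1])
}

#' Write a scan in the legacy ASCII dialect
#'
#' @param scan a [Scan-class].
#' @param path output path.
#' @param description free-text description line.
#' @param typeCode single-character data type code.
#' @export
writeLegacyScan <- function(scan, path, description = "aucflow export",
                            typeCode = "I") {
    hdr <- sprintf("%s %d %.1f %.0f %.0f %.7E %.0f", typeCode, scan@cell,
                   scan@temperature, scan@rpm, scan@time, scan@omega2t,
                   scan@wavelength)
    rows <- sprintf("%9.4f %12.5E", scan@radii, scan@values)
    writeLines(c(description, hdr, rows), path)
    invisible(path)
}

## ------------------------- profiles: store & freeze ------------------------

profileFile <- function(store, guid)
    file.path(store@path, "profiles", paste0(guid, ".json"))

# AnalysisProfile <-> plain list (JSON-able)
profileToList <- function(p) list(
    guid = p@guid, runName = p@runName, temperature = p@temperature,
    readOnly = p@readOnly, radialRange = p@radialRange,
    radialStep = p@radialStep,
    rotorCalibration = p@rotorCalibration@stretchCoeffs,
    speedSteps = lapply(p@speedSteps, function(s) list(
        setRpm = s@setRpm, rampRate = s@rampRate, duration = s@duration,
        scanInterval = s@scanInterval, initialDelay = s@initialDelay)),
    centerpieces = lapply(p@centerpieces, function(cp) list(
        sectorAngle = cp@sectorAngle, pathlength = cp@pathlength,
        baseBottom = cp@baseBottom)),
    channels = lapply(p@channels, function(ch) list(
        cell = ch@cell, channel = ch@channel,
        loadingVolume = ch@loadingVolume,
        volumeTolerance = ch@volumeTolerance,
        concentrationRatio = ch@concentrationRatio,
        ratioTolerance = ch@ratioTolerance,
        rightDataLimit = ch@rightDataLimit, wavelengths = ch@wavelengths,
        solution = list(density = ch@solution@density,
                        viscosity = ch@solution@viscosity,
                        analytes = ch@solution@analytes))),
    workflow = list(sRange = p@workflow@sRange, sPoints = p@workflow@sPoints,
                    kRange = p@workflow@kRange, kPoints = p@workflow@kPoints,
                    gridSpacing = p@workflow@gridSpacing,
                    fitTI = p@workflow@fitTI, fitRI = p@workflow@fitRI,
                    fitMeniscus = p@workflow@fitMeniscus,
                    meniscusPoints = p@workflow@meniscusPoints,
                    meniscusSpan = p@workflow@meniscusSpan,
                    maxIterations = p@workflow@maxIterations,
                    monteCarlo = p@workflow@monteCarlo,
                    solverStep = p@workflow@solverStep,
                    subgridSize = p@workflow@subgridSize))

# `l` comes from jsonlite::read_json(..., simplifyVector = FALSE): every
# JSON array is a plain list and needs unlist().
profileFromList <- function(l) {
    wf <- do.call(fitWorkflowSpec, lapply(l$workflow, unlist))
    pick <- function(x, nm) unlist(lapply(x, `[[`, nm))
    new("AnalysisProfile", guid = l$guid, runName = l$runName,
        temperature = l$temperature,
        speedSteps = lapply(l$speedSteps, function(s)
            do.call(speedStep, lapply(s, unlist))),
        channels = lapply(l$channels, function(ch) channelSpec(
            cell = ch$cell, channel = ch$channel,
            solution = solution(density = ch$solution$density,
                                viscosity = ch$solution$viscosity,
                                vbar = pick(ch$solution$analytes, "vbar"),
                                extinction = pick(ch$solution$analytes,
                                                  "extinction"),
                                molarRatio = pick(ch$solution$analytes,
                                                  "molarRatio")),
            loadingVolume = ch$loadingVolume,
            volumeTolerance = ch$volumeTolerance,
            concentrationRatio = ch$concentrationRatio,
            ratioTolerance = ch$ratioTolerance,
            rightDataLimit = ch$rightDataLimit,
            wavelengths = unlist(ch$wavelengths))),
        centerpieces = lapply(l$centerpieces, function(cp)
            centerpiece(cp$sectorAngle, cp$pathlength, cp$baseBottom)),
        rotorCalibration = rotorCalibration(unlist(l$rotorCalibration)),
        workflow = wf, radialRange = unlist(l$radialRange),
        radialStep = l$radialStep, readOnly = l$readOnly)
}

#' Persist / load an analysis profile
#'
#' Writing over a stored frozen profile is a permission error at any user
#' level: a frozen GMP protocol is immutable through the store API and can
#' only be superseded via [mutateFrozen()] (new GUID, new run name).
#'
#' @param store an [AucStore-class].
#' @param profile an [AnalysisProfile-class] with a GUID (see
#'   [freezeProfile()]; unfrozen drafts get one on first store).
#' @export
storeProfile <- function(store, profile) {
    if (!nzchar(profile@guid)) profile@guid <- newGuid()
    f <- profileFile(store, profile@guid)
    if (file.exists(f)) {
        old <- jsonlite::read_json(f, simplifyVector = TRUE)
        if (isTRUE(old$readOnly))
            stop("permission denied: profile ", profile@guid,
                 " is frozen (read-only)")
    }
    if (profile@readOnly && store@userLevel == "operator")
        stop("permission denied: storing a frozen profile requires designer level")
    jsonlite::write_json(profileToList(profile), f, digits = NA,
                         auto_unbox = TRUE)
    invisible(profile@guid)
}

#' @rdname storeProfile
#' @param guid profile GUID.
#' @export
loadProfile <- function(store, guid) {
    f <- profileFile(store, guid)
    if (!file.exists(f)) stop("profile ", guid, " not found")
    profileFromList(jsonlite::read_json(f, simplifyVector = FALSE))
}

#' List run names known to the store
#' @param store an [AucStore-class].
#' @return Character vector of run names (stored profiles and experiments).
#' @export
listRunNames <- function(store) {
    profs <- list.files(file.path(store@path, "profiles"),
                        pattern = "\\.json$", full.names = TRUE)
    nm <- vapply(profs, function(f)
        jsonlite::read_json(f, simplifyVector = TRUE)$runName %||% "",
        character(1))
    unique(c(nm[nzchar(nm)],
             list.dirs(file.path(store@path, "experiments"),
                       recursive = FALSE, full.names = FALSE)))
}

#' Check an analysis profile for completeness
#'
#' Returns a character vector of violations (empty when the profile is ready
#' for submission): every channel needs a solution, a loading volume,
#' wavelengths, a right data limit and a centerpiece; the profile needs speed
#' steps and a rotor calibration; a run name already used in the store is
#' reported as a duplicate.
#'
#' @param profile an [AnalysisProfile-class].
#' @param store optional [AucStore-class] for the duplicate-name check.
#' @return Character vector of violations.
#' @export
validateProfile <- function(profile, store = NULL) {
    v <- character(0)
    if (!length(profile@speedSteps)) v <- c(v, "no speed steps defined")
    for (ch in profile@channels) {
        id <- paste0(ch@cell, ch@channel)
        if (!length(ch@loadingVolume) || is.na(ch@loadingVolume))
            v <- c(v, paste("missing loading volume for channel", id))
        if (!length(ch@wavelengths))
            v <- c(v, paste("no wavelengths for channel", id))
        if (!length(ch@rightDataLimit) || is.na(ch@rightDataLimit))
            v <- c(v, paste("missing right data limit for channel", id))
        if (is.null(profile@centerpieces[[as.character(ch@cell)]]))
            v <- c(v, paste("no centerpiece for cell", ch@cell))
    }
    if (!is.null(store)) {
        profs <- list.files(file.path(store@path, "profiles"),
                            pattern = "\\.json$", full.names = TRUE)
        for (f in profs) {
            l <- jsonlite::read_json(f, simplifyVector = TRUE)
            if (identical(l$runName, profile@runName) &&
                !identical(l$guid, profile@guid)) {
                v <- c(v, paste0("duplicate run name '", profile@runName, "'"))
                break
            }
        }
    }
    v
}

#' Freeze an analysis profile (GMP read-only)
#'
#' Assigns a GUID (if absent) and marks the profile read-only. Further field
#' writes through [`profileField<-`] or store overwrites are permission
#' errors; a derived change must go through [mutateFrozen()].
#'
#' @param profile an [AnalysisProfile-class].
#' @return The frozen profile.
#' @export
freezeProfile <- function(profile) {
    if (!nzchar(profile@guid)) profile@guid <- newGuid()
    profile@readOnly <- TRUE
    profile
}

#' Modify a profile field, respecting freeze semantics
#'
#' @param profile an [AnalysisProfile-class].
#' @param name slot name.
#' @param value new value.
#' @return The updated profile; writing to a frozen profile is an error.
#' @export
`profileField<-` <- function(profile, name, value) {
    if (profile@readOnly)
        stop("permission denied: profile '", profile@runName,
             "' is frozen; derive a new profile with mutateFrozen()")
    slot(profile, name) <- value
    profile
}

#' Derive a new profile from a frozen one
#'
#' The GMP path for changing a frozen protocol: a copy with the requested
#' changes, a fresh GUID and a new run name. A change set that leaves the
#' content identical still receives a new GUID (conservative: identity of a
#' GMP protocol is its GUID, not its content).
#'
#' @param profile a frozen [AnalysisProfile-class].
#' @param changes named list of slot values to replace (may be empty).
#' @param newRunName run name for the derived profile (must differ).
#' @return An unfrozen derived [AnalysisProfile-class] with a new GUID.
#' @export
mutateFrozen <- function(profile, changes = list(), newRunName) {
    if (!profile@readOnly) stop("profile is not frozen; edit it directly")
    if (missing(newRunName) || identical(newRunName, profile@runName))
        stop("a derived profile requires a new run name")
    out <- profile
    out@readOnly <- FALSE
    for (nm in names(changes)) slot(out, nm) <- changes[[nm]]
    out@runName <- newRunName
    out@guid <- newGuid()
    out
}

## --------------------------- edit profiles & models ------------------------

#' Persist / load an edit profile
#' @param store an [AucStore-class]; @param runName experiment name.
#' @param edit an [EditProfile-class].
#' @export
storeEditProfile <- function(store, runName, edit) {
    d <- file.path(store@path, "experiments", runName, "edits")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    key <- tripleKey(edit@cell * 1.0, edit@channel, edit@wavelength)
    jsonlite::write_json(list(
        cell = edit@cell, channel = edit@channel,
        wavelength = edit@wavelength, meniscus = edit@meniscus,
        leftLimit = edit@leftLimit, rightLimit = edit@rightLimit,
        baseline = edit@baseline, plateau = edit@plateau,
        gridStep = edit@gridStep),
        file.path(d, paste0(key, ".json")), digits = NA, auto_unbox = TRUE)
    invisible(key)
}

#' @rdname storeEditProfile
#' @param cell,channel,wavelength triple identity.
#' @export
loadEditProfile <- function(store, runName, cell, channel, wavelength) {
    key <- tripleKey(cell * 1.0, channel, wavelength)
    f <- file.path(store@path, "experiments", runName, "edits",
                   paste0(key, ".json"))
    if (!file.exists(f)) stop("edit profile ", key, " not found")
    l <- jsonlite::read_json(f, simplifyVector = TRUE)
    new("EditProfile", cell = as.integer(l$cell), channel = l$channel,
        wavelength = l$wavelength, meniscus = l$meniscus,
        leftLimit = l$leftLimit, rightLimit = l$rightLimit,
        baseline = l$baseline, plateau = l$plateau, gridStep = l$gridStep)
}

#' Persist / load a fitted model
#'
#' The species table goes to CSV (one row per species), the noise vectors and
#' scalars to a JSON sidecar.
#'
#' @param store an [AucStore-class]; @param runName experiment name.
#' @param model a [ModelRecord-class].
#' @param label file label (e.g. triple key + stage index).
#' @export
storeModel <- function(store, runName, model, label) {
    d <- file.path(store@path, "experiments", runName, "models")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(model@species, file.path(d, paste0(label, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(
        rmsd = model@rmsd, meniscus = model@meniscus, stage = model@stage,
        iterations = model@iterations, tiNoise = model@tiNoise,
        riNoise = model@riNoise, mcStats = model@mcStats),
        file.path(d, paste0(label, ".json")), digits = NA, auto_unbox = TRUE)
    invisible(label)
}

#' @rdname storeModel
#' @param label file label used at store time.
#' @export
loadModel <- function(store, runName, label) {
    d <- file.path(store@path, "experiments", runName, "models")
    f <- file.path(d, paste0(label, ".json"))
    if (!file.exists(f)) stop("model ", label, " not found")
    l <- jsonlite::read_json(f, simplifyVector = TRUE)
    sp <- utils::read.csv(file.path(d, paste0(label, ".csv")))
    mc <- if (length(l$mcStats)) as.data.frame(l$mcStats) else data.frame()
    new("ModelRecord", species = sp, rmsd = l$rmsd,
        tiNoise = as.numeric(l$tiNoise), riNoise = as.numeric(l$riNoise),
        meniscus = l$meniscus, stage = l$stage,
        iterations = as.integer(l$iterations), mcStats = mc)
}
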