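## Autoflow supervisor: a persistent state machine tracking each experiment
## through the staged workflow, with session locking and reattachment.

AUTOFLOW_STAGES <- c("DESIGN", "LIVE_UPDATE", "IMPORT", "EDITING",
                     "ANALYSIS", "REPORT", "DONE")

# event -> (required current status, next status)
AUTOFLOW_EVENTS <- list(
    "data-complete"     = c("LIVE_UPDATE", "IMPORT"),
    "import-complete"   = c("IMPORT",      "EDITING"),
    "edit-complete"     = c("EDITING",     "ANALYSIS"),
    "analysis-complete" = c("ANALYSIS",    "REPORT"),
    "report-written"    = c("REPORT",      "DONE"))

#' Autoflow event vocabulary
#'
#' The events that advance a run through
#' LIVE_UPDATE -> IMPORT -> EDITING -> ANALYSIS -> REPORT -> DONE, in order.
#' @return Character vector of event names.
#' @export
autoflowEvents <- function() names(AUTOFLOW_EVENTS)

recordFile <- function(store, runName)
    file.path(store@path, "autoflow", paste0(runName, ".json"))

journalFile <- function(store) file.path(store@path, "autoflow", "journal.tsv")

journalAppend <- function(store, runName, event, old, new, session = "") {
    line <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), runName, event,
                  old, new, session, sep = "\t")
    cat(line, "\n", sep = "", file = journalFile(store), append = TRUE)
}

persistRecord <- function(store, rec) {
    jsonlite::write_json(list(
        runName = rec@runName, profileGuid = rec@profileGuid,
        instrument = rec@instrument, status = rec@status,
        timestamps = as.list(rec@timestamps), lock = rec@lock,
        note = rec@note),
        recordFile(store, rec@runName), digits = NA, auto_unbox = TRUE)
    invisible(rec)
}

loadRecord <- function(store, runName) {
    f <- recordFile(store, runName)
    if (!file.exists(f)) stop("no autoflow record for run '", runName, "'")
    l <- jsonlite::read_json(f, simplifyVector = TRUE)
    new("AutoflowRecord", runName = l$runName, profileGuid = l$profileGuid,
        instrument = l$instrument, status = l$status,
        timestamps = unlist(l$timestamps) %||% stats::setNames(numeric(0),
                                                               character(0)),
        lock = l$lock, note = l$note)
}

#' Submit a frozen profile to an instrument
#'
#' Creates the autoflow record in status LIVE_UPDATE. Requires a frozen,
#' complete profile and an idle instrument (at most one live -- non-DONE --
#' record per instrument); a busy instrument is refused naming the blocking
#' run.
#'
#' @param store an [AucStore-class].
#' @param profile a frozen, valid [AnalysisProfile-class].
#' @param instrument instrument identifier.
#' @return The persisted [AutoflowRecord-class].
#' @export
submitRun <- function(store, profile, instrument) {
    if (!profile@readOnly)
        stop("GMP submission requires a frozen profile; call freezeProfile()")
    viol <- validateProfile(profile)
    if (length(viol))
        stop("profile incomplete: ", paste(viol, collapse = "; "))
    for (rec in reattachRuns(store))
        if (rec@instrument == instrument)
            stop("instrument '", instrument, "' is busy with run '",
                 rec@runName, "'")
    rec <- new("AutoflowRecord", runName = profile@runName,
               profileGuid = profile@guid, instrument = instrument,
               status = "LIVE_UPDATE",
               timestamps = c(LIVE_UPDATE = as.numeric(Sys.time())),
               lock = "", note = "")
    journalAppend(store, rec@runName, "submit", "DESIGN", "LIVE_UPDATE")
    persistRecord(store, rec)
}

#' Advance an autoflow record by one workflow event
#'
#' Only the event matching the current status is legal; out-of-order events
#' raise an illegal-transition error and leave the record unchanged. The
#' transition timestamp is recorded and journaled.
#'
#' @param store an [AucStore-class].
#' @param record an [AutoflowRecord-class] (or run name).
#' @param event one of [autoflowEvents()].
#' @return The updated, persisted record.
#' @export
advanceRun <- function(store, record, event) {
    if (is.character(record)) record <- loadRecord(store, record)
    tr <- AUTOFLOW_EVENTS[[event]]
    if (is.null(tr)) stop("unknown autoflow event '", event, "'")
    if (record@status != tr[1])
        stop("illegal transition: event '", event, "' requires status ",
             tr[1], " but run '", record@runName, "' is in ", record@status)
    record@status <- tr[2]
    record@timestamps <- c(record@timestamps,
                           stats::setNames(as.numeric(Sys.time()), tr[2]))
    journalAppend(store, record@runName, event, tr[1], tr[2], record@lock)
    persistRecord(store, record)
}

#' Acquire or release the session lock of a run
#'
#' A session GUID prevents two operators from concurrently importing or
#' advancing the same run. The lock is granted when free or already held by
#' the same session; release is idempotent. Lock state persists across
#' process restarts.
#'
#' @param store an [AucStore-class].
#' @param record an [AutoflowRecord-class] (or run name).
#' @param sessionGuid session identifier.
#' @return The updated record.
#' @export
acquireLock <- function(store, record, sessionGuid) {
    if (is.character(record)) record <- loadRecord(store, record)
    if (nzchar(record@lock) && record@lock != sessionGuid)
        stop("run '", record@runName, "' is locked by session ", record@lock)
    record@lock <- sessionGuid
    journalAppend(store, record@runName, "lock", record@status,
                  record@status, sessionGuid)
    persistRecord(store, record)
}

#' @rdname acquireLock
#' @export
releaseLock <- function(store, record, sessionGuid) {
    if (is.character(record)) record <- loadRecord(store, record)
    if (nzchar(record@lock) && record@lock != sessionGuid)
        stop("run '", record@runName, "' is locked by session ", record@lock)
    if (nzchar(record@lock))
        journalAppend(store, record@runName, "unlock", record@status,
                      record@status, sessionGuid)
    record@lock <- ""
    persistRecord(store, record)
}

#' Reattach to unfinished runs
#'
#' Lists every non-DONE autoflow record in the store with enough context
#' (status, profile GUID, instrument, lock) to resume its stage -- the
#' recovery path after a client crash or restart.
#'
#' @param store an [AucStore-class].
#' @return List of [AutoflowRecord-class].
#' @export
reattachRuns <- function(store) {
    fs <- list.files(file.path(store@path, "autoflow"),
                     pattern = "\\.json$", full.names = FALSE)
    recs <- lapply(sub("\\.json$", "", fs), function(rn)
        loadRecord(store, rn))
    Filter(function(r) r@status != "DONE", recs)
}

#' Abandon a run
#'
#' Allowed only from LIVE_UPDATE or IMPORT (data not yet committed) and only
#' at admin level; the journal retains the full history.
#'
#' @param store an [AucStore-class].
#' @param record an [AutoflowRecord-class] (or run name).
#' @export
abandonRun <- function(store, record) {
    if (is.character(record)) record <- loadRecord(store, record)
    if (store@userLevel != "admin")
        stop("permission denied: abandoning a run requires admin level")
    if (!record@status %in% c("LIVE_UPDATE", "IMPORT"))
        stop("runs can only be abandoned from LIVE_UPDATE or IMPORT, not ",
             record@status)
    journalAppend(store, record@runName, "abandon", record@status, "ABANDONED")
    unlink(recordFile(store, record@runName))
    invisible(TRUE)
}
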