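#' Electrode labels of the 60-electrode MEA grid
#'
#' Standard 8x8 MEA layout labelled in row-column style ("12" = row 1,
#' column 2) with the four corner positions (11, 18, 81, 88) absent, giving
#' 60 recording electrodes.
#'
#' @return Character vector of the 60 valid electrode labels, sorted.
#' @examples
#' length(electrodeLabels())  # 60
#' @export
electrodeLabels <- function() {
  labs <- as.vector(outer(1:8, 1:8, function(r, c) paste0(r, c)))
  sort(setdiff(labs, c("11", "18", "81", "88")))
}

#' MEARecording: per-electrode spike-time recording
#'
#' An S4 container for one MEA recording session: a named list of sorted
#' spike-time vectors (seconds), one per electrode, plus recording-level
#' metadata. This is the common currency between the network simulator, the
#' synthetic generator and the burst detector. Spike times are stored in
#' seconds as real numbers; the nominal acquisition rate (default 25 kHz) is
#' carried as metadata only, since all analysis operates on detected spike
#' times rather than voltage traces.
#'
#' @slot recordingId character, identifier for the session.
#' @slot duration numeric, recording length in seconds (default 600).
#' @slot sampleRate numeric, nominal acquisition rate in Hz (metadata only).
#' @slot spikes named list of numeric vectors; names are electrode labels
#'   from [electrodeLabels()], values are ascending spike times in seconds.
#' @slot condition character, biological condition label (NA if unset).
#' @slot dayFromInduction integer, days from neuronal induction (NA if unset).
#' @slot replicateId character, biological replicate label (NA if unset).
#'
#' @seealso [MEARecording()] for the validating constructor,
#'   [validateRecording()], [readSpikeTable()], [runDetector()].
#' @name MEARecording-class
#' @aliases MEARecording-class
#' @exportClass MEARecording
setClass("MEARecording",
  slots = c(
    recordingId = "character",
    duration = "numeric",
    sampleRate = "numeric",
    spikes = "list",
    condition = "character",
    dayFromInduction = "integer",
    replicateId = "character"
  ),
  prototype = list(
    recordingId = "rec", duration = 600, sampleRate = 25000,
    spikes = list(), condition = NA_character_,
    dayFromInduction = NA_integer_, replicateId = NA_character_
  )
)

setValidity("MEARecording", function(object) {
  msgs <- character(0)
  if (length(object@duration) != 1 || is.na(object@duration) ||
      object@duration <= 0)
    msgs <- c(msgs, "duration must be a single positive number")
  if (length(object@spikes) > 60)
    msgs <- c(msgs, "at most 60 electrode channels are allowed")
  if (length(object@spikes) > 0 && is.null(names(object@spikes)))
    msgs <- c(msgs, "spikes must be a named list keyed by electrode label")
  if (!all(vapply(object@spikes, is.numeric, logical(1))))
    msgs <- c(msgs, "all spike-time vectors must be numeric")
  if (length(msgs)) msgs else TRUE
})

#' Construct an MEARecording
#'
#' Validating constructor: channels are ordered by electrode label and spike
#' times are sorted ascending (sorting is the only repair applied). Spike
#' times outside `[0, duration]`, duplicate electrode labels or labels
#' outside the 60-electrode grid are errors.
#'
#' @param spikes named list of numeric spike-time vectors (seconds); names
#'   must be labels from [electrodeLabels()].
#' @param duration recording length in seconds.
#' @param recordingId identifier string.
#' @param condition optional condition label.
#' @param dayFromInduction optional integer day.
#' @param replicateId optional replicate label.
#' @param sampleRate nominal acquisition rate in Hz (metadata only).
#' @return A validated [MEARecording-class] object.
#' @examples
#' rec <- MEARecording(list("12" = c(0.5, 0.2)), duration = 10)
#' spikeTimes(rec, "12")  # 0.2 0.5
#' @export
MEARecording <- function(spikes = list(), duration = 600,
                         recordingId = "rec", condition = NA,
                         dayFromInduction = NA, replicateId = NA,
                         sampleRate = 25000) {
  if (length(spikes) > 0) {
    ids <- names(spikes)
    if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
      stop("every channel must be named with an electrode label")
    bad <- setdiff(ids, electrodeLabels())
    if (length(bad))
      stop("invalid electrode label(s): ", paste(bad, collapse = ", "),
           " (grid is 8x8 minus corners 11, 18, 81, 88)")
    if (anyDuplicated(ids))
      stop("duplicate electrode label(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    spikes <- lapply(spikes, function(t) sort(as.numeric(t)))
    oob <- vapply(spikes, function(t)
      length(t) > 0 && (min(t) < 0 || max(t) > duration), logical(1))
    if (any(oob))
      stop("spike times outside [0, duration] on electrode(s): ",
           paste(ids[oob], collapse = ", "))
    spikes <- spikes[order(ids)]
  }
  new("MEARecording",
      recordingId = as.character(recordingId),
      duration = as.numeric(duration),
      sampleRate = as.numeric(sampleRate),
      spikes = spikes,
      condition = as.character(condition),
      dayFromInduction = as.integer(dayFromInduction),
      replicateId = as.character(replicateId))
}

#' @rdname synchroburst-generics
#' @export
setMethod("recordingDuration", "MEARecording", function(x) x@duration)

#' @rdname synchroburst-generics
#' @export
setMethod("electrodeIds", "MEARecording", function(x) names(x@spikes))

#' @describeIn MEARecording-class spike times of one electrode
#'   (`electrode` given) or the full named list.
#' @param x,electrode object and electrode label.
#' @export
setMethod("spikeTimes", "MEARecording", function(x, electrode = NULL) {
  if (is.null(electrode)) return(x@spikes)
  if (!electrode %in% names(x@spikes))
    stop("no channel for electrode ", electrode)
  x@spikes[[electrode]]
})

#' @rdname synchroburst-generics
#' @export
setMethod("nSpikes", "MEARecording", function(x)
  sum(vapply(x@spikes, length, integer(1))))

#' @rdname synchroburst-generics
#' @export
setMethod("conditionLabel", "MEARecording", function(x) x@condition)

setMethod("show", "MEARecording", function(object) {
  cat("MEARecording '", object@recordingId, "'\n", sep = "")
  cat("  duration: ", object@duration, " s | channels: ",
      length(object@spikes), " | spikes: ", nSpikes(object), "\n", sep = "")
  if (!is.na(object@condition))
    cat("  condition: ", object@condition, "\n", sep = "")
  if (!is.na(object@dayFromInduction))
    cat("  day from induction: ", object@dayFromInduction, "\n", sep = "")
  if (!is.na(object@replicateId))
    cat("  replicate: ", object@replicateId, "\n", sep = "")
})

#' ValidationReport: outcome of checking an MEARecording
#'
#' @slot ok logical; `TRUE` iff `issues` has no rows.
#' @slot issues data.frame with columns `electrodeId` and `message`.
#' @name ValidationReport-class
#' @exportClass ValidationReport
setClass("ValidationReport",
  slots = c(ok = "logical", issues = "data.frame"),
  prototype = list(
    ok = TRUE,
    issues = data.frame(electrodeId = character(0), message = character(0))
  )
)

setValidity("ValidationReport", function(object) {
  if (object@ok != (nrow(object@issues) == 0))
    "ok must be TRUE exactly when issues is empty"
  else TRUE
})

setMethod("show", "ValidationReport", function(object) {
  if (object@ok) cat("ValidationReport: OK\n")
  else {
    cat("ValidationReport:", nrow(object@issues), "issue(s)\n")
    for (i in seq_len(nrow(object@issues)))
      cat("  [", object@issues$electrodeId[i], "] ",
          object@issues$message[i], "\n", sep = "")
  }
})

#' Validate an MEARecording
#'
#' Pure check that reports (never repairs, never raises) structural problems
#' of a recording: spike times that are unsorted, `NA`/non-finite or outside
#' `[0, duration]`, duplicate or invalid electrode labels. Objects built via
#' [MEARecording()] always validate clean; this guards recordings assembled
#' by other means.
#'
#' @param rec an [MEARecording-class].
#' @return A [ValidationReport-class].
#' @examples
#' validateRecording(MEARecording(list("12" = 1:3), duration = 10))
#' @export
validateRecording <- function(rec) {
  stopifnot(is(rec, "MEARecording"))
  issues <- list()
  add <- function(id, msg)
    issues[[length(issues) + 1]] <<- data.frame(electrodeId = id,
                                                message = msg)
  ids <- names(rec@spikes)
  if (length(rec@spikes) > 0 && is.null(ids)) {
    add("<recording>", "channels are unnamed")
    ids <- rep("", length(rec@spikes))
  }
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add(d, "duplicate electrode label")
  for (b in setdiff(unique(ids), electrodeLabels()))
    add(b, "not a valid electrode label on the 60-electrode grid")
  for (k in seq_along(rec@spikes)) {
    t <- rec@spikes[[k]]
    id <- if (length(ids) >= k) ids[k] else "<unnamed>"
    if (length(t) == 0) next
    if (anyNA(t) || any(!is.finite(t))) {
      add(id, "non-finite spike times"); next
    }
    if (is.unsorted(t)) add(id, "spike times not sorted ascending")
    if (min(t) < 0 || max(t) > rec@duration)
      add(id, sprintf("spike times outside [0, %g] s", rec@duration))
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(electrodeId = character(0), message = character(0))
  new("ValidationReport", ok = nrow(issues) == 0, issues = issues)
}
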