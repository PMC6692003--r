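#' @name synchroburst-generics
#' @title Accessor generics
#'
#' @description Small accessor generics shared by the package's S4 classes.
#' `recordingDuration` returns the recording (or simulation) length in
#' seconds, `electrodeIds` the electrode labels present, `spikeTimes` the
#' sorted spike times (seconds) of one electrode or all of them,
#' `nSpikes` total spike counts, `conditionLabel` the condition metadata
#' string, `sbpm` the synchronous-bursts-per-minute statistic and
#' `networkBursts` the table of detected network bursts.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return See the method for each class.
NULL

#' @rdname synchroburst-generics
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname synchroburst-generics
#' @export
setGeneric("electrodeIds", function(x) standardGeneric("electrodeIds"))

#' @rdname synchroburst-generics
#' @export
setGeneric("spikeTimes", function(x, ...) standardGeneric("spikeTimes"))

#' @rdname synchroburst-generics
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname synchroburst-generics
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname synchroburst-generics
#' @export
setGeneric("sbpm", function(x) standardGeneric("sbpm"))

#' @rdname synchroburst-generics
#' @export
setGeneric("networkBursts", function(x) standardGeneric("networkBursts"))
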