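## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' @name accessors
#' @title Accessors for kineticGC objects
#' @description `scenario()` returns the collection scenario of a
#'   configuration or result; `cloneTable()` the clone definitions;
#'   `timeSeries()`, `cellEvents()` and `ocLog()` the tabular outputs of a
#'   run; `agLedger()` the antigen-conservation and cell-bookkeeping ledger;
#'   `runSeed()` the seed a result was produced with.
#' @param x a [GCConfig-class] or [GCResult-class] object.
#' @return the corresponding slot content (data.frame, numeric vector or
#'   scalar; see the class documentation).
#' @examples
#' cfg <- smallGCConfig(scenario = 1)
#' scenario(cfg)
#' cloneTable(cfg)
NULL

#' @rdname accessors
#' @export
setGeneric("scenario", function(x) standardGeneric("scenario"))
#' @rdname accessors
#' @export
setGeneric("cloneTable", function(x) standardGeneric("cloneTable"))
#' @rdname accessors
#' @export
setGeneric("timeSeries", function(x) standardGeneric("timeSeries"))
#' @rdname accessors
#' @export
setGeneric("cellEvents", function(x) standardGeneric("cellEvents"))
#' @rdname accessors
#' @export
setGeneric("ocLog", function(x) standardGeneric("ocLog"))
#' @rdname accessors
#' @export
setGeneric("agLedger", function(x) standardGeneric("agLedger"))
#' @rdname accessors
#' @export
setGeneric("runSeed", function(x) standardGeneric("runSeed"))

#' @rdname accessors
setMethod("scenario", "GCConfig", function(x) x@scenario)
#' @rdname accessors
setMethod("scenario", "GCResult", function(x) x@config@scenario)
#' @rdname accessors
setMethod("cloneTable", "GCConfig", function(x) x@clones)
#' @rdname accessors
setMethod("cloneTable", "GCResult", function(x) x@config@clones)
#' @rdname accessors
setMethod("timeSeries", "GCResult", function(x) x@timeSeries)
#' @rdname accessors
setMethod("cellEvents", "GCResult", function(x) x@cellEvents)
#' @rdname accessors
setMethod("ocLog", "GCResult", function(x) x@ocLog)
#' @rdname accessors
setMethod("agLedger", "GCResult", function(x) x@ledger)
#' @rdname accessors
setMethod("runSeed", "GCResult", function(x) x@seed)
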