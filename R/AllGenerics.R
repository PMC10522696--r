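#' @include AllClasses.R
NULL

#' Accessors for lamsel classes
#'
#' Small accessor generics so downstream code never touches slots.
#'
#' @param x a lamsel object.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("lfp", function(x, ...) standardGeneric("lfp"))
#' @rdname accessors
#' @export
setGeneric("mua", function(x, ...) standardGeneric("mua"))
#' @rdname accessors
#' @export
setGeneric("trialTable", function(x, ...) standardGeneric("trialTable"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x, ...) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("timeZero", function(x, ...) standardGeneric("timeZero"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x, ...) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("csdValues", function(x, ...) standardGeneric("csdValues"))
#' @rdname accessors
#' @export
setGeneric("validChannels", function(x, ...) standardGeneric("validChannels"))
#' @rdname accessors
#' @export
setGeneric("markerChannel", function(x, ...) standardGeneric("markerChannel"))
#' @rdname accessors
#' @export
setGeneric("compartments", function(x, ...) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setGeneric("selectionFreq", function(x, ...) standardGeneric("selectionFreq"))
#' @rdname accessors
#' @export
setGeneric("popSizes", function(x, ...) standardGeneric("popSizes"))
#' @rdname accessors
#' @export
setGeneric("chanceBounds", function(x, ...) standardGeneric("chanceBounds"))
#' @rdname accessors
#' @export
setGeneric("selectionTimes", function(x, ...) standardGeneric("selectionTimes"))
#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(x, ...) standardGeneric("posteriorDraws"))
#' @rdname accessors
#' @export
setGeneric("posteriorMedians", function(x, ...) standardGeneric("posteriorMedians"))
#' @rdname accessors
#' @export
setGeneric("credibleInterval89", function(x, ...) standardGeneric("credibleInterval89"))
#' @rdname accessors
#' @export
setGeneric("bayesR2", function(x, ...) standardGeneric("bayesR2"))
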