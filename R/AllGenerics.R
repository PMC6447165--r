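#' @name tpscan-generics
#' @title Generics defined by tpscan
#' @description S4 generics for the TP-walk pipeline; see the methods for
#'   details: [tpSequence()], [tpWalk()], [driftProfile()],
#'   [scanSequence()].
NULL

#' @rdname tpSequence
#' @export
setGeneric("tpSequence", function(x, ...) standardGeneric("tpSequence"))

#' @rdname tpWalk
#' @export
setGeneric("tpWalk", function(x, ...) standardGeneric("tpWalk"))

#' @rdname driftProfile
#' @export
setGeneric("driftProfile",
  function(x, window, mode = "drift-magnitude", ...)
    standardGeneric("driftProfile"))

#' @rdname scanSequence
#' @export
setGeneric("scanSequence",
  function(x, params = SegmentationParams(), ...)
    standardGeneric("scanSequence"))

#' @rdname accessors
#' @export
setGeneric("tpCounts", function(x) standardGeneric("tpCounts"))

#' @rdname accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @rdname accessors
#' @export
setGeneric("walkPositions", function(x) standardGeneric("walkPositions"))

#' @rdname accessors
#' @export
setGeneric("stepMoved", function(x) standardGeneric("stepMoved"))

#' @rdname accessors
#' @export
setGeneric("realPart", function(x) standardGeneric("realPart"))

#' @rdname accessors
#' @export
setGeneric("imagPart", function(x) standardGeneric("imagPart"))

#' @rdname netDisplacement
#' @export
setGeneric("netDisplacement", function(x) standardGeneric("netDisplacement"))
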