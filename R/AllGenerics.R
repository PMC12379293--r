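#' @rdname PulseSeries-class
#' @param x a PulseSeries or CandidateEvents object.
#' @export
setGeneric("pulseRecords", function(x) standardGeneric("pulseRecords"))

#' @rdname PulseSeries-class
#' @export
setGeneric("nPulses", function(x) standardGeneric("nPulses"))

#' @rdname PulseSeries-class
#' @export
setGeneric("startDatetime", function(x) standardGeneric("startDatetime"))

#' @rdname PulseSeries-class
#' @param value replacement value.
#' @export
setGeneric("startDatetime<-", function(x, value) standardGeneric("startDatetime<-"))

#' @rdname PulseSeries-class
#' @export
setGeneric("thresholdDb", function(x) standardGeneric("thresholdDb"))

#' @rdname CandidateEvents-class
#' @param x a CandidateEvents object.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname CandidateEvents-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname CandidateEvents-class
#' @export
setGeneric("passedEvents", function(x) standardGeneric("passedEvents"))

#' @rdname CandidateEvents-class
#' @export
setGeneric("pulseIndices", function(x) standardGeneric("pulseIndices"))

#' @rdname CandidateEvents-class
#' @export
setGeneric("eventSeries", function(x) standardGeneric("eventSeries"))

#' @rdname featureImportances
#' @export
setGeneric("featureImportances", function(model, ...) standardGeneric("featureImportances"))
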