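#' @include AllClasses.R
NULL

#' Imposed turns of an object
#' @param x A [Trace], [ForceRamp] or [VarianceProfile].
#' @return Signed number of imposed turns.
#' @export
setGeneric("turns", function(x) standardGeneric("turns"))

#' @rdname turns
#' @export
setMethod("turns", "Trace", function(x) x@turns)
#' @rdname turns
#' @export
setMethod("turns", "ForceRamp", function(x) x@turns)
#' @rdname turns
#' @export
setMethod("turns", "VarianceProfile", function(x) x@turns)

#' Force grid of a ramp or profile
#' @param x A [ForceRamp] or [VarianceProfile].
#' @return Numeric vector of forces in pN.
#' @export
setGeneric("forceGrid", function(x) standardGeneric("forceGrid"))

#' @rdname forceGrid
#' @export
setMethod("forceGrid", "ForceRamp", function(x) x@forceGrid)
#' @rdname forceGrid
#' @export
setMethod("forceGrid", "VarianceProfile", function(x) x@force)

#' Traces of a force ramp
#' @param x A [ForceRamp].
#' @return List of [Trace] objects.
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname traces
#' @export
setMethod("traces", "ForceRamp", function(x) x@traces)

#' Time stamps of a trace
#' @param x A [Trace].
#' @return Numeric vector of times in s.
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' @rdname traceTime
#' @export
setMethod("traceTime", "Trace", function(x) x@time)

#' Extension samples of a trace
#' @param x A [Trace].
#' @return Numeric vector of extensions in nm.
#' @export
setGeneric("traceExtension", function(x) standardGeneric("traceExtension"))

#' @rdname traceExtension
#' @export
setMethod("traceExtension", "Trace", function(x) x@extension)

#' Peak-classification label
#' @param x A [PeakClassification].
#' @return `"no_peak"`, `"single"` or `"double"`.
#' @export
setGeneric("peakLabel", function(x) standardGeneric("peakLabel"))

#' @rdname peakLabel
#' @export
setMethod("peakLabel", "PeakClassification", function(x) x@label)

#' Characteristic forces of a classification
#' @param x A [PeakClassification].
#' @return Named numeric vector: `fC` for a single peak, `fC1`/`fC2` for a
#'   double peak, empty for no peak.
#' @export
setGeneric("characteristicForces",
           function(x) standardGeneric("characteristicForces"))

#' @rdname characteristicForces
#' @export
setMethod("characteristicForces", "PeakClassification", function(x) {
  switch(x@label,
         no_peak = stats::setNames(numeric(0), character(0)),
         single = c(fC = x@fC),
         double = c(fC1 = x@fC1, fC2 = x@fC2))
})
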