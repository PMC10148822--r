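#' Imaging protocol accessors
#'
#' Accessors for the acquisition protocol attached to an imaging session:
#' frame rate (Hz), number of global force-free baseline frames, the
#' pre/stimulus/post epoch layout, stimulus labels, field size and pixel
#' size.
#'
#' @param x An [ImagingProtocol-class], [ImagingSession-class] or
#'   [DffTraces-class] object.
#' @return The corresponding protocol component.
#' @name protocol-accessors
NULL

#' @rdname protocol-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname protocol-accessors
#' @export
setGeneric("stimulusLabels", function(x) standardGeneric("stimulusLabels"))

#' @rdname protocol-accessors
#' @export
setGeneric("epochLayout", function(x) standardGeneric("epochLayout"))

#' @rdname protocol-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname protocol-accessors
#' @export
setGeneric("fieldSize", function(x) standardGeneric("fieldSize"))

#' @rdname protocol-accessors
#' @export
setGeneric("imagingProtocol", function(x) standardGeneric("imagingProtocol"))

#' @export
#' @rdname ImagingSession-class
setGeneric("traces", function(x) standardGeneric("traces"))

#' @export
#' @rdname ImagingSession-class
setGeneric("neuronAreas", function(x) standardGeneric("neuronAreas"))

#' @export
#' @rdname computeDff
setGeneric("computeDff", function(x, ...) standardGeneric("computeDff"))

#' @export
#' @rdname CellMarkerTable-class
setGeneric("probeNames", function(x) standardGeneric("probeNames"))

#' @export
#' @rdname CellMarkerTable-class
setGeneric("markerData", function(x) standardGeneric("markerData"))
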