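# Accessor generics for the core containers. Slot access from user code is
# discouraged; these are the supported surface.

#' @rdname ThermalFrame-class
#' @param object,x a ThermalFrame
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname ThermalFrame-class
#' @export
setGeneric("timestamp", function(x) standardGeneric("timestamp"))

#' @rdname ThermalFrame-class
#' @export
setGeneric("emissivity", function(x) standardGeneric("emissivity"))

#' @rdname ThermalFrame-class
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname FrameSequence-class
#' @param x a FrameSequence
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname FrameSequence-class
#' @export
setGeneric("rois", function(x) standardGeneric("rois"))

#' @rdname FrameSequence-class
#' @export
setGeneric("cadence", function(x) standardGeneric("cadence"))

#' @rdname FrameSequence-class
#' @export
setGeneric("daySchedule", function(x) standardGeneric("daySchedule"))

#' Extract ROI pixel temperatures from a frame
#'
#' Returns the temperatures of every pixel inside the region, in row-major
#' order. For oval ROIs, a pixel belongs to the region when its centre falls
#' inside the ellipse inscribed in the bounding box; for rectangles and
#' point cursors, every pixel of the bounding box belongs.
#'
#' @param frame a [ThermalFrame-class].
#' @param roi a [RegionOfInterest-class] lying within the frame.
#' @return numeric vector of temperatures, degrees C.
#' @examples
#' f <- ThermalFrame(rbind(c(28, 29), c(30, 31)))
#' roiExtract(f, RegionOfInterest("all", "rectangle", c(0, 0, 2, 2)))
#' @export
setGeneric("roiExtract", function(frame, roi) standardGeneric("roiExtract"))

#' @rdname AsymptoticParams-class
#' @param x an AsymptoticParams or StressKineticsFit
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' Equilibrium temperature predicted by a fitted asymptotic model
#'
#' The model's asymptote `theta1`: the temperature the leaf would reach at
#' infinite time, e.g. thermal equilibrium with ambient air for a wilted,
#' non-transpiring canopy.
#'
#' @param x a [StressKineticsFit-class].
#' @return predicted equilibrium temperature, degrees C.
#' @export
setGeneric("predictedEquilibrium",
           function(x) standardGeneric("predictedEquilibrium"))

#' @rdname StressKineticsFit-class
#' @param x a StressKineticsFit
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname StressKineticsFit-class
#' @export
setGeneric("shapeClass", function(x) standardGeneric("shapeClass"))

#' @rdname OnsetResult-class
#' @param x an OnsetResult
#' @export
setGeneric("onsetTime", function(x) standardGeneric("onsetTime"))
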