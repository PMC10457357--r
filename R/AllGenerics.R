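#' Number of frames in a schedule or image
#'
#' @param x A [FrameSchedule-class], [TimeActivityCurve-class] or
#'   [DynamicImage-class].
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame start times
#'
#' @param x A [FrameSchedule-class] (or object carrying one).
#' @param unit `"s"` (default) or `"min"`.
#' @return Numeric vector of per-frame start times since injection.
#' @export
setGeneric("frameStarts", function(x, unit = "s") standardGeneric("frameStarts"))

#' Frame durations
#'
#' @inheritParams frameStarts
#' @return Numeric vector of per-frame durations.
#' @export
setGeneric("frameDurations", function(x, unit = "s") standardGeneric("frameDurations"))

#' Frame mid-times
#'
#' Mid-frame times `start + duration / 2`. These are the time points at
#' which kinetic quantities (Patlak coordinates, cumulative input
#' integrals) are evaluated, so the default unit is minutes.
#'
#' @inheritParams frameStarts
#' @param unit `"min"` (default) or `"s"`.
#' @return Numeric vector, strictly increasing.
#' @export
setGeneric("frameMidTimes", function(x, unit = "min") standardGeneric("frameMidTimes"))

#' Total acquisition length
#'
#' @inheritParams frameMidTimes
#' @return Scalar, end of the last frame.
#' @export
setGeneric("totalDuration", function(x, unit = "min") standardGeneric("totalDuration"))

#' Frame schedule of an object
#'
#' @param x Object carrying a [FrameSchedule-class].
#' @return The `FrameSchedule`.
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' Per-frame activity of a time-activity curve
#'
#' @param x A [TimeActivityCurve-class].
#' @return Numeric vector, kBq/mL.
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' Label of a curve or mask
#'
#' @param x Object with a free-text label.
#' @return Character scalar.
#' @export
setGeneric("curveLabel", function(x) standardGeneric("curveLabel"))

#' Asymptotic net influx rate of an irreversible two-tissue system
#'
#' For rate constants K1, k2, k3 the Patlak plot of the noise-free system
#' approaches slope `K1 * k3 / (k2 + k3)` (0 when `k2 + k3 == 0`).
#'
#' @param object A [CompartmentParams-class].
#' @return Ki in mL plasma per mL tissue per min.
#' @export
setGeneric("asymptoticKi", function(object) standardGeneric("asymptoticKi"))

#' Estimated net influx rate of a Patlak fit
#'
#' @param object A [PatlakFit-class] or [MRgluResult-class].
#' @return Ki (slope) in mL/mL/min.
#' @export
setGeneric("ki", function(object) standardGeneric("ki"))

#' Intercept of a Patlak fit
#'
#' The ordinate intercept, an apparent distribution volume of the
#' exchangeable compartment plus blood.
#'
#' @param object A [PatlakFit-class].
#' @return Unitless intercept.
#' @export
setGeneric("v0", function(object) standardGeneric("v0"))

#' Coefficient of determination of a fit
#'
#' @param object A [PatlakFit-class].
#' @return r-squared in \[0, 1\], or `NA` when the ordinate is constant.
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' Quality flags of a fit or result
#'
#' @param object A [PatlakFit-class] or [MRgluResult-class].
#' @return Character vector (possibly empty), e.g. `"negative_slope"`.
#' @export
setGeneric("qualityFlags", function(object) standardGeneric("qualityFlags"))

#' Image voxel data
#'
#' @param x A [DynamicImage-class].
#' @return The 4D activity array (x, y, z, frame), kBq/mL.
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' Voxel size
#'
#' @param x A [DynamicImage-class].
#' @return Numeric length-3, mm per axis.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Ground-truth tissue-class labels of a phantom image
#'
#' @param x A [DynamicImage-class].
#' @return Integer 3D array of class codes, or `NULL` when the image
#'   carries no ground truth.
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' Tissue-class code table
#'
#' @param x A [DynamicImage-class] or [PhantomSpec-class].
#' @return Named integer vector mapping class names to label codes.
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))

#' Logical voxel mask of an ROI
#'
#' @param x A [ROIMask-class].
#' @return Logical 3D array.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' Provenance of an ROI mask
#'
#' Records how the mask was derived: rule kind, parameters, the realised
#' threshold in kBq/mL and the reference frame index where applicable.
#'
#' @param x A [ROIMask-class].
#' @return Named list.
#' @export
setGeneric("maskProvenance", function(x) standardGeneric("maskProvenance"))

#' Number of voxels in a mask
#'
#' @param x A [ROIMask-class].
#' @return Integer count of `TRUE` voxels.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Mean blood glucose of a panel
#'
#' @param object A [GlucosePanel-class].
#' @param unit `"mg/dL"` (default) or `"mmol/L"`.
#' @return Scalar mean glucose.
#' @export
setGeneric("meanGlucose", function(object, unit = "mg/dL") standardGeneric("meanGlucose"))

#' Saturation-corrected maximal metabolic rate of glucose
#'
#' @param object An [MRgluResult-class].
#' @return MRglu_max in mg per 100 mL tissue per min.
#' @export
setGeneric("mrglu", function(object) standardGeneric("mrglu"))
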