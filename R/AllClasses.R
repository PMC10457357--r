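#' @include AllGenerics.R
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Frame schedule of a dynamic PET acquisition
#'
#' Contiguous, non-overlapping frames starting at injection. Start times
#' and durations are stored in seconds (the acquisition and sidecar
#' convention); kinetic code works on mid-times in minutes via
#' [frameMidTimes()].
#'
#' @slot start Numeric, per-frame start time in seconds; `start[1] == 0`.
#' @slot duration Numeric, per-frame duration in seconds, all positive;
#'   `start[i+1] == start[i] + duration[i]`.
#'
#' @seealso [frameSchedule()], [fdgFrameSchedule()]
#' @export
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@start; d <- object@duration
  msg <- character()
  if (length(s) < 1L || length(s) != length(d))
    msg <- c(msg, "start and duration must have equal length >= 1")
  if (length(d) && any(!is.finite(d) | d <= 0))
    msg <- c(msg, "all durations must be finite and > 0")
  if (length(s)) {
    if (!isTRUE(all.equal(s[1], 0)))
      msg <- c(msg, "first frame must start at 0")
    if (length(s) > 1L &&
        max(abs(s[-1] - (s[-length(s)] + d[-length(d)]))) > 1e-6)
      msg <- c(msg, "frames must be contiguous and non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Parametric plasma tracer concentration model
#'
#' Sum of rise-and-decay exponential terms
#' \deqn{C_p(t) = \sum_j A_j (e^{-\lambda_j t} - e^{-\mu t}),}
#' with a common fast rise rate \eqn{\mu} exceeding every decay rate
#' \eqn{\lambda_j}. The form is zero at injection, nonnegative for all
#' t >= 0, shows a single early bolus peak followed by monotone decay,
#' and has a closed-form running integral — which makes it an exact
#' oracle for cumulative-input computations.
#'
#' Real acquisitions derive the input function from the image rather
#' than from a parametric form; this model exists to generate synthetic
#' data with known truth.
#'
#' @slot amplitudes Numeric, kBq/mL, all positive.
#' @slot decayRates Numeric, 1/min, same length as `amplitudes`.
#' @slot riseRate Numeric scalar, 1/min, greater than every decay rate.
#'
#' @seealso [plasmaModel()], [evalPlasma()], [plasmaIntegral()]
#' @export
setClass("PlasmaModel",
  representation(amplitudes = "numeric", decayRates = "numeric",
                 riseRate = "numeric"))

setValidity("PlasmaModel", function(object) {
  msg <- character()
  if (length(object@amplitudes) < 1L ||
      length(object@amplitudes) != length(object@decayRates))
    msg <- c(msg, "amplitudes and decayRates must have equal length >= 1")
  if (any(object@amplitudes <= 0)) msg <- c(msg, "amplitudes must be > 0")
  if (any(object@decayRates <= 0)) msg <- c(msg, "decayRates must be > 0")
  if (length(object@riseRate) != 1L ||
      object@riseRate <= max(object@decayRates))
    msg <- c(msg, "riseRate must be a scalar exceeding every decay rate")
  if (length(msg)) msg else TRUE
})

#' Rate constants of the irreversible two-tissue FDG model
#'
#' Ground-truth kinetic constants used by the simulator. k4 is fixed at
#' zero: phosphorylated FDG is trapped over the scan, which is what makes
#' Patlak analysis applicable.
#'
#' @slot k1 Plasma-to-tissue transport, mL plasma / mL tissue / min.
#' @slot k2 Tissue-to-plasma efflux, 1/min.
#' @slot k3 Phosphorylation (trapping) rate, 1/min.
#' @slot vb Fractional blood volume in the voxel, unitless in \[0, 1).
#'
#' @seealso [compartmentParams()], [asymptoticKi()]
#' @export
setClass("CompartmentParams",
  representation(k1 = "numeric", k2 = "numeric", k3 = "numeric",
                 vb = "numeric"))

setValidity("CompartmentParams", function(object) {
  v <- c(object@k1, object@k2, object@k3, object@vb)
  msg <- character()
  if (length(v) != 4L || any(!is.finite(v)))
    msg <- c(msg, "K1, k2, k3, vb must be finite scalars")
  else {
    if (any(v[1:3] < 0)) msg <- c(msg, "rates must be >= 0")
    if (object@vb < 0 || object@vb >= 1) msg <- c(msg, "vb must be in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Time-activity curve
#'
#' Per-frame mean activity for a region or voxel; the shared
#' representation for tissue curves and the image-derived input function.
#'
#' @slot schedule A [FrameSchedule-class].
#' @slot activity Numeric, kBq/mL, one finite value per frame.
#' @slot label Free-text region label.
#'
#' @seealso [timeActivityCurve()], [extractTAC()], [frameAverage()]
#' @export
setClass("TimeActivityCurve",
  representation(schedule = "FrameSchedule", activity = "numeric",
                 label = "character"))

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@activity) != length(object@schedule@start))
    msg <- c(msg, "activity length must equal the frame count")
  if (any(!is.finite(object@activity)))
    msg <- c(msg, "activity must be finite")
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' Dynamic 4D PET image
#'
#' A 4D activity volume (x, y, z, frame) with voxel geometry, a frame
#' schedule, and — for simulated phantoms — an optional ground-truth
#' tissue-class label volume.
#'
#' @slot data 4D numeric array, kBq/mL.
#' @slot voxelSize Numeric length-3, mm per axis, all positive.
#' @slot schedule A [FrameSchedule-class]; frame axis length must match.
#' @slot labels Optional integer 3D array of tissue-class codes aligned
#'   with the grid (0 = background), or `NULL`.
#' @slot classes Named integer vector mapping class names to codes
#'   (empty when no ground truth is attached).
#'
#' @seealso [dynamicImage()], [buildPhantom()], [readDynamicImage()]
#' @export
setClass("DynamicImage",
  representation(data = "array", voxelSize = "numeric",
                 schedule = "FrameSchedule", labels = "arrayOrNULL",
                 classes = "integer"))

setValidity("DynamicImage", function(object) {
  msg <- character()
  dm <- dim(object@data)
  if (length(dm) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, frame)")
  else if (dm[4] != length(object@schedule@start))
    msg <- c(msg, "frame axis length must equal the schedule frame count")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values (mm)")
  if (!is.null(object@labels)) {
    if (!identical(dim(object@labels), dm[1:3]))
      msg <- c(msg, "labels must be a 3D array matching the spatial grid")
  }
  if (length(msg)) msg else TRUE
})

#' Region-of-interest voxel mask
#'
#' Boolean volume aligned with an image grid, plus provenance: the rule
#' that produced it, its parameters, the realised threshold value and the
#' reference frame index where applicable.
#'
#' @slot mask Logical 3D array with at least one `TRUE` voxel.
#' @slot provenance Named list describing the derivation.
#'
#' @seealso [cylinderROI()], [thresholdROILastFrame()], [venaCavaROI()]
#' @export
setClass("ROIMask",
  representation(mask = "array", provenance = "list"))

setValidity("ROIMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a logical 3D array")
  else if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one voxel")
  if (length(msg)) msg else TRUE
})

#' Result of a Patlak linear fit
#'
#' @slot ki Slope: net influx rate, mL/mL/min. Negative slopes are
#'   reported as-is, carrying a `"negative_slope"` flag.
#' @slot v0 Intercept (unitless apparent distribution volume).
#' @slot rSquared Coefficient of determination; `NA` for a flat ordinate.
#' @slot nUsed Number of points entering the regression (>= 2).
#' @slot window Closed fit window on frame mid-times, minutes.
#' @slot flags Character quality flags (`"negative_slope"`, `"flat"`).
#'
#' @seealso [fitPatlak()]
#' @export
setClass("PatlakFit",
  representation(ki = "numeric", v0 = "numeric", rSquared = "numeric",
                 nUsed = "integer", window = "numeric", flags = "character"))

setValidity("PatlakFit", function(object) {
  msg <- character()
  if (object@nUsed < 2L) msg <- c(msg, "a fit requires >= 2 points")
  if (length(object@window) != 2L || diff(object@window) <= 0)
    msg <- c(msg, "window must be an increasing pair of minutes")
  r2 <- object@rSquared
  if (!is.na(r2) && (r2 < -1e-12 || r2 > 1 + 1e-12))
    msg <- c(msg, "rSquared must lie in [0, 1] when defined")
  if (length(msg)) msg else TRUE
})

#' Blood glucose panel taken during a scan
#'
#' The scan protocol samples tail-vein glucose at 10, 20 and 40 min
#' after injection; the arithmetic mean (as mg/dL) enters the
#' MRglu_max computation.
#'
#' @slot times Sampling times in minutes (`NA` allowed when unrecorded).
#' @slot values Glucose values as supplied, all positive.
#' @slot unit Unit of `values`: `"mg/dL"` or `"mmol/L"`.
#' @slot meanMgDl Arithmetic mean converted to mg/dL
#'   (1 mmol/L = 18.016 mg/dL).
#'
#' @seealso [meanCglu()]
#' @export
setClass("GlucosePanel",
  representation(times = "numeric", values = "numeric", unit = "character",
                 meanMgDl = "numeric"))

setValidity("GlucosePanel", function(object) {
  msg <- character()
  if (length(object@values) < 1L || any(object@values <= 0))
    msg <- c(msg, "at least one positive glucose value is required")
  if (!object@unit %in% c("mg/dL", "mmol/L"))
    msg <- c(msg, "unit must be 'mg/dL' or 'mmol/L'")
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times must match values in length")
  if (length(msg)) msg else TRUE
})

#' Saturation-corrected maximal metabolic rate of glucose
#'
#' Houses `MRglu_max = Ki * (Km + Cglu)` together with its inputs, so the
#' identity `mrglu(x) / ki(x) - cglu == Km` holds exactly. With Ki in
#' mL/mL/min and concentrations in mg/dL the rate is mg per 100 mL
#' tissue per min. No lumped constant is applied.
#'
#' @slot mrgluMax The rate, mg/(100 mL tissue)/min.
#' @slot ki Net influx rate used, mL/mL/min.
#' @slot kmMgDl Michaelis-Menten constant, mg/dL (default 130).
#' @slot cgluMgDl Mean blood glucose during the scan, mg/dL.
#' @slot flags Quality flags propagated from the Patlak fit.
#'
#' @seealso [mrgluMax()]
#' @export
setClass("MRgluResult",
  representation(mrgluMax = "numeric", ki = "numeric", kmMgDl = "numeric",
                 cgluMgDl = "numeric", flags = "character"))

setValidity("MRgluResult", function(object) {
  msg <- character()
  if (object@kmMgDl <= 0) msg <- c(msg, "Km must be > 0")
  if (object@cgluMgDl <= 0) msg <- c(msg, "Cglu must be > 0")
  tol <- 1e-9 * max(1, abs(object@mrgluMax))
  if (abs(object@mrgluMax - object@ki * (object@kmMgDl + object@cgluMgDl)) > tol)
    msg <- c(msg, "mrgluMax must equal ki * (Km + Cglu)")
  if (length(msg)) msg else TRUE
})

#' Specification of a digital FDG phantom
#'
#' Geometry mirrors the anatomy the ROI rules address: two skeletal
#' muscle cylinders, a myocardial shell around a blood-pool interior,
#' and a vena-cava tube, in a background of zero activity. Blood classes
#' carry the (frame-averaged) plasma curve rather than a tissue model.
#' Voxel indices are 1-based, following R convention.
#'
#' @slot dim Integer grid shape (x, y, z); default 64 x 64 x 32.
#' @slot voxelSize mm per axis; default 0.4 isotropic, a typical preclinical
#'   reconstruction voxel size.
#' @slot schedule Frame schedule the phantom is viewed through.
#' @slot muscle,myocardium [CompartmentParams-class] per tissue class.
#' @slot geometry Named list of placement parameters (see
#'   [phantomSpec()]).
#' @slot noiseScale Voxelwise noise scale (0 = noise-free); see
#'   [addNoise()] for the noise law.
#' @slot seed Integer seed for the voxel noise.
#'
#' @seealso [phantomSpec()], [buildPhantom()]
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", voxelSize = "numeric",
                 schedule = "FrameSchedule",
                 muscle = "CompartmentParams",
                 myocardium = "CompartmentParams",
                 geometry = "list", noiseScale = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 8L))
    msg <- c(msg, "dim must be 3 integers >= 8")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values")
  if (object@noiseScale < 0) msg <- c(msg, "noiseScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Design of a simulated longitudinal cohort
#'
#' Three-arm structure emulating a diabetes treatment study: a healthy
#' control arm, an untreated diabetic arm with rising glucose and
#' falling insulin, and a treated arm whose glycemia re-normalises. Arm
#' means are piecewise-linear in time; animals deviate from them by
#' multiplicative lognormal noise.
#'
#' @slot arms List of per-arm trajectory definitions: each a list with
#'   `name`, `weeks`, `glucose` (mmol/L knots) and `insulin`
#'   (microU/mL knots).
#' @slot n Animals per arm.
#' @slot weeks Observation weeks, strictly increasing.
#' @slot cv Coefficient of variation of the multiplicative noise.
#' @slot seed Integer seed.
#'
#' @seealso [cohortDesign()], [simulateCohort()]
#' @export
setClass("CohortDesign",
  representation(arms = "list", n = "integer", weeks = "numeric",
                 cv = "numeric", seed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(object@weeks) < 2L || any(diff(object@weeks) <= 0))
    msg <- c(msg, "weeks must be strictly increasing with >= 2 points")
  if (object@cv < 0) msg <- c(msg, "cv must be >= 0")
  for (a in object@arms) {
    if (!all(c("name", "weeks", "glucose", "insulin") %in% names(a)))
      msg <- c(msg, "each arm needs name, weeks, glucose, insulin")
    else if (any(a$glucose < 0) || any(a$insulin < 0))
      msg <- c(msg, sprintf("arm '%s': trajectories must be nonnegative", a$name))
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a simulated mito-stress plate
#'
#' Four-phase extracellular-flux trace: three (by default) baseline
#' measurements followed by oligomycin (ATP-synthase block), FCCP
#' (chemical uncoupling) and rotenone + antimycin A (complex I/III
#' block) injections, each phase sitting at a plateau mean.
#'
#' @slot ocr Named numeric length-4 OCR plateau means, pmol O2/min, in
#'   phase order `baseline, oligomycin, fccp, rot_aa`; all >= 0.
#' @slot ecar Named numeric length-4 ECAR plateau means, mpH/min.
#' @slot nPerPhase Measurements per phase (>= 1).
#' @slot nWells Replicate wells.
#' @slot ocrSd,ecarSd Gaussian measurement noise SDs.
#' @slot condition Condition label attached to every well.
#' @slot seed Integer seed.
#'
#' @seealso [mitoTraceSpec()], [mitoPreset()], [simulateMitoPlate()]
#' @export
setClass("MitoTraceSpec",
  representation(ocr = "numeric", ecar = "numeric", nPerPhase = "integer",
                 nWells = "integer", ocrSd = "numeric", ecarSd = "numeric",
                 condition = "character", seed = "integer"))

.mitoPhases <- c("baseline", "oligomycin", "fccp", "rot_aa")

setValidity("MitoTraceSpec", function(object) {
  msg <- character()
  if (!identical(names(object@ocr), .mitoPhases) ||
      !identical(names(object@ecar), .mitoPhases))
    msg <- c(msg, "ocr and ecar must be named with the 4 phases in fixed order")
  if (any(object@ocr < 0) || any(object@ecar < 0))
    msg <- c(msg, "plateau means must be >= 0")
  if (object@nPerPhase < 1L) msg <- c(msg, "nPerPhase must be >= 1")
  if (object@nWells < 1L) msg <- c(msg, "nWells must be >= 1")
  if (object@ocrSd < 0 || object@ecarSd < 0) msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})
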