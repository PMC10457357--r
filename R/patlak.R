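#' @include AllClasses.R
NULL

#' Cumulative integral of an input curve at frame mid-times
#'
#' Running \eqn{\int_0^t C_p\,d\tau} evaluated at the frame mid-times
#' by duration-weighted frame sums: every completed frame contributes
#' `activity * duration`, and the current frame contributes half of
#' its own. Because a frame's reported activity is its time-average,
#' the completed-frame part is exact for frame-averaged curves; a
#' constant input `c` integrates to exactly `c * t` at every mid-time.
#' This is the Patlak abscissa numerator for a measured (frame-sampled)
#' input function.
#'
#' @param inputTac A [TimeActivityCurve-class] (the image-derived input
#'   function).
#' @return Numeric vector of integral values, kBq.min/mL, one per frame.
#' @export
cumulativeInputIntegral <- function(inputTac) {
  stopifnot(methods::is(inputTac, "TimeActivityCurve"))
  cp <- inputTac@activity
  durs <- frameDurations(inputTac@schedule, "min")
  contrib <- cp * durs
  cumsum(contrib) - contrib / 2
}

#' Patlak transformation of a tissue / input curve pair
#'
#' Classical Patlak coordinates for an irreversible tracer:
#' \deqn{x(t) = \int_0^t C_p\,d\tau \, / \, C_p(t), \qquad
#'       y(t) = C_t(t) / C_p(t),}
#' evaluated at frame mid-times. Frames whose input activity falls
#' below `epsFraction` times the input maximum (e.g. pre-arrival
#' frames) are flagged unusable with a reason code rather than
#' producing unstable ratios.
#'
#' @param tissue Tissue [TimeActivityCurve-class].
#' @param input Input-function [TimeActivityCurve-class], on the same
#'   schedule.
#' @param epsFraction Usability cutoff as a fraction of `max(input)`,
#'   default `1e-3`.
#' @return A data frame of class `PatlakPoints` with columns
#'   `mid_min`, `x`, `y`, `usable`, `reason` (`NA` coordinates on
#'   unusable frames).
#' @export
patlakTransform <- function(tissue, input, epsFraction = 1e-3) {
  stopifnot(methods::is(tissue, "TimeActivityCurve"),
            methods::is(input, "TimeActivityCurve"))
  if (!.sameSchedule(tissue, input))
    stop("tissue and input curves must share a frame schedule")
  cp <- input@activity
  cutoff <- epsFraction * max(cp)
  usable <- cp >= cutoff & cp > 0
  if (!any(usable)) stop("degenerate input: no usable frames")
  integ <- cumulativeInputIntegral(input)
  x <- ifelse(usable, integ / cp, NA_real_)
  y <- ifelse(usable, tissue@activity / cp, NA_real_)
  out <- data.frame(mid_min = frameMidTimes(tissue@schedule, "min"),
                    x = x, y = y, usable = usable,
                    reason = ifelse(usable, "", "low_input"))
  class(out) <- c("PatlakPoints", "data.frame")
  out
}

#' Fit the linear segment of a Patlak plot
#'
#' Unweighted ordinary least squares on the usable points whose frame
#' mid-times fall inside the closed window (default 16-40 min, the
#' late segment where the exchangeable compartment has equilibrated).
#' The slope is the net influx rate Ki; the intercept V0 is an apparent
#' distribution volume. Negative slopes are reported as-is with a
#' `"negative_slope"` flag; a constant ordinate yields Ki = 0 with a
#' `"flat"` flag and undefined r-squared.
#'
#' @param points A `PatlakPoints` data frame from [patlakTransform()].
#' @param window Closed fit window on mid-times, minutes; default
#'   `c(16, 40)`.
#' @return A [PatlakFit-class].
#' @examples
#' pts <- data.frame(mid_min = 16:40, x = 16:40, y = 0.02 * (16:40) + 0.5,
#'                   usable = TRUE, reason = "")
#' ki(fitPatlak(pts))  # 0.02
#' @export
fitPatlak <- function(points, window = c(16, 40)) {
  stopifnot(is.data.frame(points),
            all(c("mid_min", "x", "y", "usable") %in% names(points)))
  if (length(window) != 2L || diff(window) <= 0)
    stop("window must be an increasing pair of minutes")
  sel <- points$usable & points$mid_min >= window[1] &
    points$mid_min <= window[2]
  n <- sum(sel)
  if (n < 2L)
    stop(sprintf("insufficient data: %d usable point(s) in [%g, %g] min",
                 n, window[1], window[2]))
  x <- points$x[sel]; y <- points$y[sel]
  if (max(x) - min(x) <= 0) stop("degenerate abscissa: no spread in x")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((y - mean(y))^2)
  flags <- character()
  if (tss == 0) {
    r2 <- NA_real_
    slope <- 0
    flags <- c(flags, "flat")
  } else {
    r2 <- 1 - sum(stats::resid(fit)^2) / tss
  }
  if (slope < 0) flags <- c(flags, "negative_slope")
  methods::new("PatlakFit", ki = slope, v0 = intercept, rSquared = r2,
               nUsed = as.integer(n), window = as.numeric(window),
               flags = flags)
}

#' @rdname ki
#' @export
setMethod("ki", "PatlakFit", function(object) object@ki)

#' @rdname v0
#' @export
setMethod("v0", "PatlakFit", function(object) object@v0)

#' @rdname rSquared
#' @export
setMethod("rSquared", "PatlakFit", function(object) object@rSquared)

#' @rdname qualityFlags
#' @export
setMethod("qualityFlags", "PatlakFit", function(object) object@flags)

#' Number of points used by a Patlak fit
#'
#' @param fit A [PatlakFit-class].
#' @return Integer.
#' @export
nFramesUsed <- function(fit) fit@nUsed

#' Fit window of a Patlak fit
#'
#' @param fit A [PatlakFit-class].
#' @return Numeric length-2, minutes.
#' @export
fitWindow <- function(fit) fit@window

setMethod("show", "PatlakFit", function(object) {
  cat(sprintf(
    "PatlakFit: Ki = %.5g mL/mL/min, V0 = %.4g, r2 = %s (n = %d, [%g, %g] min)%s\n",
    object@ki, object@v0,
    if (is.na(object@rSquared)) "NA" else sprintf("%.4f", object@rSquared),
    object@nUsed, object@window[1], object@window[2],
    if (length(object@flags)) paste0("  [", paste(object@flags, collapse = ","), "]")
    else ""))
})

#' Average blood glucose over a scan
#'
#' Arithmetic mean of the glucose samples (the scan protocol takes
#' three, at 10, 20 and 40 min after injection), converted to mg/dL
#' when supplied in mmol/L (1 mmol/L = 18.016 mg/dL).
#'
#' @param values Positive glucose values.
#' @param unit `"mg/dL"` or `"mmol/L"`.
#' @param times Optional sampling times in minutes.
#' @return A [GlucosePanel-class].
#' @examples
#' meanGlucose(meanCglu(c(10, 11, 12), "mmol/L"))  # 198.176 mg/dL
#' @export
meanCglu <- function(values, unit = c("mg/dL", "mmol/L"), times = NULL) {
  unit <- match.arg(unit)
  if (length(values) < 1L || any(!is.finite(values)) || any(values <= 0))
    stop("glucose samples must be positive and finite")
  if (is.null(times)) times <- rep(NA_real_, length(values))
  m <- mean(values)
  methods::new("GlucosePanel", times = as.numeric(times),
               values = as.numeric(values), unit = unit,
               meanMgDl = if (unit == "mmol/L") m * 18.016 else m)
}

#' @rdname meanGlucose
#' @export
setMethod("meanGlucose", "GlucosePanel", function(object, unit = "mg/dL") {
  unit <- match.arg(unit, c("mg/dL", "mmol/L"))
  if (unit == "mg/dL") object@meanMgDl else object@meanMgDl / 18.016
})

setMethod("show", "GlucosePanel", function(object) {
  cat(sprintf("GlucosePanel: %d sample(s) in %s, mean Cglu = %.4g mg/dL\n",
              length(object@values), object@unit, object@meanMgDl))
})

#' Saturation-corrected maximal metabolic rate of glucose
#'
#' \deqn{MR_{glu}^{max} = K_i (K_m + C_{glu})} with the
#' Michaelis-Menten constant Km defaulting to 130 mg/dL. With Ki in
#' mL/mL/min and concentrations in mg/dL the result is mg per 100 mL
#' tissue per min. No lumped constant is applied, and no parameter for
#' one is exposed. A negative Ki propagates with its quality flag.
#'
#' @param fit A [PatlakFit-class].
#' @param panel A [GlucosePanel-class].
#' @param kmMgDl Km in mg/dL, default 130.
#' @return An [MRgluResult-class].
#' @examples
#' pts <- data.frame(mid_min = 16:40, x = 16:40, y = 0.02 * (16:40),
#'                   usable = TRUE, reason = "")
#' mrglu(mrgluMax(fitPatlak(pts), meanCglu(270, "mg/dL")))  # 8
#' @export
mrgluMax <- function(fit, panel, kmMgDl = 130) {
  stopifnot(methods::is(fit, "PatlakFit"), methods::is(panel, "GlucosePanel"))
  if (kmMgDl <= 0) stop("Km must be > 0")
  cglu <- panel@meanMgDl
  methods::new("MRgluResult", mrgluMax = fit@ki * (kmMgDl + cglu),
               ki = fit@ki, kmMgDl = as.numeric(kmMgDl), cgluMgDl = cglu,
               flags = fit@flags)
}

#' @rdname mrglu
#' @export
setMethod("mrglu", "MRgluResult", function(object) object@mrgluMax)

#' @rdname ki
#' @export
setMethod("ki", "MRgluResult", function(object) object@ki)

#' @rdname qualityFlags
#' @export
setMethod("qualityFlags", "MRgluResult", function(object) object@flags)

setMethod("show", "MRgluResult", function(object) {
  cat(sprintf(
    "MRgluResult: %.4g mg/(100 mL.min)  [Ki = %.5g, Km = %g, Cglu = %.4g mg/dL]%s\n",
    object@mrgluMax, object@ki, object@kmMgDl, object@cgluMgDl,
    if (length(object@flags)) paste0("  [", paste(object@flags, collapse = ","), "]")
    else ""))
})

#' Voxelwise Patlak Ki parametric map
#'
#' Applies the Patlak transform and windowed OLS fit independently to
#' every voxel inside the body mask, sharing the input-function
#' abscissa across voxels. Voxels that cannot be fitted (no activity in
#' the fit window) are set to `NA` with a reason code in the quality
#' volume.
#'
#' @param image A [DynamicImage-class].
#' @param idif Image-derived input function on the image's schedule.
#' @param window Closed fit window in minutes, default `c(16, 40)`.
#' @param bodyMask [ROIMask-class] or logical array restricting the
#'   computation; voxels outside are `NA`.
#' @param epsFraction Input usability cutoff (see [patlakTransform()]).
#' @return List with elements `ki` (3D array, mL/mL/min, `NA` where not
#'   fitted), `r_squared` (3D array), and `quality` (integer 3D array:
#'   0 fitted, 1 outside mask, 2 unusable voxel, 3 fitted with negative
#'   slope).
#' @export
patlakParametricMap <- function(image, idif, window = c(16, 40), bodyMask,
                                epsFraction = 1e-3) {
  stopifnot(methods::is(image, "DynamicImage"),
            methods::is(idif, "TimeActivityCurve"))
  if (!isTRUE(all.equal(frameStarts(image@schedule),
                        frameStarts(idif@schedule))))
    stop("input function must be on the image's frame schedule")
  dm <- dim(image@data)[1:3]
  body <- .asMaskArray(bodyMask, dm)
  cp <- idif@activity
  cutoff <- epsFraction * max(cp)
  mids <- frameMidTimes(image@schedule, "min")
  usable <- cp >= cutoff & cp > 0
  sel <- usable & mids >= window[1] & mids <= window[2]
  if (sum(sel) < 2L) stop("insufficient usable frames inside the window")
  integ <- cumulativeInputIntegral(idif)
  x <- (integ / cp)[sel]
  idx <- which(body)
  nvox <- prod(dm)
  frames <- which(sel)
  # voxels x frames ordinate matrix: y = Ct / Cp
  Y <- vapply(frames, function(f) image@data[idx + (f - 1) * nvox] / cp[f],
              numeric(length(idx)))
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = length(idx))
  fitted <- rowSums(abs(Y)) > 0
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.vector(Y %*% xc) / sxx
  intercept <- rowMeans(Y) - slope * mean(x)
  res <- Y - outer(slope, x) - intercept
  tss <- rowSums((Y - rowMeans(Y))^2)
  r2 <- ifelse(tss > 0, 1 - rowSums(res^2) / tss, NA_real_)
  kiVol <- array(NA_real_, dm)
  r2Vol <- array(NA_real_, dm)
  qual <- array(1L, dm)
  qual[idx] <- ifelse(fitted, ifelse(slope < 0, 3L, 0L), 2L)
  kiVol[idx[fitted]] <- slope[fitted]
  r2Vol[idx[fitted]] <- r2[fitted]
  list(ki = kiVol, r_squared = r2Vol, quality = qual)
}
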