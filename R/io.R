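#' @include AllClasses.R
NULL

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write a dynamic image as NIfTI-1 plus a frame-timing sidecar
#'
#' The 4D volume goes to `path` (`.nii` or `.nii.gz`); frame timing goes
#' to a JSON sidecar of the same basename with `FrameTimesStart` and
#' `FrameDuration` arrays in seconds (the BIDS PET convention). When the
#' image carries ground-truth labels they are written alongside as
#' `<basename>_labels.nii[.gz]` with the class table in the sidecar.
#'
#' @param image A [DynamicImage-class].
#' @param path Output NIfTI path.
#' @return `path`, invisibly.
#' @export
writeDynamicImage <- function(image, path) {
  stopifnot(methods::is(image, "DynamicImage"))
  nii <- RNifti::asNifti(image@data)
  RNifti::pixdim(nii) <- c(image@voxelSize, 1)
  RNifti::writeNifti(nii, path)
  side <- list(FrameTimesStart = frameStarts(image@schedule),
               FrameDuration = frameDurations(image@schedule))
  if (!is.null(image@labels)) {
    labPath <- sub("\\.nii(\\.gz)?$", "_labels.nii\\1", path)
    lnii <- RNifti::asNifti(image@labels)
    RNifti::pixdim(lnii) <- image@voxelSize
    RNifti::writeNifti(lnii, labPath, datatype = "int16")
    side$TissueClasses <- as.list(image@classes)
  }
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dynamic image written by [writeDynamicImage()]
#'
#' @param path NIfTI path; the JSON frame-timing sidecar (and, if
#'   present, the `_labels` volume) are picked up by naming convention.
#' @return A [DynamicImage-class].
#' @export
readDynamicImage <- function(path) {
  nii <- RNifti::readNifti(path)
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  sch <- frameSchedule(side$FrameDuration)
  if (max(abs(frameStarts(sch) - side$FrameTimesStart)) > 1e-6)
    stop("sidecar frame times are not contiguous from 0")
  labPath <- sub("\\.nii(\\.gz)?$", "_labels.nii\\1", path)
  labels <- NULL
  classes <- integer()
  if (file.exists(labPath)) {
    labels <- array(as.integer(RNifti::readNifti(labPath)),
                    dim(RNifti::readNifti(labPath)))
    if (!is.null(side$TissueClasses))
      classes <- unlist(side$TissueClasses)
  }
  dynamicImage(array(as.numeric(nii), dim(nii)), RNifti::pixdim(nii)[1:3],
               sch, labels = labels, classes = classes)
}

#' Write an ROI mask as an integer NIfTI volume
#'
#' @param mask A [ROIMask-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxelSize mm per axis for the header, default 1.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path, voxelSize = c(1, 1, 1)) {
  stopifnot(methods::is(mask, "ROIMask"))
  nii <- RNifti::asNifti(array(as.integer(mask@mask), dim(mask@mask)))
  RNifti::pixdim(nii) <- voxelSize
  RNifti::writeNifti(nii, path, datatype = "int16")
  invisible(path)
}

#' Read an ROI mask written by [writeMask()]
#'
#' @param path NIfTI path; nonzero voxels become `TRUE`.
#' @return A [ROIMask-class] with file provenance.
#' @export
readMask <- function(path) {
  nii <- RNifti::readNifti(path)
  methods::new("ROIMask", mask = array(as.numeric(nii) != 0, dim(nii)),
               provenance = list(kind = "file", path = path))
}

#' Write a time-activity curve as CSV
#'
#' Columns: `frame_start_s`, `frame_duration_s`,
#' `mean_activity_kBq_per_mL`.
#'
#' @param tac A [TimeActivityCurve-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTAC <- function(tac, path) {
  stopifnot(methods::is(tac, "TimeActivityCurve"))
  utils::write.csv(as.data.frame(tac), path, row.names = FALSE)
  invisible(path)
}

#' Read a time-activity curve CSV written by [writeTAC()]
#'
#' @param path CSV path.
#' @param label Label for the curve.
#' @return A [TimeActivityCurve-class].
#' @export
readTAC <- function(path, label = "") {
  d <- utils::read.csv(path)
  need <- c("frame_start_s", "frame_duration_s", "mean_activity_kBq_per_mL")
  if (!all(need %in% names(d)))
    stop("TAC CSV must have columns: ", paste(need, collapse = ", "))
  sch <- frameSchedule(d$frame_duration_s)
  if (max(abs(frameStarts(sch) - d$frame_start_s)) > 1e-6)
    stop("TAC frames are not contiguous from 0")
  timeActivityCurve(sch, d$mean_activity_kBq_per_mL, label)
}

#' Write phantom ground truth as YAML
#'
#' Per-class rate constants and closed-form Ki, plus grid geometry —
#' the reference a recovery analysis compares its estimates against.
#'
#' @param spec A [PhantomSpec-class].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(spec, path) {
  gt <- phantomGroundTruth(spec)
  classes <- lapply(seq_len(nrow(gt)), function(i) {
    row <- as.list(gt[i, setdiff(names(gt), "class")])
    row[!vapply(row, function(v) is.na(v), logical(1))]
  })
  names(classes) <- gt$class
  yaml::write_yaml(list(grid = as.integer(spec@dim),
                        voxel_size_mm = spec@voxelSize,
                        noise_scale = spec@noiseScale,
                        seed = spec@seed,
                        classes = classes), path)
  invisible(path)
}

#' Fit report of a Patlak analysis as a plain list
#'
#' Suitable for `jsonlite::write_json()`: slope, intercept, fit
#' diagnostics, window and flags, plus the MRglu quantities when a
#' result is supplied.
#'
#' @param fit A [PatlakFit-class].
#' @param result Optional [MRgluResult-class].
#' @return Named list.
#' @export
patlakReport <- function(fit, result = NULL) {
  out <- list(ki_ml_ml_min = fit@ki, v0 = fit@v0,
              r_squared = fit@rSquared, n_frames = fit@nUsed,
              window_min = fit@window, flags = fit@flags)
  if (!is.null(result)) {
    stopifnot(methods::is(result, "MRgluResult"))
    out$mrglu_max_mg_100ml_min <- result@mrgluMax
    out$km_mg_dl <- result@kmMgDl
    out$cglu_mg_dl <- result@cgluMgDl
  }
  out
}

#' Write a cohort table as CSV
#'
#' @param cohort Data frame from [simulateCohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV written by [writeCohort()]
#'
#' @param path CSV path.
#' @return Data frame in the [simulateCohort()] layout.
#' @export
readCohort <- function(path) {
  d <- utils::read.csv(path)
  need <- c("subject", "arm", "week", "glucose", "glucose_unit",
            "insulin", "insulin_unit")
  if (!all(need %in% names(d)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  d
}

#' Write a mito-stress plate table as CSV
#'
#' @param plate Data frame from [simulateMitoPlate()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeMitoPlate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate CSV written by [writeMitoPlate()]
#'
#' @param path CSV path.
#' @return Data frame in the [simulateMitoPlate()] layout.
#' @export
readMitoPlate <- function(path) {
  d <- utils::read.csv(path)
  need <- c("well", "condition", "measurement_index", "phase", "ocr", "ecar")
  if (!all(need %in% names(d)))
    stop("plate CSV must have columns: ", paste(need, collapse = ", "))
  d
}
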