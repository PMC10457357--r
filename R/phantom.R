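#' @include AllClasses.R
NULL

#' Construct a dynamic image
#'
#' @param data 4D numeric array (x, y, z, frame), kBq/mL.
#' @param voxelSize mm per axis (length 3, or a scalar recycled).
#' @param schedule A [FrameSchedule-class].
#' @param labels Optional integer 3D ground-truth class array.
#' @param classes Named integer vector of class codes.
#' @return A [DynamicImage-class].
#' @export
dynamicImage <- function(data, voxelSize, schedule, labels = NULL,
                         classes = integer()) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  cls <- as.integer(classes)
  names(cls) <- names(classes)
  methods::new("DynamicImage", data = data, voxelSize = as.numeric(voxelSize),
               schedule = schedule, labels = labels, classes = cls)
}

#' @rdname imageData
#' @export
setMethod("imageData", "DynamicImage", function(x) x@data)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "DynamicImage", function(x) x@voxelSize)

#' @rdname schedule
#' @export
setMethod("schedule", "DynamicImage", function(x) x@schedule)

#' @rdname nFrames
#' @export
setMethod("nFrames", "DynamicImage", function(x) nFrames(x@schedule))

#' @rdname tissueLabels
#' @export
setMethod("tissueLabels", "DynamicImage", function(x) x@labels)

#' @rdname classMap
#' @export
setMethod("classMap", "DynamicImage", function(x) x@classes)

setMethod("show", "DynamicImage", function(object) {
  dm <- dim(object@data)
  cat(sprintf("DynamicImage: %dx%dx%d voxels x %d frames, %.2gx%.2gx%.2g mm\n",
              dm[1], dm[2], dm[3], dm[4],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  if (!is.null(object@labels))
    cat("  ground-truth classes:",
        paste(names(object@classes), collapse = ", "), "\n")
})

# in-plane digital disc: 1-based integer voxel centers strictly inside
# the radius (deterministic, brute-force-checkable rasterisation)
.discIndex <- function(nx, ny, cx, cy, radius) {
  d2 <- outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+")
  d2 < radius^2
}

.phantomClassMap <- c(background = 0L, muscle = 1L, myocardium = 2L,
                      blood_pool = 3L, vena_cava = 4L)

#' Specify a digital FDG phantom
#'
#' Default geometry (in a 64 x 64 x 32 grid at 0.4 mm isotropic — the
#' reconstruction voxel size typical of preclinical scanners): two 10-voxel-diameter,
#' 10-slice muscle cylinders; a myocardial spherical shell (inner
#' radius 4, outer 6.5 voxels) enclosing a blood-pool interior; and a
#' vena-cava tube of radius 2 voxels running most of the z extent. For
#' other grid shapes the placements scale proportionally. Blood-pool
#' and vena-cava voxels carry the frame-averaged plasma curve; the
#' background is zero.
#'
#' @param dim Grid shape, default `c(64, 64, 32)`.
#' @param voxelSize mm per axis (scalar recycled), default 0.4.
#' @param schedule Frame schedule; default [fdgFrameSchedule()].
#' @param muscle Muscle kinetics; default
#'   `compartmentParams(0.1, 0.25, 0.05, vb = 0.03)` (Ki = 0.0167).
#' @param myocardium Cardiac kinetics; default
#'   `compartmentParams(0.3, 0.6, 0.15, vb = 0.1)` (Ki = 0.06).
#' @param geometry Named list overriding individual placement entries:
#'   `muscleCenters` (list of in-plane centers), `muscleDiameterPx`,
#'   `muscleSlices`, `muscleZ1` (first slice), `heartCenter` (xyz),
#'   `heartOuterR`, `heartInnerR`, `cavaCenter` (xy), `cavaRadius`,
#'   `cavaZ` (first and last slice).
#' @param noiseScale Voxelwise noise scale (see [addNoise()]); 0 for a
#'   noise-free phantom.
#' @param seed Seed for the voxel noise.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(64L, 64L, 32L), voxelSize = 0.4,
                        schedule = fdgFrameSchedule(),
                        muscle = compartmentParams(0.1, 0.25, 0.05, vb = 0.03),
                        myocardium = compartmentParams(0.3, 0.6, 0.15, vb = 0.1),
                        geometry = list(), noiseScale = 0, seed = 1L) {
  dim <- as.integer(dim)
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  geo <- list(
    muscleCenters = list(c(round(dim[1] / 4), round(dim[2] / 4)),
                         c(round(3 * dim[1] / 4), round(dim[2] / 4))),
    muscleDiameterPx = 10,
    muscleSlices = 10L,
    muscleZ1 = max(1L, round(dim[3] / 2) - 4L),
    heartCenter = c(round(dim[1] / 2), round(3 * dim[2] / 4) - 4L,
                    round(dim[3] / 2)),
    heartOuterR = 6.5,
    heartInnerR = 4.0,
    cavaCenter = c(round(dim[1] / 2), round(dim[2] / 2)),
    cavaRadius = 2.0,
    cavaZ = c(4L, dim[3] - 4L))
  bad <- setdiff(names(geometry), names(geo))
  if (length(bad)) stop("unknown geometry entries: ", paste(bad, collapse = ", "))
  geo[names(geometry)] <- geometry
  methods::new("PhantomSpec", dim = dim, voxelSize = as.numeric(voxelSize),
               schedule = schedule, muscle = muscle, myocardium = myocardium,
               geometry = geo, noiseScale = as.numeric(noiseScale),
               seed = as.integer(seed))
}

# label volume for a spec; errors if classes would overlap
.phantomLabels <- function(spec) {
  dm <- spec@dim
  geo <- spec@geometry
  lab <- array(0L, dm)
  assign_class <- function(lab, vox, code) {
    if (any(lab[vox] != 0L))
      stop("phantom specification error: tissue classes overlap")
    lab[vox] <- code
    lab
  }
  # muscle cylinders
  z1 <- geo$muscleZ1
  zm <- z1:(z1 + geo$muscleSlices - 1L)
  if (max(zm) > dm[3]) stop("muscle cylinder exceeds grid in z")
  for (ctr in geo$muscleCenters) {
    disc <- .discIndex(dm[1], dm[2], ctr[1], ctr[2], geo$muscleDiameterPx / 2)
    vox <- array(FALSE, dm); vox[, , zm] <- disc
    lab <- assign_class(lab, vox, .phantomClassMap[["muscle"]])
  }
  # myocardial shell + blood-pool interior (sphere)
  hc <- geo$heartCenter
  d2 <- outer(outer((seq_len(dm[1]) - hc[1])^2,
                    (seq_len(dm[2]) - hc[2])^2, "+"),
              (seq_len(dm[3]) - hc[3])^2, "+")
  lab <- assign_class(lab, d2 >= geo$heartInnerR^2 & d2 < geo$heartOuterR^2,
                      .phantomClassMap[["myocardium"]])
  lab <- assign_class(lab, d2 < geo$heartInnerR^2,
                      .phantomClassMap[["blood_pool"]])
  # vena-cava tube
  cz <- geo$cavaZ
  disc <- .discIndex(dm[1], dm[2], geo$cavaCenter[1], geo$cavaCenter[2],
                     geo$cavaRadius)
  vox <- array(FALSE, dm); vox[, , cz[1]:cz[2]] <- disc
  assign_class(lab, vox, .phantomClassMap[["vena_cava"]])
}

#' Per-class ground truth of a phantom
#'
#' @param spec A [PhantomSpec-class].
#' @return Data frame with one row per tissue class: code, rate
#'   constants, the closed-form asymptotic Ki of the tissue kinetics,
#'   and `true_slope` — the Patlak slope a perfect analysis recovers
#'   from a voxel of that class. The two differ by the blood-volume
#'   factor: the voxel signal is
#'   \eqn{C_t = (1 - V_b)(C_1 + C_2) + V_b C_p}, and the \eqn{V_b C_p}
#'   term contributes only to the intercept, so the recoverable slope
#'   is \eqn{(1 - V_b) K_i}. Blood classes carry the plasma curve, not
#'   a tissue model, and have `NA` kinetics.
#' @export
phantomGroundTruth <- function(spec) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  p <- function(x) c(x@k1, x@k2, x@k3, x@vb, asymptoticKi(x),
                     (1 - x@vb) * asymptoticKi(x))
  m <- rbind(muscle = p(spec@muscle), myocardium = p(spec@myocardium))
  data.frame(class = c(rownames(m), "blood_pool", "vena_cava"),
             code = .phantomClassMap[c(rownames(m), "blood_pool", "vena_cava")],
             K1 = c(m[, 1], NA, NA), k2 = c(m[, 2], NA, NA),
             k3 = c(m[, 3], NA, NA), vb = c(m[, 4], NA, NA),
             true_ki = c(m[, 5], NA, NA),
             true_slope = c(m[, 6], NA, NA), row.names = NULL)
}

#' Build a dynamic phantom image
#'
#' Every voxel of a tissue class carries that class's frame-averaged
#' model curve; blood-pool and vena-cava voxels carry the frame-averaged
#' plasma curve; background voxels are zero. With `noiseScale > 0`,
#' independent frame-duration-weighted Gaussian noise (the [addNoise()]
#' law) is added per voxel and frame, seeded by the spec.
#'
#' @param spec A [PhantomSpec-class].
#' @param plasma A [PlasmaModel-class] driving all classes.
#' @return A [DynamicImage-class] with ground-truth labels attached.
#' @examples
#' img <- buildPhantom(phantomSpec(), plasmaModel())
#' @export
buildPhantom <- function(spec, plasma = plasmaModel()) {
  stopifnot(methods::is(spec, "PhantomSpec"))
  lab <- .phantomLabels(spec)
  sch <- spec@schedule
  tEnd <- totalDuration(sch, "min")
  fineT <- seq(0, tEnd, by = 0.5 / 60)
  bloodTac <- frameAverage(
    data.frame(time_min = fineT, conc_kBq_ml = evalPlasma(plasma, fineT)),
    sch, "blood")
  curves <- list(
    muscle = frameAverage(simulateTissue(spec@muscle, plasma, tEnd = tEnd),
                          sch, "muscle"),
    myocardium = frameAverage(simulateTissue(spec@myocardium, plasma,
                                             tEnd = tEnd), sch, "myocardium"),
    blood_pool = bloodTac, vena_cava = bloodTac)
  nf <- nFrames(sch)
  nvox <- prod(spec@dim)
  arr <- array(0, c(spec@dim, nf))
  durMin <- frameDurations(sch, "min")
  withSeed(if (spec@noiseScale > 0) spec@seed else NULL, {
    for (cls in names(curves)) {
      idx <- which(lab == .phantomClassMap[[cls]])
      if (!length(idx)) next
      act <- activity(curves[[cls]])
      for (f in seq_len(nf)) {
        v <- rep(act[f], length(idx))
        if (spec@noiseScale > 0) {
          sd <- spec@noiseScale * sqrt(max(act[f], 0.01) / durMin[f])
          v <- pmax(v + stats::rnorm(length(idx), 0, sd), 0)
        }
        arr[idx + (f - 1) * nvox] <- v
      }
    }
  })
  dynamicImage(arr, spec@voxelSize, sch, labels = lab,
               classes = .phantomClassMap)
}
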