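# Shared fixtures, built once per test run. Everything is generated in
# code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# frame-averaged plasma curve (the ideal image-derived input function)
# on a given schedule
idealIdif <- function(plasma = plasmaModel(), sched = fdgFrameSchedule()) {
  fineT <- seq(0, totalDuration(sched, "min"), by = 0.5 / 60)
  frameAverage(data.frame(time_min = fineT,
                          conc_kBq_ml = evalPlasma(plasma, fineT)),
               sched, "blood")
}

# frame-averaged tissue curve for one kinetic parameter set
regionTac <- function(params, plasma = plasmaModel(),
                      sched = fdgFrameSchedule(), label = "tissue") {
  frameAverage(simulateTissue(params, plasma,
                              tEnd = totalDuration(sched, "min")),
               sched, label)
}

# the default noise-free phantom, built once (used by ROI, map and
# acceptance tests)
defaultPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- buildPhantom(phantomSpec(), plasmaModel())
  .fixtures$phantom
}

# brute-force enumeration of voxel centers strictly inside a disc of
# the given diameter (independent oracle for digital-cylinder counts)
bruteDiscCount <- function(diameterPx) {
  r <- diameterPx / 2
  span <- -ceiling(r):ceiling(r)
  sum(outer(span^2, span^2, `+`) < r^2)
}

# search volume covering the voxels of one phantom class, padded by a
# margin of background
classBox <- function(image, code, pad = 2L) {
  lab <- tissueLabels(image)
  idx <- which(lab == code, arr.ind = TRUE)
  dm <- dim(lab)
  boxMask(image,
          c(max(1L, min(idx[, 1]) - pad), min(dm[1], max(idx[, 1]) + pad)),
          c(max(1L, min(idx[, 2]) - pad), min(dm[2], max(idx[, 2]) + pad)),
          c(max(1L, min(idx[, 3]) - pad), min(dm[3], max(idx[, 3]) + pad)))
}
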