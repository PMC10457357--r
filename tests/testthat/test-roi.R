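# small deterministic image for geometric tests
.toyImage <- function(vals = NULL, dm = c(12L, 12L, 8L), nf = 3L) {
  arr <- if (is.null(vals)) array(1, c(dm, nf)) else vals
  dynamicImage(arr, 0.4, frameSchedule(rep(60, nf)))
}

test_that("cylinder ROIs rasterise as strict-interior digital discs", {
  img <- .toyImage()
  one <- cylinderROI(img, c(6, 6, 4), diameterPx = 1, nSlices = 1)
  expect_equal(nVoxels(one), 1L)
  expect_true(maskArray(one)[6, 6, 4])

  img2 <- .toyImage(dm = c(24L, 24L, 12L))
  ten <- cylinderROI(img2, c(12, 12, 2), diameterPx = 10, nSlices = 10)
  expect_equal(nVoxels(ten), 10L * bruteDiscCount(10))
  # disjoint left + right cylinders: union size is the sum of parts
  img3 <- .toyImage(dm = c(48L, 24L, 12L))
  left <- cylinderROI(img3, c(12, 12, 2), 10, 10)
  right <- cylinderROI(img3, c(36, 12, 2), 10, 10)
  expect_equal(sum(maskArray(left) | maskArray(right)),
               nVoxels(left) + nVoxels(right))
  expect_error(cylinderROI(img, c(6, 6, 7), 10, 10), "geometry")
})

test_that("cylinder axis argument orients the cylinder correctly", {
  img <- .toyImage(dm = c(24L, 12L, 24L))
  m <- cylinderROI(img, c(2, 6, 12), diameterPx = 6, nSlices = 4, axis = 1L)
  expect_equal(nVoxels(m), 4L * bruteDiscCount(6))
  # all voxels lie in x-slabs 2..5
  idx <- which(maskArray(m), arr.ind = TRUE)
  expect_setequal(unique(idx[, 1]), 2:5)
})

test_that("last-frame threshold rule is inclusive at the cut", {
  dm <- c(6L, 6L, 2L)
  arr <- array(0, c(dm, 2))
  arr[, , , 2] <- 10
  arr[1, 1, 1, 2] <- 100
  arr[2, 1, 1, 2] <- 40     # exactly at 40% of the max: must be included
  arr[3, 1, 1, 2] <- 39.99  # just below: excluded
  img <- dynamicImage(arr, 0.4, frameSchedule(c(60, 60)))
  search <- boxMask(img, c(1, 6), c(1, 6), c(1, 2))
  m <- thresholdROILastFrame(img, search, 0.40)
  expect_true(maskArray(m)[1, 1, 1])
  expect_true(maskArray(m)[2, 1, 1])
  expect_false(maskArray(m)[3, 1, 1])
  expect_equal(maskProvenance(m)$threshold_kBq_ml, 40)
  # uniform activity: the whole search volume is at the maximum
  uni <- .toyImage()
  s2 <- boxMask(uni, c(2, 5), c(2, 5), c(1, 3))
  expect_equal(nVoxels(thresholdROILastFrame(uni, s2)), nVoxels(s2))
})

test_that("the 40% rule recovers the phantom myocardial shell exactly", {
  img <- defaultPhantom()
  search <- classBox(img, classMap(img)[["myocardium"]])
  m <- thresholdROILastFrame(img, search, 0.40)
  expect_identical(which(maskArray(m)),
                   which(tissueLabels(img) == classMap(img)[["myocardium"]]))
})

test_that("vena cava rule picks the first frame with uptake and a strict cut", {
  dm <- c(6L, 6L, 4L)
  nf <- 6L
  arr <- array(0, c(dm, nf))
  arr[3, 3, , 3:6] <- 50    # activity appears only from frame 3 onward
  arr[4, 3, , 3:6] <- 30    # exactly 60% of 50: strict rule excludes it
  arr[4, 4, , 3:6] <- 31
  img <- dynamicImage(arr, 0.4, frameSchedule(rep(30, nf)))
  search <- boxMask(img, c(1, 6), c(1, 6), c(1, 4))
  m <- venaCavaROI(img, search, 0.60)
  expect_equal(maskProvenance(m)$reference_frame, 3L)
  expect_true(all(maskArray(m)[3, 3, ]))
  expect_false(any(maskArray(m)[4, 3, ]))
  expect_true(all(maskArray(m)[4, 4, ]))
  # nothing ever reaches uptake in a zero image
  zero <- dynamicImage(array(0, c(dm, nf)), 0.4, frameSchedule(rep(30, nf)))
  expect_error(venaCavaROI(zero, search), "degenerate")
})

test_that("the 60% rule recovers the phantom vena-cava tube", {
  img <- defaultPhantom()
  code <- classMap(img)[["vena_cava"]]
  m <- venaCavaROI(img, classBox(img, code))
  tube <- which(tissueLabels(img) == code)
  expect_true(all(which(maskArray(m)) %in% tube))
  expect_gte(length(intersect(which(maskArray(m)), tube)) / length(tube),
             0.90)
})

test_that("threshold masks are monotone in the fraction and idempotent", {
  set.seed(5)
  dm <- c(10L, 10L, 6L)
  arr <- array(stats::runif(prod(dm) * 4, 0, 100), c(dm, 4))
  img <- dynamicImage(arr, 0.4, frameSchedule(rep(60, 4)))
  search <- boxMask(img, c(2, 9), c(2, 9), c(1, 6))
  for (fr in list(c(0.2, 0.5), c(0.4, 0.6), c(0.3, 0.9))) {
    lo <- thresholdROILastFrame(img, search, fr[1])
    hi <- thresholdROILastFrame(img, search, fr[2])
    expect_true(all(which(maskArray(hi)) %in% which(maskArray(lo))))
  }
  m <- thresholdROILastFrame(img, search, 0.40)
  again <- thresholdROILastFrame(img, m, 0.40)
  expect_identical(maskArray(again), maskArray(m))
})

test_that("TAC extraction is an unweighted mean and linear in the image", {
  img <- .toyImage(array(4.2, c(12, 12, 8, 3)))
  search <- boxMask(img, c(1, 4), c(1, 4), c(1, 2))
  expect_equal(activity(extractTAC(img, search)), rep(4.2, 3))
  # singleton mask reproduces the voxel series
  dm <- c(5L, 5L, 3L)
  arr <- array(stats::rnorm(prod(dm) * 4), c(dm, 4))
  img2 <- dynamicImage(arr, 0.4, frameSchedule(rep(60, 4)))
  single <- array(FALSE, dm); single[2, 3, 1] <- TRUE
  expect_equal(activity(extractTAC(img2, single)), arr[2, 3, 1, ])
  # linearity: scaling the image scales the TAC
  img3 <- dynamicImage(3 * arr, 0.4, frameSchedule(rep(60, 4)))
  box <- array(TRUE, dm)
  expect_equal(activity(extractTAC(img3, box)),
               3 * activity(extractTAC(img2, box)))
})

test_that("phantom muscle TAC round-trips through build and extraction", {
  img <- defaultPhantom()
  muscleMask <- tissueLabels(img) == classMap(img)[["muscle"]]
  tac <- extractTAC(img, muscleMask)
  expect_equal(activity(tac),
               activity(regionTac(phantomSpec()@muscle, plasmaModel(),
                                  schedule(img))),
               tolerance = 1e-10)
})

test_that("empty or mismatched masks are rejected", {
  img <- .toyImage()
  empty <- array(FALSE, c(12L, 12L, 8L))
  expect_error(extractTAC(img, empty), "empty")
  wrong <- array(TRUE, c(3L, 3L, 3L))
  expect_error(extractTAC(img, wrong), "grid")
})
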