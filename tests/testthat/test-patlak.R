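test_that("cumulative input integral handles constants and single frames", {
  sch <- fdgFrameSchedule()
  mids <- frameMidTimes(sch, "min")
  const <- timeActivityCurve(sch, rep(2.5, 24))
  expect_equal(cumulativeInputIntegral(const), 2.5 * mids, tolerance = 1e-12)
  one <- timeActivityCurve(frameSchedule(60), 4)
  expect_equal(cumulativeInputIntegral(one), 4 * 0.5)
})

test_that("trapezoid input integral tracks the closed form", {
  # the bolus model sampled through the 24-frame schedule; the analytic
  # running integral is the oracle. Around the bolus peak the sparse
  # frame grid cannot resolve the curvature, so accuracy is asserted
  # where the abscissa is consumed: the full-schedule cumulative value
  # and the per-frame increments inside the fit window.
  sch <- fdgFrameSchedule()
  mids <- frameMidTimes(sch, "min")
  pm <- plasmaModel()
  tac <- timeActivityCurve(sch, evalPlasma(pm, mids))
  est <- cumulativeInputIntegral(tac)
  exact <- plasmaIntegral(pm, mids)
  expect_lt(abs(est[24] - exact[24]) / exact[24], 0.005)
  win <- which(mids >= 16 & mids <= 40)
  incErr <- abs(diff(est) - diff(exact)) / diff(exact)
  expect_lt(max(incErr[win - 1]), 0.005)
})

test_that("Patlak transform reproduces an exact linear system", {
  sch <- fdgFrameSchedule()
  idif <- idealIdif(sched = sch)
  integ <- cumulativeInputIntegral(idif)
  tissue <- timeActivityCurve(sch, 0.02 * integ)
  pts <- patlakTransform(tissue, idif)
  expect_true(all(pts$usable))
  expect_equal(pts$y, 0.02 * pts$x, tolerance = 1e-12)
})

test_that("frames without input activity are flagged unusable", {
  sch <- fdgFrameSchedule()
  cp <- activity(idealIdif(sched = sch))
  cp[1:2] <- 0
  idif <- timeActivityCurve(sch, cp)
  tissue <- timeActivityCurve(sch, rep(1, 24))
  pts <- patlakTransform(tissue, idif)
  expect_false(any(pts$usable[1:2]))
  expect_equal(pts$reason[1:2], c("low_input", "low_input"))
  expect_true(all(pts$usable[3:24]))
  allZero <- timeActivityCurve(sch, rep(0, 24))
  expect_error(patlakTransform(tissue, allZero), "degenerate")
  expect_error(patlakTransform(tissue, idealIdif()), NA)
  shorter <- timeActivityCurve(frameSchedule(rep(60, 5)), rep(1, 5))
  expect_error(patlakTransform(shorter, idif), "schedule")
})

test_that("a simulated irreversible system turns linear late with the closed-form slope", {
  p <- compartmentParams(0.1, 0.2, 0.05)
  pts <- patlakTransform(regionTac(p), idealIdif())
  fit <- fitPatlak(pts)
  expect_equal(ki(fit), asymptoticKi(p), tolerance = 0.01)
  expect_gt(rSquared(fit), 0.9999)
})

test_that("the windowed OLS fit behaves on exact, flat and deficient input", {
  mids <- frameMidTimes(fdgFrameSchedule(), "min")
  exact <- data.frame(mid_min = mids, x = mids, y = 0.02 * mids + 0.5,
                      usable = TRUE, reason = "")
  fit <- fitPatlak(exact)
  expect_equal(ki(fit), 0.02, tolerance = 1e-12)
  expect_equal(v0(fit), 0.5, tolerance = 1e-10)
  expect_equal(rSquared(fit), 1)
  expect_equal(nFramesUsed(fit), 7L)  # mid-times inside [16, 40]
  flat <- exact; flat$y <- 2
  ffit <- fitPatlak(flat)
  expect_equal(ki(ffit), 0)
  expect_true("flat" %in% qualityFlags(ffit))
  expect_true(is.na(rSquared(ffit)))
  neg <- exact; neg$y <- -0.01 * mids
  expect_true("negative_slope" %in% qualityFlags(fitPatlak(neg)))
  expect_lt(ki(fitPatlak(neg)), 0)
  expect_error(fitPatlak(exact, window = c(39.9, 40)), "insufficient")
  expect_error(fitPatlak(exact, window = c(40, 16)), "window")
})

test_that("OLS estimates equal a centered normal-equation oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- sort(stats::runif(n, 10, 50))
    y <- 0.03 * x + stats::rnorm(n, 0, 0.2)
    pts <- data.frame(mid_min = x, x = x, y = y, usable = TRUE, reason = "")
    fit <- fitPatlak(pts, window = range(x))
    xc <- x - mean(x)
    slope <- sum(xc * y) / sum(xc^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(ki(fit), slope, tolerance = 1e-10)
    expect_equal(v0(fit), intercept, tolerance = 1e-10)
  }
})

test_that("Ki is invariant to joint scaling and equivariant to tissue scaling", {
  p <- compartmentParams(0.15, 0.3, 0.08)
  tissue <- regionTac(p)
  idif <- idealIdif()
  base <- ki(fitPatlak(patlakTransform(tissue, idif)))
  scale <- function(tac, c) timeActivityCurve(schedule(tac),
                                              c * activity(tac))
  joint <- ki(fitPatlak(patlakTransform(scale(tissue, 3.7),
                                        scale(idif, 3.7))))
  expect_equal(joint, base, tolerance = 1e-12)
  tisOnly <- ki(fitPatlak(patlakTransform(scale(tissue, 2), idif)))
  expect_equal(tisOnly, 2 * base, tolerance = 1e-12)
})

test_that("mean scan glucose converts units as declared", {
  panel <- meanCglu(c(10, 11, 12), "mmol/L", times = c(10, 20, 40))
  expect_equal(meanGlucose(panel), 11 * 18.016)
  expect_equal(meanGlucose(panel, "mmol/L"), 11)
  expect_equal(length(panel@values), 3L)
  expect_equal(meanGlucose(meanCglu(130, "mg/dL")), 130)
  expect_error(meanCglu(c(10, -1), "mmol/L"), "positive")
})

test_that("MRglu_max is Ki times (Km + Cglu), with Km recoverable exactly", {
  mids <- frameMidTimes(fdgFrameSchedule(), "min")
  mkFit <- function(slope) fitPatlak(data.frame(
    mid_min = mids, x = mids, y = slope * mids, usable = TRUE, reason = ""))
  panel <- meanCglu(270, "mg/dL")
  res <- mrgluMax(mkFit(0.02), panel)
  expect_equal(mrglu(res), 0.02 * (130 + 270))  # = 8.0
  expect_equal(mrglu(res) / ki(res) - res@cgluMgDl, 130)
  # zero slope propagates to zero rate for any glucose
  z <- mrgluMax(mkFit(0), meanCglu(25, "mmol/L"))
  expect_equal(mrglu(z), 0)
  # strictly increasing and exactly linear in Cglu with slope Ki
  rates <- vapply(c(100, 200, 300), function(g)
    mrglu(mrgluMax(mkFit(0.02), meanCglu(g, "mg/dL"))), numeric(1))
  expect_equal(diff(rates), 0.02 * c(100, 100), tolerance = 1e-12)
  # negative slope propagates with its flag rather than erroring
  neg <- mrgluMax(mkFit(-0.01), panel)
  expect_true("negative_slope" %in% qualityFlags(neg))
  expect_lt(mrglu(neg), 0)
})

test_that("voxel Ki maps match per-class closed forms on the phantom", {
  img <- defaultPhantom()
  lab <- tissueLabels(img)
  idif <- extractTAC(img, lab == classMap(img)[["vena_cava"]])
  body <- lab > 0
  res <- patlakParametricMap(img, idif, bodyMask = body)
  gt <- phantomGroundTruth(phantomSpec())
  for (cls in c("muscle", "myocardium")) {
    truth <- gt$true_slope[gt$class == cls]
    vals <- res$ki[lab == classMap(img)[[cls]]]
    expect_lt(stats::median(abs(vals - truth) / truth), 0.02)
  }
  expect_true(all(res$quality[!body] == 1L))
  expect_true(all(is.na(res$ki[!body])))
})

test_that("a single-voxel map agrees with the scalar fit path", {
  img <- defaultPhantom()
  lab <- tissueLabels(img)
  idif <- extractTAC(img, lab == classMap(img)[["vena_cava"]])
  vox <- which(lab == classMap(img)[["muscle"]], arr.ind = TRUE)[1, ]
  m <- array(FALSE, dim(lab)); m[vox[1], vox[2], vox[3]] <- TRUE
  res <- patlakParametricMap(img, idif, bodyMask = m)
  scalar <- fitPatlak(patlakTransform(extractTAC(img, m), idif))
  expect_equal(res$ki[m][1], ki(scalar), tolerance = 1e-10)
  expect_equal(res$r_squared[m][1], rSquared(scalar), tolerance = 1e-8)
})

test_that("map voxels with no activity get a sentinel and reason code", {
  img <- defaultPhantom()
  lab <- tissueLabels(img)
  idif <- extractTAC(img, lab == classMap(img)[["vena_cava"]])
  body <- lab > 0
  bg <- which(lab == 0L)[1:50]
  body[bg] <- TRUE     # deliberately include zero-activity background
  res <- patlakParametricMap(img, idif, bodyMask = body)
  expect_true(all(res$quality[bg] == 2L))
  expect_true(all(is.na(res$ki[bg])))
})
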