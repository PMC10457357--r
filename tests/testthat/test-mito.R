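.handTrace <- function() {
  data.frame(
    well = "W1", condition = "control",
    measurement_index = 1:12,
    phase = rep(c("baseline", "oligomycin", "fccp", "rot_aa"), each = 3),
    ocr = c(98, 101, 100, 45, 40, 42, 150, 160, 155, 12, 10, 11),
    ecar = c(20, 20, 20, 25, 25, 25, 30, 30, 30, 15, 15, 15))
}

test_that("phase summaries apply last/min/max/min vendor rules", {
  s <- phaseSummaries(.handTrace())
  expect_equal(unname(s), c(100, 40, 160, 10))
  custom <- phaseSummaries(.handTrace(),
                           rules = c(baseline = "mean", oligomycin = "min",
                                     fccp = "max", rot_aa = "min"))
  expect_equal(unname(custom[1]), mean(c(98, 101, 100)))
  broken <- .handTrace()[.handTrace()$phase != "fccp", ]
  expect_error(phaseSummaries(broken), "fccp")
})

test_that("mito parameters follow the definitional arithmetic", {
  p <- mitoParams(.handTrace())
  expect_equal(p$non_mito, 10)
  expect_equal(p$basal, 90)
  expect_equal(p$proton_leak, 30)
  expect_equal(p$atp_linked, 60)
  expect_equal(p$maximal, 150)
  expect_equal(p$spare_capacity, 60)
  expect_equal(p$coupling_efficiency, 60 / 90)
  expect_equal(p$ocr_ecar_ratio, 100 / 20)
  # fully coupled limit: oligomycin plateau equals non-mito -> zero leak
  tr <- .handTrace(); tr$ocr[4:6] <- 10
  expect_equal(mitoParams(tr)$proton_leak, 0)
  # zero background: basal equals the raw baseline summary
  tr2 <- .handTrace(); tr2$ocr[10:12] <- 0
  expect_equal(mitoParams(tr2)$basal, 100)
})

test_that("conservation identities hold exactly on randomized traces", {
  set.seed(23)
  for (rep in seq_len(1000)) {
    tr <- data.frame(
      measurement_index = 1:8,
      phase = rep(c("baseline", "oligomycin", "fccp", "rot_aa"), each = 2),
      ocr = stats::runif(8, 0, 200))
    p <- mitoParams(tr)
    expect_equal(p$basal, p$atp_linked + p$proton_leak, tolerance = 1e-12)
    expect_equal(p$spare_capacity, p$maximal - p$basal, tolerance = 1e-12)
  }
})

test_that("adding a constant to all OCR shifts only non-mito respiration", {
  tr <- .handTrace()
  shifted <- tr; shifted$ocr <- tr$ocr + 17
  a <- mitoParams(tr); b <- mitoParams(shifted)
  expect_equal(b$non_mito, a$non_mito + 17)
  for (col in c("basal", "proton_leak", "atp_linked", "maximal",
                "spare_capacity"))
    expect_equal(b[[col]], a[[col]])
})

test_that("negative-rate traces are flagged rather than raised", {
  tr <- .handTrace()
  tr$ocr[1:3] <- 5  # baseline below non-mito background
  p <- mitoParams(tr)
  expect_lt(p$basal, 0)
  expect_match(p$flags, "negative_basal")
})

test_that("the preference ratio uses the last baseline measurement", {
  expect_equal(ocrEcarRatio(.handTrace()), 5)
  eq <- .handTrace(); eq$ecar[3] <- eq$ocr[3]
  expect_equal(ocrEcarRatio(eq), 1)
  zero <- .handTrace(); zero$ecar[3] <- 0
  expect_true(is.na(ocrEcarRatio(zero)))
  expect_error(ocrEcarRatio(.handTrace(), measurementIndex = 5),
               "not a baseline")
  expect_error(ocrEcarRatio(.handTrace(), measurementIndex = 99),
               "not present")
})

test_that("zero-noise plates recover plateau differences exactly", {
  plate <- simulateMitoPlate(mitoPreset("control", ocrSd = 0, ecarSd = 0))
  expect_equal(sort(unique(plate$ocr)), c(10, 40, 100, 160))
  res <- mitoParamsByWell(plate)
  expect_equal(unique(res$perWell$basal), 90)
  expect_equal(unique(res$perWell$proton_leak), 30)
  expect_equal(unique(res$perWell$maximal), 150)
  expect_equal(res$perCondition$sem_basal, 0)
  # post-oligomycin OCR sits below baseline in the control preset
  expect_lt(unique(plate$ocr[plate$phase == "oligomycin"]),
            unique(plate$ocr[plate$phase == "baseline"]))
})

test_that("the uncoupled preset shows larger proton leak and oxidative preference", {
  ctrl <- mitoParamsByWell(simulateMitoPlate(
    mitoPreset("control", ocrSd = 0, ecarSd = 0)))$perCondition
  unc <- mitoParamsByWell(simulateMitoPlate(
    mitoPreset("uncoupled", ocrSd = 0, ecarSd = 0)))$perCondition
  expect_gt(unc$proton_leak, ctrl$proton_leak)
  expect_gt(unc$ocr_ecar_ratio, ctrl$ocr_ecar_ratio)
  # and with realistic noise the ordering still holds on well means
  ctrlN <- mitoParamsByWell(simulateMitoPlate(
    mitoPreset("control", seed = 2L)))$perCondition
  uncN <- mitoParamsByWell(simulateMitoPlate(
    mitoPreset("uncoupled", seed = 2L)))$perCondition
  expect_gt(uncN$proton_leak, ctrlN$proton_leak)
})

test_that("plate simulation is seeded and annotated in fixed phase order", {
  a <- simulateMitoPlate(mitoPreset("control", seed = 9L))
  b <- simulateMitoPlate(mitoPreset("control", seed = 9L))
  expect_identical(a, b)
  one <- a[a$well == a$well[1], ]
  expect_equal(one$phase,
               rep(c("baseline", "oligomycin", "fccp", "rot_aa"), each = 3))
  expect_equal(one$measurement_index, 1:12)
  expect_true(all(a$ocr >= 0) && all(a$ecar >= 0))
})
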