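test_that("plasma model is zero at injection and matches its closed form", {
  pm <- plasmaModel()
  expect_equal(evalPlasma(pm, 0), 0)
  # independent hand evaluation of the sum-of-exponentials form
  byHand <- function(t) {
    350 * (exp(-0.9 * t) - exp(-5 * t)) + 80 * (exp(-0.008 * t) - exp(-5 * t))
  }
  for (t in c(1, 5, 40))
    expect_equal(evalPlasma(pm, t), byHand(t), tolerance = 1e-12)
  expect_error(evalPlasma(pm, -1), "times")
})

test_that("plasma curve has a single early peak then monotone decay", {
  pm <- plasmaModel()
  t <- seq(0, 40, by = 0.01)
  y <- evalPlasma(pm, t)
  expect_true(all(y >= 0))
  pk <- which.max(y)
  expect_lt(t[pk], 2)           # bolus peak within the first 2 min
  expect_true(all(diff(y[pk:length(y)]) <= 0))
  expect_true(all(diff(y[1:pk]) >= 0))
})

test_that("closed-form plasma integral agrees with adaptive quadrature", {
  pm <- plasmaModel()
  for (t in c(0.5, 5, 40)) {
    q <- stats::integrate(function(x) evalPlasma(pm, x), 0, t,
                          rel.tol = 1e-10)$value
    expect_equal(plasmaIntegral(pm, t), q, tolerance = 1e-8)
  }
})

test_that("tissue simulation degenerates correctly at edge kinetics", {
  # pure integrator: constant plasma, K1 only -> Ct = K1 * t
  t <- seq(0, 10, by = 0.5 / 60)
  cp <- rep(1, length(t))
  p <- compartmentParams(0.1, 0, 0)
  ct <- PatlakPET:::.tissueFromPlasma(p, t, cp)
  expect_equal(ct, 0.1 * t, tolerance = 1e-10)
  # no exchange: K1 = 0 -> Ct = Vb * Cp
  p0 <- compartmentParams(0, 0.2, 0.05, vb = 0.04)
  pm <- plasmaModel()
  cpReal <- evalPlasma(pm, t)
  expect_equal(PatlakPET:::.tissueFromPlasma(p0, t, cpReal), 0.04 * cpReal)
  # conservation: Vb = 0 and k2 = k3 = 0 and K1 = 0 -> identically zero
  expect_equal(PatlakPET:::.tissueFromPlasma(compartmentParams(0, 0, 0),
                                             t, cpReal),
               rep(0, length(t)))
})

test_that("simulated tissue reaches the closed-form Patlak asymptote", {
  # plateau input: late slope of Ct vs cumulative input = K1 k3/(k2+k3)
  t <- seq(0, 120, by = 0.5 / 60)
  cp <- rep(1, length(t))
  p <- compartmentParams(0.1, 0.2, 0.05)
  ct <- PatlakPET:::.tissueFromPlasma(p, t, cp)
  icp <- cumsum(c(0, (cp[-1] + cp[-length(cp)]) / 2 * diff(t)))
  late <- t > 100
  slope <- stats::coef(stats::lm(ct[late] ~ icp[late]))[2]
  expect_equal(unname(slope), 0.02, tolerance = 0.01)
})

test_that("analytic convolution matches an independent ODE solver", {
  requireNamespace("deSolve")
  pm <- plasmaModel()
  p <- compartmentParams(0.12, 0.3, 0.07, vb = 0.05)
  fine <- simulateTissue(p, pm, tEnd = 40)
  rhs <- function(t, y, parms) {
    cp <- evalPlasma(pm, t)
    list(c(0.12 * cp - (0.3 + 0.07) * y[1], 0.07 * y[1]))
  }
  tout <- seq(0, 40, by = 0.25)
  ode <- deSolve::ode(c(0, 0), tout, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  ctOde <- (1 - 0.05) * (ode[, 2] + ode[, 3]) +
    0.05 * evalPlasma(pm, tout)
  ctPkg <- stats::approx(fine$time_min, fine$conc_kBq_ml, tout)$y
  expect_equal(ctPkg, ctOde, tolerance = 1e-5)
})

test_that("tissue simulation rejects bad inputs", {
  p <- compartmentParams(0.1, 0.2, 0.05)
  expect_error(simulateTissue(p, plasmaModel(), fineDt = 0.1), "fineDt")
  expect_error(simulateTissue(p, plasmaModel(), tEnd = 0), "degenerate")
})

test_that("frame averaging is exact for constant and linear curves", {
  sch <- fdgFrameSchedule()
  t <- seq(0, 40, by = 0.5 / 60)
  constTac <- frameAverage(data.frame(t, rep(3.7, length(t))), sch)
  expect_equal(activity(constTac), rep(3.7, 24))
  # mean of a*t over a frame equals the value at the frame mid-time
  linTac <- frameAverage(data.frame(t, 2.5 * t), sch)
  expect_equal(activity(linTac), 2.5 * frameMidTimes(sch, "min"),
               tolerance = 1e-9)
  expect_equal(nFrames(linTac), 24L)
})

test_that("frame averaging commutes with scalar scaling", {
  sch <- fdgFrameSchedule()
  fine <- simulateTissue(compartmentParams(0.1, 0.2, 0.05), plasmaModel())
  a <- activity(frameAverage(fine, sch))
  fine2 <- fine
  fine2$conc_kBq_ml <- 7 * fine2$conc_kBq_ml
  expect_equal(activity(frameAverage(fine2, sch)), 7 * a)
})

test_that("frame averaging demands full schedule coverage", {
  sch <- fdgFrameSchedule()
  t <- seq(0, 30, by = 0.5 / 60)   # stops at 30 min, schedule runs to 40
  expect_error(frameAverage(data.frame(t, t), sch), "coverage")
})

test_that("noise injection follows its stated law and seed contract", {
  tac <- regionTac(compartmentParams(0.1, 0.2, 0.05))
  expect_identical(addNoise(tac, 0), tac)
  expect_equal(activity(addNoise(tac, 1, seed = 42)),
               activity(addNoise(tac, 1, seed = 42)))
  expect_false(isTRUE(all.equal(activity(addNoise(tac, 1, seed = 42)),
                                activity(addNoise(tac, 1, seed = 43)))))
  # Monte-Carlo check of sd = scale * sqrt(activity / duration) at the
  # last frame (5 min duration)
  f <- 24L
  act <- activity(tac)[f]
  expectedSd <- 0.8 * sqrt(act / 5)
  draws <- vapply(seq_len(1000), function(i)
    activity(addNoise(tac, 0.8, seed = i))[f], numeric(1))
  expect_lt(abs(stats::sd(draws) - expectedSd) / expectedSd, 0.10)
  # clipped at zero
  cold <- timeActivityCurve(schedule(tac), rep(0.001, 24))
  expect_true(all(activity(addNoise(cold, 5, seed = 1)) >= 0))
})

test_that("seeded generation leaves the session RNG stream untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(addNoise(regionTac(compartmentParams(0.1, 0.2, 0.05)),
                     1, seed = 7))
  expect_identical(.Random.seed, before)
})
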