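# Component functions of the gastric feedback model.

test_that("the retention curve is full at t=0, empty in the limit, and its
           half-crossing matches root finding", {
  b <- exp(0.009 * 91.72)
  expect_equal(retainedFraction(0, 0.009, b), 1)
  expect_lt(retainedFraction(5000, 0.009, b), 1e-12)
  # monotone non-increasing on a grid
  fr <- retainedFraction(seq(0, 600, by = 1), 0.009, b)
  expect_true(all(diff(fr) <= 0))
  # half-crossing at the root-finding oracle's value (~149 min)
  tHalf <- thalfRetentionOracle(0.009, 91.72)
  expect_equal(retainedFraction(tHalf, 0.009, b), 0.5, tolerance = 1e-9)
  expect_equal(tHalf, 148.8847, tolerance = 1e-4)
  expect_error(retainedFraction(-1, 0.009, b), ">= 0")
  expect_error(retainedFraction(1, -0.1, b), "> 0")
})

test_that("emptied increments telescope: load is conserved to 1e-9", {
  p <- stomachParams(k = 0.009, T_LAG = 91.72, CAL_GRD = 1)
  st <- newStomachState(p)
  st <- gastroSim:::stomachIntake(st, 35.6)
  total <- 0
  for (i in 1:2000) {
    adv <- emptiedIncrement(st, p, dt = 1)
    st <- adv$state
    total <- total + adv$nut
    expect_gte(adv$nut, 0)
  }
  expect_equal(total + st$retained, 35.6, tolerance = 1e-9)
  # and the closed form agrees with the discrete path at every step width
  expect_equal(st$retained,
               35.6 * retainedFraction(2000, p$k, exp(p$k * p$T_LAG)),
               tolerance = 1e-9)
})

test_that("the first minute's emptying equals the retention-curve difference", {
  p <- stomachParams(k = 0.009, T_LAG = 91.72, CAL_GRD = 0.6)
  b <- exp(p$k * p$T_LAG)
  st <- gastroSim:::stomachIntake(newStomachState(p), 35.6)
  adv <- emptiedIncrement(st, p, dt = 1)
  oracle <- 35.6 * (retainedFraction(0, p$k, b) - retainedFraction(1, p$k, b))
  expect_equal(adv$nut, oracle * 0.6, tolerance = 1e-9)
  # empty stomach gives nothing
  empty <- newStomachState(p)
  expect_equal(emptiedIncrement(empty, p)$nut, 0)
})

test_that("sgmd is the expected sigmoid", {
  expect_equal(sgmd(0, 0.3), 0)
  expect_equal(sgmd(1, 0.3), 2 / (1 + exp(-0.3)) - 1)
  expect_equal(sgmd(1, 0.3), 0.148885, tolerance = 1e-6)
  expect_equal(sgmd(1e9, 0.3), 1, tolerance = 1e-12)
  x <- sgmd(seq(0, 10, by = 0.1), 0.3)
  expect_true(all(diff(x) > 0))
  expect_error(sgmd(-1, 0.3), ">= 0")
})

test_that("brake events reduce k multiplicatively and keep retention continuous", {
  p <- stomachParams(k = 0.009, T_LAG = 91.72, THD = 0.45, IR_TR = 0.3,
                     BRK = 0.03)
  st <- gastroSim:::stomachIntake(newStomachState(p), 35.6)
  for (i in 1:50) st <- emptiedIncrement(st, p)$state

  # below threshold: nothing happens
  noFire <- applyBrake(st, p, irVe = 0)
  expect_false(noFire$fired)
  expect_identical(noFire$state, st)

  # above threshold: k and b recomputed, retained untouched
  before <- st$retained
  fired <- applyBrake(st, p, irVe = 10)   # sgmd(10*0.3) ~ 0.905 > 0.45
  expect_true(fired$fired)
  expect_equal(fired$state$k, 0.009 * 0.97)
  expect_equal(fired$state$b, exp(0.009 * 0.97 * 91.72))
  expect_identical(fired$state$retained, before)
  # the re-solved virtual time reproduces the same retained fraction
  expect_equal(fired$state$load *
                 retainedFraction(fired$state$tau, fired$state$k,
                                  fired$state$b),
               before, tolerance = 1e-9)

  # 15 events compound to k * 0.97^15 exactly
  st15 <- st
  for (i in 1:15) st15 <- applyBrake(st15, p, irVe = 10)$state
  expect_equal(st15$k, 0.009 * 0.97^15, tolerance = 1e-12)
  # at fixed shape b the no-feedback half-emptying time scales as 1/k, so
  # 15 events stretch it by exactly 1/0.97^15
  b0 <- exp(0.009 * 91.72)
  tAt <- function(k) -log(1 - 0.5^(1 / b0)) / k
  expect_equal(tAt(st15$k) / tAt(0.009), 1 / 0.97^15, tolerance = 1e-12)
  # with b recomputed from the reduced k (as the model does), part of the
  # shift is absorbed by the shorter lag: the stretch per event sits
  # between half the brake fraction and the brake fraction itself
  ratio <- thalfRetentionOracle(st15$k, 91.72) /
    thalfRetentionOracle(0.009, 91.72)
  perEvent <- ratio^(1 / 15) - 1
  expect_gt(perEvent, 0.03 / 2.5)
  expect_lt(perEvent, 0.03)
})

test_that("across a brake the retention trajectory has no jump beyond one step", {
  p <- stomachParams(k = 0.009, T_LAG = 91.72, BRK = 0.03)
  st <- gastroSim:::stomachIntake(newStomachState(p), 35.6)
  for (i in 1:30) st <- emptiedIncrement(st, p)$state
  stepBefore <- emptiedIncrement(st, p)$nut / p$CAL_GRD
  braked <- applyBrake(st, p, irVe = 10)$state
  stepAfter <- emptiedIncrement(braked, p)$nut / p$CAL_GRD
  expect_equal(braked$retained, st$retained)
  expect_lte(abs(stepAfter - stepBefore), stepBefore)
})

test_that("a single afferent bolus peaks at T_MAX with the bolus amount", {
  for (invDr in c(0.02, 0.05, 0.1, 0.3, 0.7)) {
    p <- intestineParams(INV_DR = invDr, T_MAX = 10)
    expect_equal(afferentResponse(0, 2.5, t = 10, p), 2.5, tolerance = 1e-12)
    # dense grid search confirms the maximum sits at lag T_MAX
    lags <- seq(0.5, 80, by = 0.25)
    resp <- vapply(lags, function(s) afferentResponse(0, 1, s, p), 0)
    expect_equal(lags[which.max(resp)], 10)
    expect_lt(max(resp), 1 + 1e-12)
  }
})

test_that("the afferent response is linear in amounts and additive over boluses", {
  p <- intestineParams(INV_DR = 0.1, T_MAX = 10)
  expect_equal(afferentResponse(numeric(0), numeric(0), 50, p), 0)
  # brute-force superposition oracle over a random history
  set.seed(11)
  tt <- sort(sample(0:40, 8))
  amt <- runif(8, 0, 2)
  at <- 55
  oracle <- sum(vapply(seq_along(tt), function(i) {
    s <- at - tt[i]
    amt[i] * (0.1 * exp(1) / 1)^1 * s^1 * exp(-0.1 * s)
  }, 0))
  expect_equal(afferentResponse(tt, amt, at, p), oracle, tolerance = 1e-12)
  # homogeneity of degree 1
  expect_equal(afferentResponse(tt, 3 * amt, at, p),
               3 * afferentResponse(tt, amt, at, p), tolerance = 1e-12)
  # lags <= 0 contribute nothing
  expect_equal(afferentResponse(c(10, 60), c(1, 99), t = 60, p),
               afferentResponse(10, 1, t = 60, p))
})

test_that("the CNS transfer is proportional and TRF_K = 0 opens the loop", {
  expect_equal(efferentResponse(2, cnsParams(TRF_K = 1)), 2)
  expect_equal(efferentResponse(7.3, cnsParams(TRF_K = 0)), 0)
  expect_error(efferentResponse(-1, cnsParams()), ">= 0")
})

test_that("the brake constant derives from the reference half-time shift", {
  expect_identical(brkFromThalfShift(155, 237, 15), 0.03)
  expect_equal(brkFromThalfShift(155, 237, 15, round = FALSE),
               (237 / 155)^(1 / 15) - 1, tolerance = 1e-12)
  expect_equal(brkFromThalfShift(155, 237, 15, round = FALSE), 0.0287,
               tolerance = 1e-2)
  expect_equal(brkFromThalfShift(100, 100, 7), 0)
})

test_that("the caloric grade derives from intestinal segment lengths", {
  expect_identical(calGrdFromLengths(25, 260, 395), 0.6)
  expect_equal(calGrdFromLengths(25, 260, 395, round = FALSE), 395 / 680,
               tolerance = 1e-12)
  expect_equal(calGrdFromLengths(1, 1, 2), 0.5)
  expect_error(calGrdFromLengths(0, 1, 1), "> 0")
})

test_that("parameter constructors reject out-of-range values", {
  expect_error(stomachParams(k = 0), "k > 0")
  expect_error(stomachParams(THD = 1), "THD < 1")
  expect_error(stomachParams(BRK = 1.2), "BRK < 1")
  expect_error(intestineParams(INV_DR = 0), "INV_DR > 0")
  expect_error(cnsParams(TRF_K = -1), "TRF_K >= 0")
})
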