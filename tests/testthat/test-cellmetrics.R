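# Construct a 1-cell, 1-trial, 1-stimulus tensor whose baseline sd is
# exactly 1 and whose odor window contains a supra-threshold run of given
# length at the given level.
runTensor <- function(runLen, level = 3.5, nFrames = 80, fr = 20) {
  x <- numeric(nFrames)
  x[1:20] <- unitSdBaseline(20)
  if (runLen > 0) x[21:(20 + runLen)] <- level
  makeTensor(array(x, dim = c(1, nFrames, 1, 1)), preS = 1, odorS = 2,
             frameRate = fr)
}

test_that("500 ms activation boundary is exact: 10 frames yes, 9 no", {
  expect_true(detectActivated(runTensor(10))[1, 1, 1])
  expect_false(detectActivated(runTensor(9))[1, 1, 1])
  # threshold is strict in level too: at exactly 3 sd nothing activates
  expect_false(detectActivated(runTensor(12, level = 3))[1, 1, 1])
  expect_true(detectActivated(runTensor(12, level = 3 + 1e-6))[1, 1, 1])
})

test_that("duration rule is exact: 15 frames count, 14 do not, runs sum", {
  expect_equal(responseDuration(runTensor(15))$duration_s, 0.75)
  expect_equal(nrow(responseDuration(runTensor(14))), 0)
  # two qualifying runs of 20 and 16 frames separated by a gap
  x <- numeric(120)
  x[1:20] <- unitSdBaseline(20)
  x[26:45] <- 4; x[61:76] <- 4
  tens <- makeTensor(array(x, dim = c(1, 120, 1, 1)), preS = 1, odorS = 2)
  expect_equal(responseDuration(tens)$duration_s, (20 + 16) / 20)
  expect_equal(responseDuration(tens, rule = "longest")$duration_s, 1)
})

test_that("zero-baseline-sd cell-trials are indeterminate, not active", {
  x <- numeric(80); x[21:40] <- 5    # flat baseline
  tens <- makeTensor(array(x, dim = c(1, 80, 1, 1)))
  mask <- detectActivated(tens)
  expect_false(mask[1, 1, 1])
  expect_equal(attr(mask, "indeterminate"), 1L)
})

test_that("responsive percentage follows the trial-averaged definition", {
  mask <- array(FALSE, dim = c(4, 2, 1))
  mask[1, , 1] <- TRUE       # cell 1 active in both trials
  mask[2, 1, 1] <- TRUE      # cell 2 active in one trial
  expect_equal(unname(pctResponsive(mask)), 37.5)  # (2/4 + 1/4)/2 * 100
  expect_equal(unname(pctResponsive(array(TRUE, dim = c(3, 2, 2)))),
               c(100, 100))
  expect_equal(pctResponsive(array(FALSE, dim = c(3, 2, 2)),
                             per = "dataset"), 0)
  expect_error(pctResponsive(array(TRUE, dim = c(0, 0, 0))), "non-empty")
})

test_that("response magnitude averages activated odor-window means", {
  v <- array(0, dim = c(2, 80, 1, 1))
  v[1, 1:20, 1, 1] <- unitSdBaseline(20, sd = 0.5)  # threshold 1.5
  v[2, 1:20, 1, 1] <- unitSdBaseline(20, sd = 0.5)
  v[1, 21:60, 1, 1] <- 2
  v[2, 21:60, 1, 1] <- 0   # not activated
  tens <- makeTensor(v)
  mask <- detectActivated(tens)
  expect_equal(responseMagnitude(tens, mask)$mean, 2)
  v[2, 21:60, 1, 1] <- c(rep(2, 20), rep(4, 20))  # window mean 3
  tens2 <- makeTensor(v)
  res <- responseMagnitude(tens2, detectActivated(tens2))
  expect_equal(res$mean, mean(c(2, 3)))
  # no activated cells -> empty result, not NaN
  quiet <- makeTensor(array(rep(unitSdBaseline(20), 4) / 10,
                            dim = c(1, 80, 1, 1)))
  res0 <- responseMagnitude(quiet, detectActivated(quiet))
  expect_true(is.na(res0$mean))
  expect_equal(nrow(res0$values), 0)
})

test_that("raising the threshold never enlarges the activated set", {
  set.seed(21)
  for (i in 1:20) {
    v <- array(rnorm(2 * 80 * 2 * 2, sd = 1.5), dim = c(2, 80, 2, 2))
    tens <- makeTensor(v)
    m2 <- detectActivated(tens, kSd = 2)
    m3 <- detectActivated(tens, kSd = 3)
    expect_true(all(m2 | !m3))   # m3 subset of m2
  }
})

test_that("detection agrees with a brute-force run scanner", {
  set.seed(22)
  fr <- 20
  for (i in 1:1000) {
    x <- numeric(80)
    x[1:20] <- rnorm(20)
    if (stats::sd(x[1:20]) == 0) next
    x[21:80] <- sample(c(0, 2.5, 4, 6), 60, replace = TRUE)
    tens <- makeTensor(array(x, dim = c(1, 80, 1, 1)))
    got <- detectActivated(tens)[1, 1, 1]
    thr <- 3 * stats::sd(x[1:20] - mean(x[1:20]))
    # oracle works on the same normalized values the detector sees
    want <- oracleHasRun(x[21:60] > thr, 10L)
    expect_identical(got, want)
  }
})

test_that("planted responsive fractions are recovered from synthesis", {
  sim <- cachedFixture("hf100seed1",
    simulateHeadFixed(synthConfig(nCells = 100, seed = 1)))
  tensor <- cachedFixture("hf100seed1tensor",
    buildTensor(sim$traces, sim$events))
  mask <- detectActivated(tensor)
  odorStim <- setdiff(stimuli(tensor), "air")
  rec <- pctResponsive(mask)[odorStim]
  expect_true(all(abs(rec - 15) < 5))
  # ground-truth sensitivity and specificity at amplitude 3 / noise 1
  sens <- fp <- c()
  for (s in odorStim) {
    si <- match(s, stimuli(tensor))
    tuned <- sim$truth@odorTuned[[s]]
    sens <- c(sens, mean(mask[tuned, , si]))
    fp <- c(fp, mean(mask[-tuned, , si]))
  }
  expect_gt(mean(sens), 0.8)
  expect_lt(mean(fp), 0.05)
})

test_that("recovered magnitude matches the direct-integration expectation", {
  sim <- cachedFixture("hf100seed1",
    simulateHeadFixed(synthConfig(nCells = 100, seed = 1)))
  tensor <- cachedFixture("hf100seed1tensor",
    buildTensor(sim$traces, sim$events))
  mask <- detectActivated(tensor)
  # restrict to truly tuned cell-stimulus pairs to measure recovery
  odorStim <- setdiff(stimuli(tensor), "air")
  keep <- array(FALSE, dim = dim(mask))
  for (s in odorStim)
    keep[sim$truth@odorTuned[[s]], , match(s, stimuli(tensor))] <- TRUE
  mag <- responseMagnitude(tensor, mask & keep)$mean
  expect_equal(mag, oracleExpectedMagnitude(), tolerance = 0.3)
})
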