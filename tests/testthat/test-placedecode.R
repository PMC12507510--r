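test_that("position binning follows the half-open convention", {
  expect_equal(binPositions(c(0, 100, 50), 24, 100), c(0L, 23L, 12L))
  w <- 100 / 24
  expect_equal(binPositions(c(w - 1e-9, w, 2 * w - 1e-9), 24, 100),
               c(0L, 1L, 1L))
  expect_error(binPositions(c(3, 101), 24, 100), "frame 2")
  # uniform positions occupy bins uniformly
  set.seed(61)
  occ <- tabulate(binPositions(runif(1e5, 0, 100), 24, 100) + 1L, 24)
  expect_gt(stats::chisq.test(occ)$p.value, 0.001)
})

test_that("running mask applies the strict velocity and end-bin gates", {
  traj <- trackTrajectory(
    positionCm = c(0.5, 5, 10, 50, 50, 95),
    velocityCmS = c(10, 10, 2, 0, 15, 10),
    direction = c("rightward", "rightward", "rightward", "stationary",
                  "rightward", "rightward"),
    traversalIndex = rep(1L, 6))
  expect_equal(runningMask(traj),
               c(FALSE,  # bin 0 (end)
                 FALSE,  # bin 1 (end)
                 FALSE,  # v = 2 exactly: strict inequality
                 FALSE,  # stationary
                 TRUE,   # interior, fast
                 FALSE)) # bin 22 (end)
})

test_that("rate maps localize planted place fields", {
  sim <- quickTrack(nCells = 30, seed = 63, fracPlaceTuned = 1,
                    directionSpecificity = 0, fracOdorTuned = 0,
                    fracPortTuned = 0, noiseSd = 0.3)
  nt <- normalizeTraces(sim$traces)
  mp <- rateMaps(nt, sim$trajectory, "rightward")
  pc <- sim$truth@placeCells
  interior <- pc$center_right_cm > 15 & pc$center_right_cm < 85
  hit <- vapply(which(interior), function(j) {
    row <- mp@rates[, pc$cell[j]]
    peak <- which.max(ifelse(mp@usableBins, row, -Inf)) - 1L
    truthBin <- binPositions(pc$center_right_cm[j], 24, 100)
    abs(peak - truthBin)
  }, numeric(1))
  # calcium decay shifts peaks slightly in the running direction
  expect_lte(median(hit), 3)
  # a constant cell has a flat (zero after z-scoring) rate row
  flat <- cellTraces(matrix(1, 1, length(sim$trajectory@positionCm)))
  mpFlat <- rateMaps(normalizeTraces(flat), sim$trajectory, "rightward")
  expect_true(all(abs(mpFlat@rates[mpFlat@usableBins, 1]) < 1e-9))
})

test_that("frame decoding equals the brute-force correlation scan", {
  set.seed(64)
  for (i in 1:300) {
    nC <- sample(2:5, 1); nB <- sample(3:6, 1)
    rates <- matrix(sample(0:3, nB * nC, replace = TRUE), nB, nC)
    usable <- rep(TRUE, nB)
    template <- methods::new("PopulationRateMap", rates = rates,
                             occupancy = rep(10, nB),
                             direction = "rightward", parity = "all",
                             nBins = nB, trackCm = 100, usableBins = usable)
    fa <- as.numeric(sample(0:3, nC, replace = TRUE))
    expect_identical(decodeFrame(fa, template),
                     oracleDecodeFrame(fa, rates, usable))
  }
})

test_that("tie-breaks pick the lowest bin and degenerate rows lose", {
  rates <- rbind(c(1, 2, 3), c(2, 4, 6), c(5, 5, 5), c(3, 2, 1))
  template <- methods::new("PopulationRateMap", rates = rates,
                           occupancy = rep(1, 4), direction = "rightward",
                           parity = "all", nBins = 4, trackCm = 100,
                           usableBins = rep(TRUE, 4))
  # bins 0 and 1 correlate perfectly with the frame; tie -> bin 0
  expect_identical(decodeFrame(c(10, 20, 30), template), 0L)
  # flat template rows have undefined correlation and never win
  expect_identical(decodeFrame(c(1, 1.1, 0.9),
                               methods::new("PopulationRateMap",
                                            rates = rates[c(3, 4), ],
                                            occupancy = c(1, 1),
                                            direction = "rightward",
                                            parity = "all", nBins = 2,
                                            trackCm = 100,
                                            usableBins = c(TRUE, TRUE))),
                   1L)
  # all-undefined frame is undecodable
  expect_true(is.na(decodeFrame(c(2, 2, 2), template)))
})

test_that("noiseless place codes decode with near-zero error", {
  sim <- quickTrack(nCells = 40, seed = 65, fracPlaceTuned = 1,
                    directionSpecificity = 1, fracOdorTuned = 0,
                    fracPortTuned = 0, noiseSd = 0)
  nt <- normalizeTraces(sim$traces)
  pd <- decodePosition(nt, sim$trajectory, mode = "same_direction")
  expect_lte(pd@mse, 0.5)
  # decoded bins never fall on the excluded end bins
  expect_true(all(!pd@decodedBin %in% c(0, 1, 22, 23)))
  expect_true(all(!pd@trueBin %in% c(0, 1, 22, 23)))
})

test_that("direction-specific codes fail cross-direction decoding", {
  sim <- quickTrack(nCells = 50, seed = 66, fracPlaceTuned = 1,
                    directionSpecificity = 1, fracOdorTuned = 0,
                    fracPortTuned = 0)
  nt <- normalizeTraces(sim$traces)
  same <- decodePosition(nt, sim$trajectory, mode = "same_direction")
  res <- positionShuffleNull(nt, sim$trajectory, mode = "cross_direction",
                             nShuffles = 50, seed = 1)
  expect_gt(res$pValue, 0.05)      # indistinguishable from shuffles
  expect_lt(same@mse, res$observed@mse / 3)
})

test_that("trajectory-phase codes prefer mirrored scoring", {
  sim <- quickTrack(nCells = 50, seed = 67, fracPlaceTuned = 1,
                    directionSpecificity = 0, fracOdorTuned = 0,
                    fracPortTuned = 0)
  nt <- normalizeTraces(sim$traces)
  allo <- decodePosition(nt, sim$trajectory, mode = "cross_direction",
                         scoring = "allocentric")
  mirr <- decodePosition(nt, sim$trajectory, mode = "cross_direction",
                         scoring = "mirrored")
  expect_lt(mirr@mse, allo@mse / 5)
  expect_lte(mirr@medianAbsError, 2)
})

test_that("decoding error does not grow with more place cells", {
  mses <- sapply(1:6, function(seed) {
    sapply(c(0.2, 0.6), function(frac) {
      sim <- quickTrack(nCells = 40, seed = 70 + seed,
                        fracPlaceTuned = frac, fracOdorTuned = 0,
                        fracPortTuned = 0)
      nt <- normalizeTraces(sim$traces)
      decodePosition(nt, sim$trajectory, mode = "same_direction")@mse
    })
  })
  expect_lte(median(mses[2, ]), median(mses[1, ]))
})

test_that("differentiation index separates coding regimes", {
  simSpec <- quickTrack(nCells = 50, seed = 80, fracPlaceTuned = 0.6,
                        directionSpecificity = 1, fracOdorTuned = 0,
                        fracPortTuned = 0)
  simPhase <- quickTrack(nCells = 50, seed = 80, fracPlaceTuned = 0.6,
                         directionSpecificity = 0, fracOdorTuned = 0,
                         fracPortTuned = 0)
  dcSpec <- directionCorrelation(normalizeTraces(simSpec$traces),
                                 simSpec$trajectory)
  dcPhase <- directionCorrelation(normalizeTraces(simPhase$traces),
                                  simPhase$trajectory)
  expect_gt(differentiationIndex(dcSpec), 0.2)
  expect_lt(abs(differentiationIndex(dcPhase)), 0.1)
  expect_gt(differentiationIndex(dcSpec),
            differentiationIndex(dcPhase))
  # correlation matrix geometry
  expect_equal(dim(dcSpec@corr), c(48, 48))
  usable <- !is.na(diag(dcSpec@corr))
  expect_equal(diag(dcSpec@corr)[usable], rep(1, sum(usable)),
               ignore_attr = TRUE)
  expect_equal(dcSpec@corr, t(dcSpec@corr))
})

test_that("an allocentric-invariant code scores index 0 under the allocentric reference", {
  # hand-built traces responding to position identically in both directions
  sim <- quickTrack(nCells = 2, seed = 81)
  traj <- sim$trajectory
  pos <- traj@positionCm
  centers <- seq(10, 90, length.out = 30)
  m <- t(sapply(centers, function(cc) exp(-(pos - cc)^2 / (2 * 64))))
  m <- m + matrix(rnorm(length(m), sd = 0.05), nrow = nrow(m))
  nt <- normalizeTraces(cellTraces(m, design = "freely_moving"))
  dc <- directionCorrelation(nt, traj, phaseReference = "allocentric")
  expect_lt(abs(differentiationIndex(dc)), 0.1)
  # under the mirrored (trajectory-phase) reference the same code looks
  # direction-differentiated
  dcM <- directionCorrelation(nt, traj, phaseReference = "mirrored")
  expect_gt(differentiationIndex(dcM), differentiationIndex(dc))
})

test_that("degenerate correlation structure refuses the index", {
  sim <- quickTrack(nCells = 2, seed = 82)
  traj <- sim$trajectory
  # anti-correlated odd/even halves force cSame + cDiff <= 0
  parR <- odorplace:::.traversalParity(traj, "rightward")
  parL <- odorplace:::.traversalParity(traj, "leftward")
  sgn <- ifelse(traj@traversalIndex %in% c(parR$odd, parL$odd), 1, -1)
  pos <- traj@positionCm
  m <- rbind(sgn * pos, sgn * (100 - pos), sgn * sin(pos / 7),
             sgn * cos(pos / 9))
  nt <- normalizeTraces(cellTraces(m, design = "freely_moving"))
  expect_warning(dc <- directionCorrelation(nt, traj), "undefined")
  expect_true(is.na(differentiationIndex(dc)))
})
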