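test_that("trial vectors are one per trial with metadata preserved", {
  v <- array(rnorm(5 * 80 * 12 * 3), dim = c(5, 80, 12, 3))
  tens <- makeTensor(v, stimuli = c("odorA", "odorB", "odorC"))
  vset <- trialVectors(tens)
  expect_equal(dim(vset@vectors), c(36, 5))
  expect_equal(trialMeta(vset)$stimulus, rep(c("odorA", "odorB", "odorC"),
                                             each = 12))
  # the vector entries are odor-window means
  w <- which(tens@timeAxis >= 0 & tens@timeAxis < 2)
  expect_equal(unname(vset@vectors[1, 3]), mean(v[3, w, 1, 1]))
  # constant tensor -> identical vectors
  cset <- trialVectors(makeTensor(array(rep(1:5, 80 * 4),
                                        dim = c(5, 80, 2, 2))))
  expect_true(all(apply(cset@vectors, 2, function(x) length(unique(x))) == 1))
  expect_error(trialVectors(tens, windowS = 50), "windowS")
})

test_that("extended odor-exposure windows are supported", {
  hf <- quickHeadFixed(nCells = 6, seed = 5)
  tensor <- buildTensor(hf$traces, hf$events)
  v2 <- trialVectors(tensor, windowS = 2)
  v5 <- trialVectors(tensor, windowS = 5)
  expect_false(isTRUE(all.equal(v2@vectors, v5@vectors)))
  expect_equal(v5@windowS, 5)
})

test_that("correlation matrix is exact Pearson across cells", {
  vecs <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(-1, -2, -3, -4),
                c(4, 1, 3, 2))
  vset <- methods::new("TrialVectorSet", vectors = vecs,
                       trialMeta = data.frame(stimulus = letters[1:4],
                                              trial = 1:4, port = "none",
                                              onset_frame = NA),
                       windowS = 2)
  sim <- correlationMatrix(vset)
  m <- similarityValues(sim)
  expect_equal(diag(m), rep(1, 4))
  expect_equal(m[1, 2], 1)        # positive scaling
  expect_equal(m[1, 3], -1)       # negation
  # hand-computed Pearson for an arbitrary pair
  hand <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  expect_equal(m[1, 4], hand(vecs[1, ], vecs[4, ]), tolerance = 1e-12)
  expect_equal(m, t(m))
})

test_that("zero-variance trial vectors become NA and are excluded", {
  vecs <- rbind(c(1, 2, 3), c(2, 2, 2), c(3, 1, 2), c(1, 3, 2),
                c(2, 1, 3), c(3, 2, 1))
  vset <- methods::new("TrialVectorSet", vectors = vecs,
                       trialMeta = data.frame(
                         stimulus = c("a", "a", "a", "b", "b", "b"),
                         trial = 1:6, port = "none", onset_frame = NA),
                       windowS = 2)
  expect_message(sim <- correlationMatrix(vset), "zero-variance")
  m <- similarityValues(sim)
  expect_true(all(is.na(m[2, ])) && all(is.na(m[, 2])))
  sv <- sameVsDifferent(sim, by = "odor")
  expect_false(is.na(sv$same) || is.na(sv$different))
})

test_that("same/different contrasts recover a block-diagonal structure", {
  n <- 12
  labs <- rep(c("a", "b", "c"), each = 4)
  m <- matrix(0.1, n, n)
  for (s in unique(labs)) m[labs == s, labs == s] <- 0.8
  diag(m) <- 1
  sim <- methods::new("SimilarityMatrix", values = m,
                      trialMeta = data.frame(stimulus = labs, trial = 1:n,
                                             port = "none",
                                             onset_frame = NA),
                      ordering = "stimulus")
  sv <- sameVsDifferent(sim, by = "odor")
  expect_equal(sv$same, 0.8)
  expect_equal(sv$different, 0.1)
  expect_equal(sv$nSame, 3 * choose(4, 2))
  expect_equal(sv$nDifferent, choose(12, 2) - 3 * choose(4, 2))
})

test_that("label-shuffled data show no same/different contrast", {
  set.seed(31)
  vecs <- matrix(rnorm(12 * 30), nrow = 12)
  labs <- rep(c("a", "b", "c"), each = 4)
  vset <- methods::new("TrialVectorSet", vectors = vecs,
                       trialMeta = data.frame(stimulus = labs, trial = 1:12,
                                              port = "none",
                                              onset_frame = NA),
                       windowS = 2)
  sim <- correlationMatrix(vset)
  obs <- sameVsDifferent(sim, by = "odor")$difference
  null <- replicate(1000, {
    meta <- sim@trialMeta
    meta$stimulus <- sample(meta$stimulus)
    simP <- methods::new("SimilarityMatrix", values = sim@values,
                         trialMeta = meta, ordering = "stimulus")
    sameVsDifferent(simP, by = "odor")$difference
  })
  expect_gt(mean(abs(null) >= abs(obs)), 0.05)
})

test_that("port contrast uses within-stimulus pairs and finds port codes", {
  sim <- quickTrack(nCells = 60, seed = 33, fracOdorTuned = 0,
                    fracPortTuned = 0.4, fracPlaceTuned = 0)
  tensor <- buildTensor(sim$traces, sim$events)
  smat <- correlationMatrix(trialVectors(tensor))
  odorStim <- setdiff(stimuli(tensor), "air")
  port <- sameVsDifferent(smat, by = "port", restrict = odorStim)
  odor <- sameVsDifferent(smat, by = "odor", restrict = odorStim)
  expect_gt(port$difference, 0.1)
  expect_lt(abs(odor$difference), 0.05)
  # air control shows the same port structure
  air <- sameVsDifferent(smat, by = "port", restrict = "air")
  expect_gt(air$difference, 0.1)
  # within-stimulus pair counts: per stimulus, 12 trials = 6+6 by port
  expect_equal(port$nSame, 3 * 2 * choose(6, 2))
  expect_equal(port$nDifferent, 3 * 36)
})

test_that("similarity is invariant to positive affine rescaling", {
  set.seed(35)
  vecs <- matrix(rnorm(8 * 20), nrow = 8)
  meta <- data.frame(stimulus = rep(c("a", "b"), each = 4), trial = 1:8,
                     port = "none", onset_frame = NA)
  vset <- methods::new("TrialVectorSet", vectors = vecs, trialMeta = meta,
                       windowS = 2)
  vset2 <- methods::new("TrialVectorSet", vectors = vecs * 3.7 + 1.2,
                        trialMeta = meta, windowS = 2)
  expect_equal(similarityValues(correlationMatrix(vset)),
               similarityValues(correlationMatrix(vset2)),
               tolerance = 1e-12)
})

test_that("pooling sessions concatenates cells with aligned trials", {
  a <- quickHeadFixed(nCells = 4, seed = 36)
  b <- quickHeadFixed(nCells = 5, seed = 37)
  va <- trialVectors(buildTensor(a$traces, a$events))
  vb <- trialVectors(buildTensor(b$traces, b$events))
  # stimulus sets match but session schedules differ; align by trial index
  vb@trialMeta <- vb@trialMeta[match(
    paste(va@trialMeta$stimulus, va@trialMeta$trial),
    paste(vb@trialMeta$stimulus, vb@trialMeta$trial)), ]
  vb@vectors <- vb@vectors[match(
    paste(va@trialMeta$stimulus, va@trialMeta$trial),
    paste(vb@trialMeta$stimulus, vb@trialMeta$trial)), , drop = FALSE]
  pooled <- poolTrialVectors(list(va, vb))
  expect_equal(ncol(pooled@vectors), 9)
  expect_equal(nrow(pooled@vectors), 24)
})

test_that("type-I error of the permutation contrast check is controlled", {
  set.seed(38)
  alpha <- replicate(1000, {
    vals <- matrix(rnorm(12 * 6), nrow = 12)   # null: no label structure
    labs <- rep(c("a", "b", "c"), each = 4)
    m <- suppressWarnings(stats::cor(t(vals)))
    diag(m) <- 1
    simN <- methods::new("SimilarityMatrix", values = m,
                         trialMeta = data.frame(stimulus = labs,
                                                trial = 1:12, port = "none",
                                                onset_frame = NA),
                         ordering = "stimulus")
    obs <- sameVsDifferent(simN, by = "odor")$difference
    null <- replicate(99, {
      meta <- simN@trialMeta
      meta$stimulus <- sample(meta$stimulus)
      sameVsDifferent(methods::new("SimilarityMatrix", values = m,
                                   trialMeta = meta,
                                   ordering = "stimulus"),
                      by = "odor")$difference
    })
    (sum(abs(null) >= abs(obs)) + 1) / 100 < 0.05
  })
  expect_lte(mean(alpha), 0.07)
})

test_that("rank-sum group comparison matches the enumeration convention", {
  res <- groupCompare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res@statistic, 0)
  expect_equal(pValue(res), 0.1)
  expect_equal(pValue(groupCompare(c(5, 5), c(5, 5))), 1)
})
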