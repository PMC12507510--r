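# Independent oracles used to verify package computations. These stay
# deliberately naive and separate from the implementation paths they check.

# ---- exact big-integer arithmetic (base-1e7 limb vectors, little-endian) --

bigCarry <- function(x) {
  repeat {
    carry <- floor(x / 1e7)
    x <- x - carry * 1e7
    if (all(carry == 0)) break
    x <- c(x, 0)[seq_len(max(length(x), length(carry) + 1))]
    x[seq_along(carry) + 1L] <- x[seq_along(carry) + 1L] + carry
  }
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

bigAdd <- function(a, b) {
  n <- max(length(a), length(b))
  bigCarry(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

bigMul <- function(a, b) {
  L <- length(a) + length(b) + 2L
  res <- rep(0, L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    seg <- a[i] * b                       # <= 1e14, exact in double
    lo <- seg %% 1e7
    hi <- (seg - lo) / 1e7
    idx <- (i - 1L) + seq_along(b)
    res[idx] <- res[idx] + lo
    res[idx + 1L] <- res[idx + 1L] + hi
    res <- bigCarry(res)
    res <- c(res, rep(0, L - length(res)))  # keep room for later limbs
  }
  bigCarry(res)
}

bigToDouble <- function(a) sum(a * 1e7^(seq_along(a) - 1))

# Exact rational upper-tail binomial probabilities for p = num/den:
# P(X >= k) = sum_j C(n,j) num^j (den-num)^(n-j) / den^n, all k = 0..n.
oracleBinomUpperTail <- function(n, num = 1, den = 3) {
  pow <- function(base, m) {
    out <- 1
    for (i in seq_len(m)) out <- bigCarry(out * base)
    out
  }
  row <- list(1)                           # Pascal row for current n
  for (m in seq_len(n)) {
    nxt <- vector("list", m + 1)
    nxt[[1]] <- 1; nxt[[m + 1]] <- 1
    if (m > 1) for (j in 2:m) nxt[[j]] <- bigAdd(row[[j - 1]], row[[j]])
    row <- nxt
  }
  terms <- lapply(0:n, function(j)
    bigMul(bigMul(row[[j + 1]], pow(num, j)), pow(den - num, n - j)))
  denBig <- pow(den, n)
  suffix <- vector("list", n + 1)
  suffix[[n + 1]] <- terms[[n + 1]]
  if (n >= 1) for (j in n:1) suffix[[j]] <- bigAdd(suffix[[j + 1]], terms[[j]])
  vapply(suffix, bigToDouble, numeric(1)) / bigToDouble(denBig)
}

# ---- brute-force run-length activation scanner ---------------------------

oracleHasRun <- function(x, minLen) {
  n <- length(x)
  if (minLen > n) return(FALSE)
  for (s in seq_len(n - minLen + 1L))
    if (all(x[s:(s + minLen - 1L)])) return(TRUE)
  FALSE
}

# ---- brute-force maximum-correlation frame decoder -----------------------

oracleDecodeFrame <- function(frameActivity, rates, usable) {
  best <- -Inf; bestBin <- NA_integer_
  for (b in which(usable)) {
    r <- suppressWarnings(stats::cor(frameActivity, rates[b, ]))
    if (is.na(r)) next
    if (r > best + 1e-12) { best <- r; bestBin <- b - 1L }
  }
  bestBin
}

# ---- tiny constructed trial tensors --------------------------------------

# Build a normalized TrialTensor directly from a values array (cells x time
# x trials x stimuli); time axis has `preS` seconds before onset.
makeTensor <- function(values, preS = 1, odorS = 2, frameRate = 20,
                       stimuli = NULL, ports = NULL) {
  d <- dim(values)
  if (is.null(stimuli)) stimuli <- sprintf("stim%d", seq_len(d[4]))
  postS <- d[2] / frameRate - preS - odorS
  meta <- do.call(rbind, lapply(seq_len(d[4]), function(s) data.frame(
    stimulus = stimuli[s], trial = seq_len(d[3]),
    port = if (is.null(ports)) "none" else ports[[s]],
    onset_frame = NA_integer_)))
  methods::new("TrialTensor", values = values,
               timeAxis = (seq_len(d[2]) - 1 - preS * frameRate) / frameRate,
               windowSpec = c(pre_s = preS, odor_s = odorS, post_s = postS),
               frameRate = frameRate, stimuli = stimuli,
               cellIds = sprintf("cell_%03d", seq_len(d[1])),
               trialMeta = meta, normalized = TRUE,
               excludedCells = character(0))
}

# A deterministic baseline block with exactly zero mean and unit sd over
# `n` frames (alternating +1/-1 pattern scaled), handy for threshold tests.
unitSdBaseline <- function(n, sd = 1) {
  x <- rep(c(1, -1), length.out = n)
  sd * x / stats::sd(x)
}

# Direct-integration expectation of the recovered response magnitude for a
# head-fixed synthetic session: the injected template attenuated by the
# pooled-sd normalization (response variance inflates the z denominator).
oracleExpectedMagnitude <- function(amplitude = 3, noiseSd = 1,
                                    decayS = 1.5, fr = 20,
                                    trialsPerStim = 6, nStim = 4) {
  odorF <- 2 * fr
  trialF <- 30 * fr
  postOnset <- trialF - 10 * fr                  # frames from onset to end
  a <- exp(-1 / (decayS * fr))
  kern <- stats::filter(c(rep(1, odorF), rep(0, postOnset - odorF)), a,
                        method = "recursive")
  templ <- as.numeric(kern) / mean(kern[seq_len(odorF)])  # unit window mean
  templSm <- as.numeric(stats::filter(templ, rep(1 / 5, 5), sides = 2))
  templSm[is.na(templSm)] <- templ[is.na(templSm)]
  sigSm <- noiseSd / sqrt(5)                     # smoothed-noise sd
  r <- amplitude * sigSm * templSm               # raw smoothed response
  totFrames <- nStim * trialsPerStim * trialF
  pooledVar <- sigSm^2 + trialsPerStim * sum(r^2) / totFrames
  amplitude * sigSm / sqrt(pooledVar)
}
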