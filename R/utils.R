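# Internal helpers shared across modules.

# Centered moving average with shrunken windows at the edges, so the output
# has no phase lag and no NA padding.
.movingAverage <- function(x, w) {
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# TRUE iff `x` (logical) contains a run of TRUE of length >= minLen.
.hasRun <- function(x, minLen) {
  if (!any(x)) return(FALSE)
  r <- rle(x)
  any(r$lengths[r$values] >= minLen)
}

# Lengths of all TRUE runs in a logical vector.
.trueRunLengths <- function(x) {
  r <- rle(x)
  r$lengths[r$values]
}

# Balanced pseudorandom stimulus schedule: `blocks` shuffled copies of
# `labels`, concatenated (every label appears once per block).
.balancedSchedule <- function(labels, blocks) {
  unlist(lapply(seq_len(blocks), function(i) sample(labels)))
}

# log(sum(exp(x))) without overflow.
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pearson correlation that returns NA (no warning) on zero variance.
.safeCor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Row-standardize a matrix for fast pairwise Pearson correlation between
# rows of two matrices; zero-variance rows become NA rows.
.rowStandardize <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  ss <- sqrt(rowSums(ctr^2))
  ss[ss == 0] <- NA_real_
  ctr / ss
}

# Pairwise Pearson r between rows of a and rows of b (same #columns).
.rowCor <- function(a, b) {
  tcrossprod(.rowStandardize(a), .rowStandardize(b))
}

.stopIfNot <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}
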