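#' Upper-tail binomial probability
#'
#' Probability of observing `k` or more successes in `n` Bernoulli trials
#' with success probability `p`:
#' `P(X >= k) = sum_{j=k}^{n} C(n, j) p^j (1 - p)^(n - j)`.
#' The sum is accumulated in log space for numerical stability, so extreme
#' tails (e.g. `(1/3)^36`) are exact to machine precision. This is the
#' significance test applied to each time point of a decoding-accuracy
#' series, with `n` the number of decoded trials and `p` the chance level.
#'
#' @param k number of successes, `0 <= k <= n` (vectorized).
#' @param n number of trials.
#' @param p chance probability, in (0, 1).
#' @return upper-tail probability in (0, 1]; monotone non-increasing in `k`.
#' @examples
#' binomialUpperTail(20, 36, 1/3)
#' @export
binomialUpperTail <- function(k, n, p = 1 / 3) {
  .stopIfNot(length(n) == 1L && length(p) == 1L && n == round(n) && n >= 0,
             "'n' must be a single non-negative integer")
  .stopIfNot(p > 0 && p < 1, "'p' must lie strictly between 0 and 1")
  .stopIfNot(all(k == round(k)) && all(k >= 0) && all(k <= n),
             "'k' must satisfy 0 <= k <= n")
  vapply(k, function(ki) {
    j <- ki:n
    lt <- lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
    min(exp(.logSumExp(lt)), 1)
  }, numeric(1))
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum (Mann-Whitney U) test with exact small-sample
#' behaviour: for combined sample sizes up to `exactMax` (default 12, the
#' per-mouse group sizes of a typical cohort comparison) the null
#' distribution of U is enumerated over all assignments of the observed
#' values to groups, which remains valid under ties; larger samples use the
#' normal approximation with tie correction and continuity correction.
#' Two-sided exact p-values are `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b numeric vectors (non-empty).
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @param exactMax maximum combined n for exact enumeration.
#' @return a [TestResult-class]; the statistic is U for group `a`.
#' @export
rankSum <- function(a, b, alternative = c("two.sided", "greater", "less"),
                    exactMax = 12) {
  alternative <- match.arg(alternative)
  .stopIfNot(length(a) >= 1 && length(b) >= 1,
             "both groups must be non-empty")
  m <- length(a); n <- length(b); N <- m + n
  ranks <- rank(c(a, b))
  u <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  tails <- if (alternative == "two.sided") "two" else "one"
  if (N <= exactMax) {
    sets <- utils::combn(N, m)
    us <- apply(sets, 2L, function(ix) sum(ranks[ix]) - m * (m + 1) / 2)
    pGe <- mean(us >= u - 1e-9)
    pLe <- mean(us <= u + 1e-9)
    pval <- switch(alternative,
                   two.sided = min(1, 2 * min(pGe, pLe)),
                   greater = pGe, less = pLe)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    mu <- m * n / 2
    tie <- table(ranks)
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    z <- switch(alternative,
                two.sided = (abs(u - mu) - 0.5) / sigma,
                greater = (u - mu - 0.5) / sigma,
                less = -(u - mu + 0.5) / sigma)
    pval <- if (alternative == "two.sided") 2 * stats::pnorm(-z)
            else stats::pnorm(-z)
    pval <- min(max(pval, .Machine$double.xmin), 1)
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  methods::new("TestResult", statistic = u, pValue = pval, method = method,
               tails = tails, nPerGroup = c(m, n))
}

#' One-tailed two-sample t test
#'
#' Welch (unequal-variance) two-sample location test with a directional
#' alternative, as used for contrasting differentiation indices between
#' regions.
#'
#' @param a,b numeric vectors with at least two values each.
#' @param direction `"greater"` (mean of `a` exceeds mean of `b`) or
#'   `"less"`.
#' @return a [TestResult-class].
#' @export
oneTailedT <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  .stopIfNot(length(a) >= 2 && length(b) >= 2,
             "need >= 2 values per group")
  .stopIfNot(stats::sd(a) > 0 || stats::sd(b) > 0,
             "degenerate variance in both groups")
  ht <- stats::t.test(a, b, alternative = direction, var.equal = FALSE)
  methods::new("TestResult", statistic = unname(ht$statistic),
               pValue = max(ht$p.value, .Machine$double.xmin),
               method = "Welch two-sample t test", tails = "one",
               nPerGroup = c(length(a), length(b)))
}
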