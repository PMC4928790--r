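#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Computes the Mann-Whitney U statistic (for the first sample) using
#' midranks for ties. When the pooled sample size is at most `exact_max`
#' the two-sided p-value is exact: the permutation distribution of U is
#' enumerated over all choose(n1+n2, n1) group labelings of the pooled
#' midranks, and the p-value is the probability of a U at least as far
#' from its null mean n1*n2/2 as observed. For larger samples a normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used. Ordinal clinical scores (and binary items) produce heavy ties,
#' which both paths handle.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Largest pooled size for which the exact enumeration is
#'   used (default 12).
#' @return List with `statistic` (U for `x`), `p_value` (two-sided) and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mw_utest(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mw_utest <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.")
  }
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n <= exact_max) {
    picks <- combn(n, n1)
    u_all <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    return(list(statistic = u, p_value = p, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = u, p_value = 1, method = "normal"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = u, p_value = p, method = "normal")
}

#' Holm-Bonferroni adjustment
#'
#' Step-down Holm adjustment controlling the family-wise error rate;
#' adjusted values are clipped at 1, monotone, and returned in the input
#' order. A thin, argument-checked wrapper around
#' [stats::p.adjust()]`(method = "holm")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("p-value(s) outside [0, 1]: %s.",
                  paste(unique(p[bad]), collapse = ", ")))
  }
  p.adjust(p, method = "holm")
}

#' Performance of a binary predictor on a 2x2 table
#'
#' For counts `a` (predictor present, outcome positive), `b` (present,
#' negative), `c` (absent, positive), `d` (absent, negative): sensitivity
#' a/(a+c), specificity d/(b+d), and Yule's Q = (ad - bc)/(ad + bc), a
#' symmetric association measure in \[-1, 1\]. Zero denominators yield NA
#' with `undefined = TRUE`.
#'
#' @param a,b,c,d Non-negative integer cell counts (at least one positive).
#' @return Tibble with columns `sensitivity`, `specificity`, `yules_q`,
#'   `undefined`.
#' @examples
#' binary_predictor_metrics(10, 2, 3, 9) # Q = 0.875
#' @export
binary_predictor_metrics <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("Cell counts must be non-negative integers.")
  }
  if (sum(cells) < 1) abort("All cells are zero.")
  sens <- if (a + c > 0) a / (a + c) else NA_real_
  spec <- if (b + d > 0) d / (b + d) else NA_real_
  q <- if (a * d + b * c > 0) (a * d - b * c) / (a * d + b * c) else NA_real_
  tibble(
    sensitivity = sens, specificity = spec, yules_q = q,
    undefined = is.na(sens) || is.na(spec) || is.na(q)
  )
}

#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov distance between the sample's empirical distribution
#' and a normal with the sample's own mean and standard deviation; the
#' p-value is obtained from a seeded Monte-Carlo null (standard normal
#' samples of the same size, each reduced to its own Lilliefors distance).
#'
#' @param x Numeric sample, length at least 4.
#' @param nsim Number of Monte-Carlo null replicates (default 10000).
#' @param seed Integer seed for the null simulation; `NULL` uses the
#'   current RNG stream.
#' @return List with `statistic` and `p_value`.
#' @export
lilliefors_test <- function(x, nsim = 10000, seed = NULL) {
  if (length(x) < 4) abort("Lilliefors test needs at least 4 observations.")
  if (anyNA(x)) abort("Sample must not contain NA.")
  d_obs <- lillie_stat(x)
  sims <- with_seed(seed, {
    n <- length(x)
    vapply(seq_len(nsim), function(i) lillie_stat(rnorm(n)), numeric(1))
  })
  list(statistic = d_obs, p_value = (1 + sum(sims >= d_obs)) / (nsim + 1))
}

lillie_stat <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (s == 0) return(1) # degenerate sample: maximal distance
  z <- sort((x - mean(x)) / s)
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream;
# seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
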