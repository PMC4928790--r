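# Independent brute-force oracle: U by pair counting (not rank sums), and
# the two-sided p by enumerating every group labeling of the pooled values.
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- oracle_u(x, y)
  picks <- utils::combn(length(pooled), n1)
  u_all <- apply(picks, 2, function(ii) oracle_u(pooled[ii], pooled[-ii]))
  list(statistic = u_obs,
       p_value = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

test_that("Mann-Whitney exact enumeration matches its closed cases", {
  r <- mw_utest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  same <- mw_utest(c(2, 5, 5, 9), c(2, 5, 5, 9))
  expect_equal(same$p_value, 1)
  tied <- mw_utest(rep(3, 4), rep(3, 5))
  expect_equal(tied$statistic, 4 * 5 / 2)
  expect_equal(tied$p_value, 1)
  expect_error(mw_utest(numeric(), 1), "non-empty")
})

test_that("exact Mann-Whitney agrees with the brute-force oracle on small samples", {
  set.seed(41)
  for (rep in 1:120) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:(8 - n1), 1)
    vals <- sample(0:4, n1 + n2, replace = TRUE) # heavy ties, ordinal-like
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    got <- mw_utest(x, y)
    want <- oracle_mw(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value)
  }
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal test", {
  set.seed(42)
  for (rep in 1:20) {
    x <- sample(0:6, 15, replace = TRUE)
    y <- sample(0:6, 12, replace = TRUE)
    got <- mw_utest(x, y)
    expect_equal(got$method, "normal")
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    )
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Holm adjustment reproduces hand-computed step-down values", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.5), 0.5)
  expect_equal(holm_adjust(c(0, 0, 0)), c(0, 0, 0))
  p <- c(0.3, 0.01, 0.04, 0.9)
  perm <- c(3, 1, 4, 2)
  expect_equal(holm_adjust(p)[perm], holm_adjust(p[perm]))
  expect_equal(holm_adjust(rep(0.02, 4)), rep(0.08, 4)) # equals Bonferroni
  expect_error(holm_adjust(c(0.2, 1.4)), "outside")
})

test_that("binary predictor metrics follow the closed forms", {
  m <- binary_predictor_metrics(10, 2, 3, 9)
  expect_equal(m$yules_q, 0.875)
  expect_equal(m$sensitivity, 10 / 13)
  expect_equal(m$specificity, 9 / 11)
  expect_equal(binary_predictor_metrics(4, 3, 3, 4)$yules_q, 7 / 25)
  expect_equal(binary_predictor_metrics(5, 5, 5, 5)$yules_q, 0)
  expect_equal(binary_predictor_metrics(6, 0, 2, 4)$yules_q, 1)
  und <- binary_predictor_metrics(0, 2, 0, 3)
  expect_true(und$undefined)
  expect_true(is.na(und$sensitivity))
  expect_error(binary_predictor_metrics(0, 0, 0, 0), "zero")
  expect_error(binary_predictor_metrics(-1, 1, 1, 1), "non-negative")
  set.seed(43)
  for (rep in 1:50) {
    cells <- sample(0:8, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    q <- binary_predictor_metrics(cells[1], cells[2], cells[3], cells[4])$yules_q
    det <- cells[1] * cells[4] - cells[2] * cells[3]
    if (!is.na(q)) {
      expect_true(q >= -1 && q <= 1)
      expect_equal(sign(q), sign(det))
    }
  }
})

test_that("Lilliefors statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(44)
  for (rep in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- lilliefors_test(x, nsim = 50, seed = 1)
    expect_equal(got$statistic, unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("Lilliefors Monte-Carlo p-value is calibrated and seeded", {
  near_normal <- qnorm(((1:20) - 0.5) / 20)
  r <- lilliefors_test(near_normal, nsim = 500, seed = 7)
  expect_true(r$statistic >= 0)
  expect_gt(r$p_value, 0.5)
  bimodal <- rep(c(-1, 1), 20)
  expect_lt(lilliefors_test(bimodal, nsim = 500, seed = 7)$p_value, 0.01)
  a <- lilliefors_test(near_normal, nsim = 200, seed = 9)
  b <- lilliefors_test(near_normal, nsim = 200, seed = 9)
  expect_identical(a, b)
  expect_error(lilliefors_test(c(1, 2, 3)), "at least 4")
})

test_that("MBT prediction handles constant items and tiny groups", {
  gg <- two_group_first_scores(2, 2, items1 = c(1, 6), items2 = c(1, 6))
  pred <- mbt_prediction(gg$first, gg$comparisons[1, ])
  expect_true(all(pred$p_raw == 1)) # items constant in both groups
  expect_true(all(is.na(pred$sensitivity)))
  gg2 <- two_group_first_scores(2, 2, items1 = 1:5, items2 = integer())
  pred2 <- mbt_prediction(gg2$first, gg2$comparisons[1, ], alpha = 0.5)
  # 2+2 patients: the exact enumeration path applies
  expect_equal(min(pred2$p_raw), 1 / 3) # separation: 2/choose(4,2)
})

test_that("descriptives are NA-safe for empty groups", {
  co <- doc_cohort()
  one_class <- co[classify_outcome(co)$primary_class == "emerged", ]
  d <- doc_descriptives(one_class)
  expect_equal(d$n$remaining, 0)
  expect_true(all(is.na(d$continuous$p_raw)) || nrow(d$continuous) == 0)
})

test_that("assessment-count correlation helper is configurable", {
  co <- doc_cohort()
  r1 <- crsr_count_correlation(co)
  r2 <- crsr_count_correlation(co, duration = "delay_last_crsr",
                               method = "spearman")
  expect_true(abs(r1$estimate) <= 1 && abs(r2$estimate) <= 1)
  expect_error(crsr_count_correlation(co, duration = "nope"), "nope")
})
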