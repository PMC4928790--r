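test_that("polynomial basis is orthonormal on its reference grid", {
  for (window in list(c(0, 100), c(0, 60), c(10, 45))) {
    b <- poly_basis(window = window)
    expect_lte(b$ortho_error, 1e-8)
    g <- eval_basis(b, b$grid)
    expect_equal(max(abs(crossprod(g) - diag(4))), b$ortho_error)
    # column 0 is constant
    expect_equal(diff(range(g[, 1])), 0)
  }
  b0 <- poly_basis(degree = 0)
  expect_equal(ncol(eval_basis(b0, 0:10)), 1)
  expect_error(poly_basis(window = c(5, 5)), "window")
  expect_error(poly_basis(degree = 3, grid_n = 3), "grid_n")
  expect_error(eval_basis(poly_basis(), 0:5, degrees = 4), "degree")
})

test_that("trajectory fits represent polynomial data exactly", {
  b <- poly_basis(window = c(0, 60))
  # constant scores: zero residual, higher-degree coefficients vanish
  const <- traj_assessments("p1", c(3, 10, 24, 38, 52), function(d) rep(2, 5))
  f <- fit_trajectories(const, b)
  expect_true(all(f$rss < 1e-16))
  higher <- vapply(f$coefs, function(cf) max(abs(cf[c("d1", "d2", "d3")])),
                   numeric(1))
  expect_true(all(higher < 1e-8))
  # exact line under the baseline+slope subset
  lin <- traj_assessments("p1", seq(0, 60, by = 10), function(d) d / 20)
  fl <- fit_trajectories(lin, b, degrees = 0:1)
  expect_true(all(fl$rss[fl$subscale == "motor"] < 1e-16))
})

test_that("nested subsets never increase the residual", {
  b <- poly_basis(window = c(0, 60))
  set.seed(51)
  noisy <- traj_assessments("p1", seq(2, 58, by = 8), function(d) {
    round(pmin(6, pmax(0, 6 * plogis((d - 25) / 6) + rnorm(length(d), 0, 0.4))))
  })
  rss_full <- fit_trajectories(noisy, b, degrees = 0:3)$rss
  rss_line <- fit_trajectories(noisy, b, degrees = 0:1)$rss
  expect_true(all(rss_full <= rss_line + 1e-10))
})

test_that("fits project exactly onto spanned trajectories", {
  b <- poly_basis(window = c(0, 60))
  days <- seq(0, 60, by = 6)
  x <- eval_basis(b, days, degrees = c(0, 2))
  beta <- c(4, 0.8)
  y <- pmax(0, pmin(4, drop(x %*% beta)))
  stopifnot(all(y == drop(x %*% beta))) # stays inside the score range
  aa <- tibble::tibble(patient = "p1", day = days, auditory = y, visual = y,
                       motor = y, oromotor = pmin(y, 3),
                       communication = pmin(y, 2))
  f <- fit_trajectories(aa, b, degrees = c(0, 2))
  expect_lt(f$rss[f$subscale == "auditory"], 1e-16)
  full <- fit_trajectories(aa, b, degrees = 0:3)
  cf <- full$coefs[full$subscale == "auditory"][[1]]
  expect_lt(max(abs(cf[c("d1", "d3")])), 1e-8)
  expect_equal(unname(cf[c("d0", "d2")]), beta, tolerance = 1e-8)
})

test_that("rank deficiency is flagged and capped fits stay parsimonious", {
  b <- poly_basis(window = c(0, 60))
  three <- traj_assessments("p1", c(5, 12, 20), function(d) d / 10)
  f <- fit_trajectories(three, b, degrees = 0:3)
  expect_true(all(f$rank_deficient))
  expect_equal(length(f$coefs[[1]]), 4)
  fc <- fit_trajectories(three, b, degrees = 0:3, cap_by_n = TRUE)
  expect_false(any(fc$rank_deficient))
  expect_equal(names(fc$coefs[[1]]), c("d0", "d1"))
  expect_error(fit_trajectories(three[c(1, 1), ], b), "Duplicate")
})

test_that("tidy and glance summarise fit objects", {
  b <- poly_basis(window = c(0, 60))
  aa <- dplyr::bind_rows(
    traj_assessments("p1", c(2, 9, 16, 30), function(d) d / 10),
    traj_assessments("p2", c(4, 12, 25, 40), function(d) d / 15)
  )
  f <- fit_trajectories(aa, b, degrees = 0:1)
  td <- tidy(f)
  expect_equal(nrow(td), 2 * 5 * 2)
  expect_equal(sort(unique(td$degree)), 0:1)
  gl <- glance(f)
  expect_equal(gl$n_patients, 2)
  expect_equal(gl$n_regressors, 2)
})

test_that("group curves average patients and report SEM bands", {
  b <- poly_basis(window = c(0, 60))
  aa <- dplyr::bind_rows(
    traj_assessments("p1", c(2, 9, 16, 30, 44), function(d) d / 10),
    traj_assessments("p2", c(2, 9, 16, 30, 44), function(d) d / 10),
    traj_assessments("p3", c(3, 11, 20, 33, 46), function(d) 6 - d / 10)
  )
  f <- fit_trajectories(aa, b, degrees = 0:1)
  cv <- group_curves(f, list(up = c("p1", "p2"), down = "p3"),
                     curve_window = c(0, 45))
  expect_s3_class(cv, "doc_curves")
  # single-patient group: zero-width band
  expect_true(all(cv$sem[cv$group == "down"] == 0))
  # identical patients: mean equals either one, zero SEM
  up_motor <- cv[cv$group == "up" & cv$subscale == "motor", ]
  expect_true(all(up_motor$sem < 1e-10))
  single <- group_curves(f, list(up = c("p1", "p2")), curve_window = c(0, 45))
  expect_equal(single$mean[single$subscale == "motor"], up_motor$mean)
})

test_that("discrimination time applies the persistence rule", {
  grid <- 0:50
  mk <- function(m1, m2, s1 = 0.2, s2 = 0.2) {
    structure(
      dplyr::bind_rows(
        tibble::tibble(group = "A", subscale = "motor", day = grid, mean = m1,
                       sem = s1, n = 5L),
        tibble::tibble(group = "B", subscale = "motor", day = grid, mean = m2,
                       sem = s2, n = 5L)
      ),
      class = c("doc_curves", class(tibble::tibble())), grid_step = 1
    )
  }
  # identical curves never separate
  expect_true(is.na(discrimination_time(mk(grid / 10, grid / 10))$day))
  # fully separated bands: first grid day
  expect_equal(discrimination_time(mk(grid / 10 + 3, grid / 10))$day, 0)
  # transient separation resets the clock
  gap <- ifelse(grid %in% 10:15 | grid >= 30, 2, 0)
  expect_equal(discrimination_time(mk(grid / 10 + gap, grid / 10))$day, 30)
  # overlap at the end: never separates persistently
  gap2 <- ifelse(grid <= 40, 2, 0)
  expect_true(is.na(discrimination_time(mk(grid / 10 + gap2, grid / 10))$day))
  # shrinking both bands never delays discrimination (antitone in SEM)
  set.seed(52)
  for (rep in 1:20) {
    m1 <- cumsum(runif(51, 0, 0.2))
    m2 <- m1 + seq(0, 2, length.out = 51) * runif(1, 0.5, 1.5)
    s <- runif(1, 0.1, 0.6)
    wide <- discrimination_time(mk(m2, m1, s, s))$day
    narrow <- discrimination_time(mk(m2, m1, s / 2, s / 2))$day
    if (!is.na(wide)) {
      expect_false(is.na(narrow))
      expect_lte(narrow, wide)
    }
  }
  # mismatched grids are an error
  bad <- mk(grid / 10, grid / 10)
  bad$day[bad$group == "B"] <- bad$day[bad$group == "B"] + 0.5
  expect_error(discrimination_time(bad), "grid")
})

test_that("cutoff attainment reads the mean curve against the diagnostic levels", {
  grid <- 0:60
  cv <- structure(
    dplyr::bind_rows(
      tibble::tibble(group = "e", subscale = "motor", day = grid,
                     mean = pmin(6, grid / 7), sem = 0.1, n = 10L),
      tibble::tibble(group = "e", subscale = "communication", day = grid,
                     mean = rep(1, 61), sem = 0.1, n = 10L),
      tibble::tibble(group = "r", subscale = "motor", day = grid,
                     mean = rep(6, 61), sem = 0.1, n = 10L)
    ),
    class = c("doc_curves", class(tibble::tibble())), grid_step = 1
  )
  mt <- cutoff_attainment_time(cv, "motor")
  expect_equal(mt$day[mt$group == "e"], 42) # first day 6/7 * day >= 6
  expect_equal(mt$day[mt$group == "r"], 0) # at cutoff from day 0
  cm <- cutoff_attainment_time(cv, "communication")
  expect_true(is.na(cm$day[cm$group == "e"])) # constant below cutoff
  expect_error(cutoff_attainment_time(cv, "visual"), "arg")
})

test_that("coefficient group tests behave on identical and separated groups", {
  b <- poly_basis(window = c(0, 60))
  days <- seq(3, 55, by = 7)
  mk_patient <- function(id, t50) {
    traj_assessments(id, days, function(d) round(6 * plogis((d - t50) / 5)))
  }
  aa <- dplyr::bind_rows(
    lapply(1:6, function(i) mk_patient(paste0("e", i), 18 + i)),
    lapply(1:6, function(i) mk_patient(paste0("r", i), 50 + i))
  )
  cohort <- tibble::tibble(
    patient = c(paste0("e", 1:6), paste0("r", 1:6)),
    diagnosis = "UWS",
    outcome = rep(c("Non DOC", "UWS"), each = 6)
  )
  cmp <- doc_comparisons(classify_outcome(cohort))[1, ]
  res <- coef_group_tests(aa, cmp, b, subsets = list(c(0, 1)),
                          lilliefors_nsim = 200, seed = 3)
  expect_equal(nrow(res), 10) # 5 subscales x 2 degrees
  # clearly separated groups: the baseline coefficient differs strongly
  expect_true(all(res$p_holm[res$degree == 0] < 0.01))
  expect_true(all(res$p_holm >= res$p_raw, na.rm = TRUE))
  # identical "groups": no signal
  aa2 <- dplyr::bind_rows(
    lapply(1:4, function(i) mk_patient(paste0("e", i), 20 + i)),
    lapply(1:4, function(i) mk_patient(paste0("r", i), 20 + i))
  )
  cohort2 <- cohort[c(1:4, 7:10), ]
  cmp2 <- doc_comparisons(classify_outcome(cohort2))[1, ]
  res2 <- coef_group_tests(aa2, cmp2, b, subsets = list(c(0, 1)),
                           lilliefors_nsim = 0)
  expect_true(all(res2$p_raw > 0.9, na.rm = TRUE))
  # degenerate comparison rows are flagged, not dropped
  res3 <- coef_group_tests(aa, doc_comparisons(classify_outcome(cohort))[8, ],
                           b, subsets = list(c(0, 1)), lilliefors_nsim = 0)
  expect_true(all(res3$flagged))
  expect_true(all(is.na(res3$p_raw)))
})
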